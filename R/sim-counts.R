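# Width of every planted peak (nt). Peaks are planted inside a single exon
# (the generator guarantees one exon >= 450 nt per transcript), so their
# genomic footprint is contiguous.
PLANTED_PEAK_WIDTH <- 250L

#' Generate synthetic count matrices and truth tables
#'
#' Simulates, at the window/gene level, the count structure of a paired
#' MeRIP-seq + RNA-seq experiment over the supplied annotation:
#' * input window counts are negative-binomial with mean proportional to the
#'   host gene's abundance and a log-normal library-size factor;
#' * IP window counts share the input rate times `peak_enrichment_fold`
#'   inside planted peaks (1 elsewhere);
#' * per-gene RNA-seq counts are negative-binomial with a planted condition
#'   effect of `de_log2fc_magnitude` for flagged genes;
#' * lncRNAs flagged both differentially expressed and differentially
#'   methylated receive sign-coupled effects whose population Pearson
#'   correlation equals `meth_expr_correlation`;
#' * with `motif_planting`, a cluster of five DRACH (GGACU) sites is written
#'   into the genome around each planted peak summit.
#'
#' @param config A [sim_config()].
#' @param annotation A [genome_annotation()] (from [generate_genome()]).
#' @param genome Optional [Biostrings::DNAStringSet]; required for motif
#'   planting, returned (possibly modified) in the result.
#' @return List with elements `wcm` ([window_counts()]), `gene_counts`
#'   (integer matrix genes x libraries), `gene_condition` (named condition
#'   vector), `truth` (list of `genes`, `peaks`, `pairs` data.frames) and
#'   `genome`.
#' @export
generate_counts <- function(config, annotation, genome = NULL) {
  validate_sim_config(config)
  if (!nrow(annotation$exons)) stop("annotation has no exons")
  set.seed(config$seed + 1L)

  lnc_types <- c("lincRNA", "antisense", "processed_transcript")
  g <- annotation$genes
  lnc_ids <- g$gene_id[g$gene_type %in% lnc_types]
  n_lnc <- length(lnc_ids)
  canon <- canonical_transcripts(annotation)
  rownames(canon) <- canon$gene_id

  # ---- flags: floor rounding, seeded sampling -------------------------------
  de_flag <- setNames(rep(FALSE, nrow(g)), g$gene_id)
  for (cls in list(lnc_ids, setdiff(g$gene_id, lnc_ids))) {
    n_de <- floor(config$frac_de * length(cls))
    if (n_de > 0) de_flag[sample(cls, n_de)] <- TRUE
  }

  n_peak <- if (config$peak_enrichment_fold > 1)
    floor(config$frac_lnc_with_peak * n_lnc) else 0L
  eligible <- lnc_ids[vapply(lnc_ids, function(id) {
    ex <- tx_exons(annotation, canon[id, "transcript_id"])
    nrow(ex) > 0 && max(ex$end - ex$start) >= PLANTED_PEAK_WIDTH + 10L
  }, logical(1))]
  if (n_peak > length(eligible))
    stop("only ", length(eligible), " lncRNAs can host a ",
         PLANTED_PEAK_WIDTH, " nt peak; ", n_peak, " requested")
  peak_hosts <- if (n_peak > 0) sample(eligible, n_peak) else character(0)

  # ---- planted effect sizes -------------------------------------------------
  de_lfc <- setNames(rep(0, nrow(g)), g$gene_id)
  flagged <- names(de_flag)[de_flag]
  de_lfc[flagged] <- sample(c(-1, 1), length(flagged), replace = TRUE) *
    config$de_log2fc_magnitude

  meth_lfc <- setNames(rep(0, length(peak_hosts)), peak_hosts)
  coupled <- intersect(peak_hosts, flagged)
  if (length(coupled)) {
    eff <- coupled_effects(length(coupled), config$meth_expr_correlation,
                           config$de_log2fc_magnitude,
                           config$meth_diff_magnitude)
    de_lfc[coupled] <- eff$expr
    meth_lfc[coupled] <- eff$meth
  }

  # ---- forced cis neighbor pairs -------------------------------------------
  pairs <- data.frame(lnc_gene_id = character(), coding_gene_id = character(),
                      type = character(), stringsAsFactors = FALSE)
  np <- config$planted_neighbor_pairs
  if (np > 0) {
    coding_ids <- g$gene_id[g$gene_type == "protein_coding"]
    cand <- peak_hosts[vapply(peak_hosts, function(id)
      any(g$chrom[g$gene_id %in% coding_ids] == g$chrom[g$gene_id == id]),
      logical(1))]
    if (length(cand) < 2 * np)
      stop("not enough peak-bearing lncRNAs with coding neighbors to plant ",
           2 * np, " pairs")
    chosen <- sample(cand, 2 * np)
    taken <- character(0)
    for (j in seq_along(chosen)) {
      lid <- chosen[j]
      retro <- j <= np
      cod <- nearest_coding(g, lid, coding_ids, exclude = taken)
      if (is.na(cod)) next
      taken <- c(taken, cod)
      de_flag[lid] <- TRUE; de_flag[cod] <- TRUE
      s_lnc <- if (retro) -1 else 1
      de_lfc[lid] <- s_lnc * config$de_log2fc_magnitude
      de_lfc[cod] <- config$de_log2fc_magnitude   # coding gene goes up
      meth_lfc[lid] <- s_lnc * config$meth_diff_magnitude
      pairs <- rbind(pairs, data.frame(
        lnc_gene_id = lid, coding_gene_id = cod,
        type = if (retro) "retrograde" else "positive",
        stringsAsFactors = FALSE))
    }
  }

  # ---- peak placement -------------------------------------------------------
  peaks <- place_peaks(annotation, canon, peak_hosts, meth_lfc,
                       config$peak_enrichment_fold)

  # ---- window and gene counts ----------------------------------------------
  win <- tile_windows(annotation, config$window_size,
                      config$window_size %/% 2L)
  base_g <- setNames(exp(rnorm(nrow(g), 0, 0.5)), g$gene_id)

  conds <- c("GM", "D4")
  r <- config$replicates_per_condition
  libs <- do.call(rbind, lapply(conds, function(cond)
    data.frame(lib_id = c(sprintf("%s_ip_%d", cond, 1:r),
                          sprintf("%s_input_%d", cond, 1:r)),
               condition = cond,
               assay = rep(c("ip", "input"), each = r),
               replicate = rep(1:r, 2), stringsAsFactors = FALSE)))
  sf <- setNames(exp(rnorm(nrow(libs), 0, 0.2)), libs$lib_id)

  wbase <- config$nb_mean * base_g[win$gene_id]
  wfold <- matrix(1, nrow(win), 2, dimnames = list(NULL, conds))
  if (nrow(peaks)) {
    smid <- (win$s_start + win$s_end) / 2
    for (i in seq_len(nrow(peaks))) {
      hit <- win$gene_id == peaks$gene_id[i] &
        smid >= peaks$s_start[i] & smid < peaks$s_end[i]
      wfold[hit, "GM"] <- peaks$fold_GM[i]
      wfold[hit, "D4"] <- peaks$fold_D4[i]
    }
  }
  wexpr <- outer(2^de_lfc[win$gene_id], c(GM = 0, D4 = 1), function(e, d) e^d)

  size <- 1 / config$nb_dispersion
  counts <- sapply(seq_len(nrow(libs)), function(j) {
    cond <- libs$condition[j]
    mu <- wbase * sf[j] * wexpr[, cond] *
      (if (libs$assay[j] == "ip") wfold[, cond] else 1)
    rnbinom(length(mu), mu = mu, size = size)
  })
  colnames(counts) <- libs$lib_id
  wcm <- window_counts(win, counts, libs)

  rna_libs <- paste0(rep(conds, each = r), "_rna_", rep(1:r, 2))
  rna_cond <- setNames(rep(conds, each = r), rna_libs)
  rna_sf <- setNames(exp(rnorm(length(rna_libs), 0, 0.2)), rna_libs)
  glen <- setNames(canon$spliced_length, canon$gene_id)[g$gene_id]
  glen[is.na(glen)] <- 1000L
  gmu_base <- config$nb_mean * base_g[g$gene_id] * glen / 1000
  gene_counts <- sapply(rna_libs, function(l) {
    mult <- if (rna_cond[l] == "D4") 2^de_lfc[g$gene_id] else rep(1, nrow(g))
    rnbinom(nrow(g), mu = gmu_base * rna_sf[l] * mult, size = size)
  })
  rownames(gene_counts) <- g$gene_id

  # ---- motif planting -------------------------------------------------------
  if (config$motif_planting && nrow(peaks) && !is.null(genome)) {
    planted <- plant_drach(genome, annotation, canon, peaks)
    genome <- planted$genome
    peaks$motif_positions <- planted$positions
  } else {
    peaks$motif_positions <- rep("", nrow(peaks))
  }

  truth_genes <- data.frame(gene_id = g$gene_id, gene_type = g$gene_type,
                            base_mean = unname(base_g[g$gene_id]),
                            true_de_flag = unname(de_flag[g$gene_id]),
                            true_de_log2fc = unname(de_lfc[g$gene_id]),
                            stringsAsFactors = FALSE)
  stage_log("generate_counts",
            "%d windows x %d libs; %d DE genes; %d planted peaks (%d differential)",
            nrow(win), nrow(libs), sum(de_flag), nrow(peaks),
            sum(peaks$true_diff_flag))
  list(wcm = wcm, gene_counts = gene_counts, gene_condition = rna_cond,
       truth = list(genes = truth_genes, peaks = peaks, pairs = pairs),
       genome = genome)
}

# Coupled planted effects: a central-truncated bivariate normal. Pairs
# (Z_meth, Z_expr) are drawn from a latent bivariate normal and kept only
# when both |Z| >= COUPLING_TRUNCATION, so planted effects are continuous
# (like a real methylation-expression scatter) yet bounded away from zero
# (so truth-table quadrant membership is detectable). The latent correlation
# is calibrated so the population Pearson r of the kept pairs equals rho.
COUPLING_TRUNCATION <- 0.7

coupled_effects <- function(n, rho, expr_mag, meth_mag,
                            z0 = COUPLING_TRUNCATION) {
  rho_lat <- calibrate_coupling_rho(rho, z0)
  z1 <- numeric(0); z2 <- numeric(0)
  while (length(z1) < n) {
    u1 <- rnorm(4L * n)
    u2 <- rho_lat * u1 + sqrt(1 - rho_lat^2) * rnorm(4L * n)
    keep <- abs(u1) >= z0 & abs(u2) >= z0
    z1 <- c(z1, u1[keep]); z2 <- c(z2, u2[keep])
  }
  list(meth = meth_mag * z1[seq_len(n)], expr = expr_mag * z2[seq_len(n)])
}

.coupling_cache <- new.env(parent = emptyenv())

# latent correlation whose doubly-truncated Pearson r equals the target,
# root-found against a fixed-seed Monte-Carlo sample (deterministic, cached;
# the caller's RNG stream is left untouched)
calibrate_coupling_rho <- function(target, z0, n_mc = 2e5) {
  if (target == 0) return(0)
  if (abs(target) > 0.99) target <- sign(target) * 0.99
  key <- sprintf("%.6f_%.3f", target, z0)
  if (!is.null(.coupling_cache[[key]])) return(.coupling_cache[[key]])
  seed_state <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(seed_state))
    assign(".Random.seed", seed_state, .GlobalEnv))
  set.seed(123451L)
  u1 <- rnorm(n_mc); u2 <- rnorm(n_mc)
  trunc_r <- function(rho) {
    z2 <- rho * u1 + sqrt(1 - rho^2) * u2
    keep <- abs(u1) >= z0 & abs(z2) >= z0
    cor(u1[keep], z2[keep])
  }
  s <- sign(target)
  root <- uniroot(function(r) trunc_r(r) - abs(target),
                  lower = 0, upper = 0.9995, tol = 1e-4)$root
  .coupling_cache[[key]] <- s * root
  s * root
}

nearest_coding <- function(genes, lnc_id, coding_ids, exclude = character(0)) {
  li <- genes[genes$gene_id == lnc_id, ]
  cand <- genes[genes$gene_id %in% setdiff(coding_ids, exclude) &
                genes$chrom == li$chrom, ]
  if (!nrow(cand)) return(NA_character_)
  d <- pmax(0L, pmax(li$start - cand$end, cand$start - li$end))
  cand$gene_id[order(d, cand$start)][1]
}

place_peaks <- function(ann, canon, hosts, meth_lfc, fold) {
  if (!length(hosts))
    return(data.frame(gene_id = character(), chrom = character(),
                      strand = character(), start = integer(), end = integer(),
                      summit = integer(), s_start = integer(), s_end = integer(),
                      fold_GM = numeric(), fold_D4 = numeric(),
                      true_diff_flag = logical(), true_diff_log2fc = numeric(),
                      stringsAsFactors = FALSE))
  out <- lapply(hosts, function(id) {
    tx <- canon[id, "transcript_id"]
    ex <- tx_exons(ann, tx)
    big <- which.max(ex$end - ex$start)
    lo <- ex$start[big] + 5L
    hi <- ex$end[big] - PLANTED_PEAK_WIDTH - 5L
    gstart <- if (hi > lo) sample(lo:hi, 1L) else lo
    gend <- gstart + PLANTED_PEAK_WIDTH
    sc <- g2t_exons(ex, ex$strand[1], c(gstart, gend - 1L))
    d <- meth_lfc[[id]]
    data.frame(gene_id = id, chrom = ex$chrom[1], strand = ex$strand[1],
               start = gstart, end = gend,
               summit = gstart + PLANTED_PEAK_WIDTH %/% 2L,
               s_start = min(sc), s_end = max(sc) + 1L,
               fold_GM = fold * 2^(-d / 2), fold_D4 = fold * 2^(d / 2),
               true_diff_flag = d != 0, true_diff_log2fc = d,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# write a cluster of 5 GGACU (DNA: GGACT) sites, spaced 20 nt, centred on
# each planted peak summit; sense-strand sequence, so the reverse complement
# is written for minus-strand hosts
plant_drach <- function(genome, ann, canon, peaks) {
  positions <- character(nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    tx <- canon[peaks$gene_id[i], "transcript_id"]
    ex <- tx_exons(ann, tx)
    strand <- ex$strand[1]
    s_sum <- g2t_exons(ex, strand, peaks$summit[i])
    tpos <- s_sum - 2L + c(-40L, -20L, 0L, 20L, 40L)
    gpos <- integer(0)
    for (p in tpos) {
      gs <- sort(t2g_exons(ex, strand, c(p, p + 4L)))
      at <- IRanges::IRanges(gs[1] + 1L, gs[1] + 5L)   # 1-based for replaceAt
      val <- if (strand == "+") "GGACT" else "AGTCC"
      chrom <- peaks$chrom[i]
      genome[[chrom]] <- Biostrings::replaceAt(genome[[chrom]], at,
                                               Biostrings::DNAString(val))
      gpos <- c(gpos, gs[1])
    }
    positions[i] <- paste(sort(gpos), collapse = ",")
  }
  list(genome = genome, positions = positions)
}

#' One-call simulation of a full synthetic dataset
#'
#' @param config A [sim_config()].
#' @return The [generate_counts()] result with the annotation added under
#'   `$annotation`.
#' @export
simulate_dataset <- function(config) {
  gen <- generate_genome(config)
  sim <- generate_counts(config, gen$annotation, gen$genome)
  sim$annotation <- gen$annotation
  sim
}

#' Write a simulated dataset to disk
#'
#' Emits `genome.fa`, `annotation.gtf`, `window_counts.tsv` (chrom, start,
#' end, strand, gene_id, spliced coordinates, then one column per library),
#' `gene_counts.tsv`, `truth_genes.tsv` and `truth_peaks.tsv`. All files are
#' plain text and byte-stable for a fixed seed.
#'
#' @param sim A [simulate_dataset()] result.
#' @param outdir Output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_simulation <- function(sim, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  Biostrings::writeXStringSet(sim$genome, file.path(outdir, "genome.fa"))
  write_gtf(sim$annotation, file.path(outdir, "annotation.gtf"))
  w <- sim$wcm$windows
  wtab <- cbind(data.frame(chrom = w$chrom, start = w$g_start, end = w$g_end,
                           strand = w$strand, gene_id = w$gene_id,
                           s_start = w$s_start, s_end = w$s_end,
                           stringsAsFactors = FALSE),
                as.data.frame(sim$wcm$counts))
  write.table(wtab, file.path(outdir, "window_counts.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  gtab <- cbind(data.frame(gene_id = rownames(sim$gene_counts)),
                as.data.frame(sim$gene_counts))
  write.table(gtab, file.path(outdir, "gene_counts.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(sim$truth$genes, file.path(outdir, "truth_genes.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(sim$truth$peaks, file.path(outdir, "truth_peaks.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(sim$truth$pairs, file.path(outdir, "truth_pairs.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(outdir)
}
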