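#' Default pipeline configuration
#'
#' A nested list understood by [validate_config()] and [run_pipeline()]:
#' `simulate` (logical), `sim` (overrides for [sim_config()]), `paths`
#' (annotation/genome/window_counts/gene_counts/gene_sets for real inputs),
#' `thresholds` (`rna_padj`, `peak_fdr`, `diff_fdr`), `window`, `step`,
#' `seed`, and `stages` (logical toggles: `expr`, `peaks`, `anatomy`,
#' `integration`, `neighbors`).
#'
#' @return The default configuration list.
#' @export
default_config <- function() {
  list(simulate = TRUE,
       sim = list(),
       paths = list(),
       thresholds = list(rna_padj = 0.05, peak_fdr = 0.05, diff_fdr = 0.05),
       window = 100L, step = 50L, seed = 1L,
       stages = list(expr = TRUE, peaks = TRUE, anatomy = TRUE,
                     integration = TRUE, neighbors = TRUE))
}

#' Validate a pipeline configuration
#'
#' Collects every problem instead of failing on the first.
#'
#' @param config A configuration list, or a path to a YAML file.
#' @return Character vector of error messages (empty when valid).
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  errors <- character(0)
  known <- names(default_config())
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    errors <- c(errors, paste("unknown keys:", paste(unknown, collapse = ", ")))
  th <- config$thresholds
  for (nm in names(th)) {
    v <- th[[nm]]
    if (!is.numeric(v) || length(v) != 1L || v <= 0 || v > 1)
      errors <- c(errors, paste0("threshold out of range: ", nm, " = ", v))
  }
  for (nm in c("window", "step")) {
    v <- config[[nm]]
    if (!is.null(v) && (!is.numeric(v) || v < 1))
      errors <- c(errors, paste0(nm, " must be a positive integer"))
  }
  if (isTRUE(config$simulate) && is.null(config$seed))
    errors <- c(errors, "seed required when the simulation stage is enabled")
  if (!isTRUE(config$simulate)) {
    need <- c("annotation", "genome", "window_counts", "gene_counts")
    for (nm in need) {
      p <- config$paths[[nm]]
      if (is.null(p)) errors <- c(errors, paste("missing path:", nm))
      else if (!file.exists(p)) errors <- c(errors, paste("file not found:", p))
    }
  }
  errors
}

merge_config <- function(config) {
  base <- default_config()
  for (nm in names(config)) {
    if (is.list(base[[nm]]) && is.list(config[[nm]]))
      base[[nm]][names(config[[nm]])] <- config[[nm]]
    else base[[nm]] <- config[[nm]]
  }
  base
}

#' Run the full analysis pipeline
#'
#' Stages run in dependency order (simulate/load, expression, peaks,
#' anatomy, integration, neighbors); every stage writes its table under
#' `outdir` and logs its row attrition, and a JSON manifest records input
#' hashes, seeds, versions and per-stage row counts. Rerunning with the
#' same configuration reproduces identical output files (manifest
#' timestamp aside).
#'
#' @param config Configuration list (see [default_config()]) or YAML path.
#' @param outdir Output directory.
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config = default_config(), outdir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  errs <- validate_config(config)
  if (length(errs)) stop("invalid configuration:\n  ",
                         paste(errs, collapse = "\n  "))
  cfg <- merge_config(config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package_version = as.character(packageVersion("lncm6a")),
                   r_version = R.version.string,
                   seed = cfg$seed, timestamp = format(Sys.time()),
                   stages = list(), files = list())

  th <- cfg$thresholds
  if (isTRUE(cfg$simulate)) {
    sim_args <- cfg$sim
    sim_args$seed <- cfg$seed
    sim_args$window_size <- cfg$window
    sim <- simulate_dataset(do.call(sim_config, sim_args))
    write_simulation(sim, file.path(outdir, "simulated"))
    ann <- sim$annotation; genome <- sim$genome; wcm <- sim$wcm
    gc <- gene_counts(sim$gene_counts, sim$gene_condition)
    manifest$stages$simulate <- list(genes = nrow(ann$genes),
                                     windows = nrow(wcm$windows),
                                     planted_peaks = nrow(sim$truth$peaks))
  } else {
    ann <- read_gtf(cfg$paths$annotation)
    genome <- Biostrings::readDNAStringSet(cfg$paths$genome)
    names(genome) <- sub(" .*", "", names(genome))
    loaded <- read_window_counts(cfg$paths$window_counts, ann,
                                 width = cfg$window, step = cfg$step)
    wcm <- loaded
    gtab <- read.delim(cfg$paths$gene_counts, check.names = FALSE)
    m <- as.matrix(gtab[, -1, drop = FALSE])
    rownames(m) <- gtab[[1]]
    cond <- ifelse(grepl("^GM", colnames(m)), "GM", "D4")
    gc <- gene_counts(m, cond)
    for (nm in names(cfg$paths))
      manifest$files[[nm]] <- unname(tools::md5sum(cfg$paths[[nm]]))
  }

  de <- de_split <- NULL
  if (isTRUE(cfg$stages$expr)) {
    de <- differential_expression(gc, ann)
    de_split <- split_by_biotype(de, ann)
    write_de_table(de_split$lnc, ann, file.path(outdir, "de_lncRNA.tsv"))
    write_de_table(de_split$mrna, ann, file.path(outdir, "de_mRNA.tsv"))
    manifest$stages$expr <- list(tested = nrow(de),
                                 lnc = nrow(de_split$lnc),
                                 mrna = nrow(de_split$mrna))
  }

  peaks_gm <- peaks_d4 <- dp <- NULL
  if (isTRUE(cfg$stages$peaks)) {
    peaks_gm <- call_peaks(wcm, "GM", th$peak_fdr)
    peaks_d4 <- call_peaks(wcm, "D4", th$peak_fdr)
    write_peaks_bed(peaks_gm, file.path(outdir, "peaks_GM.bed"))
    write_peaks_bed(peaks_d4, file.path(outdir, "peaks_D4.bed"))
    dp <- differential_peaks(peaks_gm, peaks_d4, wcm, th$diff_fdr)
    write.table(dp, file.path(outdir, "diff_peaks.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    manifest$stages$peaks <- list(GM = nrow(peaks_gm), D4 = nrow(peaks_d4),
                                  union = nrow(dp))
  }

  if (isTRUE(cfg$stages$anatomy) && !is.null(dp)) {
    all_peaks <- rbind(peaks_gm, peaks_d4)
    if (nrow(all_peaks)) {
      es <- element_summary(all_peaks, ann)
      write.table(data.frame(element = names(es$counts), count = es$counts,
                             proportion = es$proportions,
                             length_share = es$length_share,
                             relative_enrichment = es$relative_enrichment),
                  file.path(outdir, "element_summary.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      mg <- metagene(all_peaks, ann)
      write.table(mg, file.path(outdir, "metagene.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      ppg <- peaks_per_gene(all_peaks)
      fg <- peak_sequences(all_peaks, ann, genome)
      bg <- nonpeak_background(all_peaks, ann, genome, seed = cfg$seed)
      mot <- motif_enrichment(fg, bg)
      write.table(mot, file.path(outdir, "motif.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      manifest$stages$anatomy <- list(peaks = nrow(all_peaks),
                                      median_peaks_per_gene = ppg$median,
                                      drach_fold = mot$fold[1])
    }
  }

  if (isTRUE(cfg$stages$integration) && !is.null(dp) && !is.null(de)) {
    rec <- integrate_meth_expr(de_split$lnc, dp)
    quad <- classify_quadrants(rec, th$rna_padj, th$diff_fdr)
    write.table(quad$records, file.path(outdir, "quadrants.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    corr <- if (sum(quad$records$group != "Excluded") >= 3)
      meth_expr_correlation(rec, "significant", th$rna_padj, th$diff_fdr)
    else list(r = NA_real_, p = NA_real_, n = 0L)
    meth_ids <- unique(c(peaks_gm$gene_id, peaks_d4$gene_id))
    lnc_de <- de_split$lnc
    ks <- tryCatch(ks_by_methylation(lnc_de$log2FoldChange,
                                     lnc_de$gene_id %in% meth_ids),
                   error = function(e) list(D = NA_real_, p = NA_real_))
    jsonlite::write_json(list(quadrant_counts = as.list(quad$counts),
                              correlation = corr, ks = ks),
                         file.path(outdir, "integration.json"),
                         auto_unbox = TRUE, digits = NA)
    manifest$stages$integration <- list(records = nrow(rec),
                                        classified = sum(quad$records$group != "Excluded"))
  }

  if (isTRUE(cfg$stages$neighbors) && !is.null(dp) && !is.null(de)) {
    lnc_de_sig <- de_split$lnc$gene_id[de_split$lnc$padj <= th$rna_padj &
                                       !is.na(de_split$lnc$padj)]
    pairs <- find_neighbors_all(lnc_de_sig, ann)
    kept <- if (!is.null(pairs)) pair_filter(pairs, de, dp, th$rna_padj)
            else data.frame()
    write.table(kept, file.path(outdir, "neighbor_pairs.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    if (!is.null(cfg$paths$gene_sets) && nrow(kept)) {
      sets <- read_gmt(cfg$paths$gene_sets)
      enr <- ora(unique(kept$coding_gene_id), sets,
                 universe = ann$genes$gene_id[ann$genes$gene_type == "protein_coding"])
      write.table(enr, file.path(outdir, "ora.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    }
    manifest$stages$neighbors <- list(candidate_pairs = if (is.null(pairs)) 0L else nrow(pairs),
                                      retained = nrow(kept))
  }

  for (f in setdiff(list.files(outdir, recursive = TRUE, full.names = TRUE),
                    file.path(outdir, "manifest.json")))
    manifest$files[[sub(paste0("^", outdir, "/?"), "", f)]] <-
      unname(tools::md5sum(f))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Read a window-count TSV emitted by [write_simulation()]
#'
#' @param path TSV with columns chrom, start, end, strand, gene_id,
#'   s_start, s_end, then one column per library (names encoding
#'   `condition_assay_replicate`).
#' @param ann The matching [genome_annotation()].
#' @param width,step Window geometry used when the file was produced.
#' @return A [window_counts()].
#' @export
read_window_counts <- function(path, ann, width = 100L, step = 50L) {
  tab <- read.delim(path, check.names = FALSE)
  meta_cols <- c("chrom", "start", "end", "strand", "gene_id", "s_start", "s_end")
  libs_ids <- setdiff(names(tab), meta_cols)
  canon <- canonical_transcripts(ann)
  tx <- setNames(canon$transcript_id, canon$gene_id)
  win <- data.frame(window_id = sprintf("W%06d", seq_len(nrow(tab))),
                    gene_id = tab$gene_id, transcript_id = unname(tx[tab$gene_id]),
                    chrom = tab$chrom, strand = tab$strand,
                    s_start = tab$s_start, s_end = tab$s_end,
                    g_start = tab$start, g_end = tab$end,
                    stringsAsFactors = FALSE)
  attr(win, "width") <- width; attr(win, "step") <- step
  attr(win, "annotation") <- ann
  parts <- strsplit(libs_ids, "_")
  libs <- data.frame(lib_id = libs_ids,
                     condition = vapply(parts, `[`, "", 1L),
                     assay = vapply(parts, `[`, "", 2L),
                     replicate = as.integer(vapply(parts, `[`, "", 3L)),
                     stringsAsFactors = FALSE)
  window_counts(win, as.matrix(tab[, libs_ids, drop = FALSE]), libs)
}
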