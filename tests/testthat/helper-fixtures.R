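# Shared fixtures and independent oracles for the test suite. Oracles are
# deliberately written as brute-force enumerations or direct formula
# evaluations, independent of the package's implementation paths.

# -- tiny hand-built annotations ---------------------------------------------

# one gene, two exons [100,200) + [300,400)
two_exon_annotation <- function(strand = "+") {
  genome_annotation(
    genes = data.frame(gene_id = "g1", gene_name = "G1", gene_type = "lincRNA",
                       chrom = "chr1", strand = strand,
                       start = 100L, end = 400L),
    transcripts = data.frame(transcript_id = "t1", gene_id = "g1"),
    exons = data.frame(transcript_id = "t1", chrom = "chr1",
                       start = c(100L, 300L), end = c(200L, 400L),
                       strand = strand))
}

three_exon_annotation <- function(strand = "+") {
  genome_annotation(
    genes = data.frame(gene_id = "g1", gene_name = "G1", gene_type = "lincRNA",
                       chrom = "chr1", strand = strand,
                       start = 100L, end = 800L),
    transcripts = data.frame(transcript_id = "t1", gene_id = "g1"),
    exons = data.frame(transcript_id = "t1", chrom = "chr1",
                       start = c(100L, 400L, 700L),
                       end = c(200L, 500L, 800L),
                       strand = strand))
}

# mirror an annotation: reverse-complement coordinates on a chromosome of
# length len and flip strands
mirror_annotation <- function(ann, len) {
  flip <- function(s) ifelse(s == "+", "-", "+")
  g <- ann$genes; e <- ann$exons
  new_g <- g
  new_g$start <- len - g$end; new_g$end <- len - g$start
  new_g$strand <- flip(g$strand)
  new_e <- e
  new_e$start <- len - e$end; new_e$end <- len - e$start
  new_e$strand <- flip(e$strand)
  genome_annotation(new_g, ann$transcripts, new_e)
}

# -- oracles ------------------------------------------------------------------

# binomial upper tail by explicit pmf summation
oracle_binom_upper <- function(x, n, p0) {
  if (n == 0) return(1)
  sum(vapply(x:n, function(k)
    choose(n, k) * p0^k * (1 - p0)^(n - k), numeric(1)))
}

# two-sided Fisher p for a 2x2 by enumerating all tables with the same
# margins and summing probabilities <= that of the observed table
oracle_fisher2x2 <- function(x11, x12, x21, x22) {
  r1 <- x11 + x12; c1 <- x11 + x21; n <- x11 + x12 + x21 + x22
  lo <- max(0, r1 + c1 - n); hi <- min(r1, c1)
  pr <- vapply(lo:hi, function(k) dhyper(k, c1, n - c1, r1), numeric(1))
  obs <- dhyper(x11, c1, n - c1, r1)
  sum(pr[pr <= obs * (1 + 1e-7)])
}

# two-sample KS D by a direct ECDF sweep over all jump points
oracle_ks_D <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  max(abs(vapply(pts, function(t) mean(x <= t) - mean(y <= t), numeric(1))))
}

# permutation p-value for the two-sample KS D (upper tail, >= observed)
oracle_ks_perm_p <- function(x, y, n_perm = 1e5, seed = 1) {
  set.seed(seed)
  z <- c(x, y); n1 <- length(x)
  ord <- order(z)
  steps <- rep(-1 / length(y), length(z))
  d_obs <- oracle_ks_D(x, y)
  hits <- 0L
  for (i in seq_len(n_perm)) {
    g <- logical(length(z)); g[sample.int(length(z), n1)] <- TRUE
    s <- ifelse(g[ord], 1 / n1, -1 / length(y))
    if (max(abs(cumsum(s))) >= d_obs - 1e-12) hits <- hits + 1L
  }
  hits / n_perm
}

# hypergeometric upper tail by explicit summation
oracle_hyper_upper <- function(overlap, N, K, n) {
  ks <- overlap:min(K, n)
  sum(vapply(ks, function(k)
    choose(K, k) * choose(N - K, n - k), numeric(1))) / choose(N, n)
}

# brute-force nearest coding neighbors by sorting every candidate
oracle_neighbors <- function(lnc_id, ann, k = 5) {
  g <- ann$genes
  li <- g[g$gene_id == lnc_id, ]
  cand <- g[g$gene_type == "protein_coding" & g$chrom == li$chrom &
            g$gene_id != lnc_id, ]
  if (!nrow(cand)) return(NULL)
  rows <- lapply(seq_len(nrow(cand)), function(i) {
    ci <- cand[i, ]
    d <- max(0, max(li$start - ci$end, ci$start - li$end))
    side <- if (d == 0) {
      if (ci$start < li$start) "upstream" else "downstream"
    } else if (ci$end <= li$start) "upstream" else "downstream"
    data.frame(coding_gene_id = ci$gene_id, side = side, distance = d,
               start = ci$start, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  out <- lapply(c("upstream", "downstream"), function(s) {
    d <- df[df$side == s, ]
    d <- d[order(d$distance, d$start), ]
    d <- head(d, k)
    if (!nrow(d)) return(NULL)
    d$rank <- seq_len(nrow(d))
    d
  })
  do.call(rbind, out)
}

# IUPAC scan oracle via regular expressions
IUPAC_RE <- c(A = "A", C = "C", G = "G", T = "T", R = "[AG]", Y = "[CT]",
              S = "[CG]", W = "[AT]", K = "[GT]", M = "[AC]", B = "[CGT]",
              D = "[AGT]", H = "[ACT]", V = "[ACG]", N = "[ACGT]")
oracle_motif_count <- function(seq, pattern) {
  pattern <- chartr("U", "T", toupper(pattern))
  re <- paste0("(?=", paste(IUPAC_RE[strsplit(pattern, "")[[1]]],
                            collapse = ""), ")")
  m <- gregexpr(re, chartr("U", "T", toupper(seq)), perl = TRUE)[[1]]
  if (length(m) == 1 && m[1] == -1) 0L else length(m)
}

# -- small simulation configs -------------------------------------------------

quick_config <- function(seed = 1, ...) {
  args <- list(seed = seed, n_chromosomes = 1L, chrom_length = 250000L,
               n_lnc = 20L, n_coding = 20L)
  args[names(list(...))] <- list(...)
  do.call(sim_config, args)
}

rand_seq <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))
}
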