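#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator. Defaults describe the
#' experimental design being emulated: two conditions (GM, D4) with two
#' replicate libraries each, 100-nt windows matching the RNA fragmentation
#' size, negative-binomial counts with variance `m + alpha * m^2`
#' (`alpha = 0.1`), 8-fold IP enrichment inside planted peaks, and a
#' planted positive coupling (r = 0.6) between methylation change and
#' expression change for lncRNAs carrying both.
#'
#' @param seed Integer seed; a fixed seed makes every emitted file
#'   byte-identical across runs.
#' @param n_chromosomes,chrom_length Number and length (nt) of chromosomes.
#' @param n_lnc,n_coding Gene counts for the lncRNA and protein-coding
#'   classes.
#' @param exon_count_range Integer pair, inclusive range of exons per
#'   transcript.
#' @param window_size Window width in nt for IP/input counting.
#' @param replicates_per_condition Replicate libraries per condition (both
#'   for RNA-seq and for each MeRIP fraction).
#' @param nb_mean Baseline negative-binomial mean per window (and per-gene
#'   scale for RNA-seq counts).
#' @param nb_dispersion NB dispersion `alpha` (variance `m + alpha m^2`).
#' @param peak_enrichment_fold IP/input rate ratio inside planted peaks;
#'   must be `>= 1`, and `1` means no peaks are planted (null model).
#' @param frac_lnc_with_peak Fraction of lncRNAs receiving a planted peak
#'   (floor rounding).
#' @param frac_de Fraction of genes per biotype class flagged differentially
#'   expressed (floor rounding).
#' @param de_log2fc_magnitude Absolute planted log2 fold change for flagged
#'   genes.
#' @param meth_diff_magnitude Absolute planted methylation log2 fold change
#'   for differential peaks.
#' @param meth_expr_correlation Target population Pearson correlation
#'   between planted methylation change and expression change over lncRNAs
#'   flagged for both, in `[-1, 1]`.
#' @param motif_planting If `TRUE`, a cluster of DRACH sites (GGACU) is
#'   written into the genome at each planted peak summit.
#' @param planted_neighbor_pairs Number of retrograde and of positive
#'   lncRNA/coding neighbor pairs to force (in addition to the fraction-based
#'   flags; default 0).
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_chromosomes = 2L,
                       chrom_length = 500000L,
                       n_lnc = 60L,
                       n_coding = 60L,
                       exon_count_range = c(2L, 4L),
                       window_size = 100L,
                       replicates_per_condition = 2L,
                       nb_mean = 50,
                       nb_dispersion = 0.1,
                       peak_enrichment_fold = 8,
                       frac_lnc_with_peak = 0.5,
                       frac_de = 0.3,
                       de_log2fc_magnitude = 2,
                       meth_diff_magnitude = 2.5,
                       meth_expr_correlation = 0.6,
                       motif_planting = TRUE,
                       planted_neighbor_pairs = 0L) {
  cfg <- list(seed = as.integer(seed),
              n_chromosomes = as.integer(n_chromosomes),
              chrom_length = as.integer(chrom_length),
              n_lnc = as.integer(n_lnc),
              n_coding = as.integer(n_coding),
              exon_count_range = as.integer(exon_count_range),
              window_size = as.integer(window_size),
              replicates_per_condition = as.integer(replicates_per_condition),
              nb_mean = nb_mean,
              nb_dispersion = nb_dispersion,
              peak_enrichment_fold = peak_enrichment_fold,
              frac_lnc_with_peak = frac_lnc_with_peak,
              frac_de = frac_de,
              de_log2fc_magnitude = de_log2fc_magnitude,
              meth_diff_magnitude = meth_diff_magnitude,
              meth_expr_correlation = meth_expr_correlation,
              motif_planting = isTRUE(motif_planting),
              planted_neighbor_pairs = as.integer(planted_neighbor_pairs))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(length(cfg$seed) == 1L, !is.na(cfg$seed))
  if (cfg$n_chromosomes < 1L) stop("n_chromosomes must be >= 1")
  if (cfg$chrom_length < 1L) stop("chrom_length must be positive")
  if (cfg$n_lnc < 0L || cfg$n_coding < 0L) stop("gene counts must be >= 0")
  if (length(cfg$exon_count_range) != 2L ||
      cfg$exon_count_range[1] < 1L ||
      cfg$exon_count_range[2] < cfg$exon_count_range[1])
    stop("exon_count_range must be an increasing integer pair >= 1")
  if (cfg$window_size < 2L) stop("window_size too small")
  if (cfg$replicates_per_condition < 1L) stop("need >= 1 replicate per condition")
  if (cfg$nb_mean <= 0) stop("nb_mean must be positive")
  if (cfg$nb_dispersion <= 0) stop("nb_dispersion must be positive")
  if (cfg$peak_enrichment_fold < 1)
    stop("peak_enrichment_fold must be >= 1 (1 = null model, no peaks)")
  for (f in c("frac_lnc_with_peak", "frac_de"))
    if (cfg[[f]] < 0 || cfg[[f]] > 1) stop(f, " must lie in [0, 1]")
  if (cfg$de_log2fc_magnitude <= 0) stop("de_log2fc_magnitude must be positive")
  if (cfg$meth_diff_magnitude <= 0) stop("meth_diff_magnitude must be positive")
  if (abs(cfg$meth_expr_correlation) > 1)
    stop("meth_expr_correlation must lie in [-1, 1]")
  invisible(cfg)
}
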