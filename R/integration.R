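LG_ALPHA <- log10(0.05)   # -1.30103: significance cutoff on log10(FDR)

#' Join differential methylation with differential expression per gene
#'
#' When a gene hosts several differential peaks, the peak with the smallest
#' FDR represents it.
#'
#' @param de A [differential_expression()] table.
#' @param diff_peaks A [differential_peaks()] table.
#' @return data.frame with columns `gene_id`, `rna_log2fc`, `rna_padj`,
#'   `meth_diff_log2fc`, `meth_lg_fdr`, one row per gene present in both
#'   inputs.
#' @export
integrate_meth_expr <- function(de, diff_peaks) {
  if (!nrow(diff_peaks))
    return(data.frame(gene_id = character(), rna_log2fc = numeric(),
                      rna_padj = numeric(), meth_diff_log2fc = numeric(),
                      meth_lg_fdr = numeric(), stringsAsFactors = FALSE))
  dp <- diff_peaks[order(diff_peaks$diff_fdr), ]
  dp <- dp[!duplicated(dp$gene_id), ]
  common <- intersect(dp$gene_id, de$gene_id)
  dp <- dp[match(common, dp$gene_id), ]
  dd <- de[match(common, de$gene_id), ]
  data.frame(gene_id = common,
             rna_log2fc = dd$log2FoldChange, rna_padj = dd$padj,
             meth_diff_log2fc = dp$diff_log2_fc,
             meth_lg_fdr = dp$diff_lg_fdr,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Four-quadrant methylation-by-expression classification
#'
#' Genes significant on both layers (expression `padj <= rna_alpha`, peak
#' FDR `<= meth_alpha`, ties significant) are classified by the signs of
#' their two changes into `Hyper-up`, `Hyper-down`, `Hypo-up`, `Hypo-down`;
#' everything else is `Excluded` (with a reason code). Methylation
#' significance may be supplied as an FDR or as log10(FDR) — state which via
#' `meth_sig`, it is never guessed.
#'
#' @param records data.frame with columns `gene_id`, `rna_log2fc`,
#'   `rna_padj`, `meth_diff_log2fc`, and `meth_lg_fdr` (or `meth_fdr` when
#'   `meth_sig = "fdr"`).
#' @param rna_alpha,meth_alpha Significance thresholds (default 0.05 each).
#' @param meth_sig `"lg_fdr"` if the methylation column is log10(FDR),
#'   `"fdr"` if it is a plain FDR.
#' @return List with `records` (input plus `group` and `reason`) and
#'   `counts` (named vector over the four groups and Excluded).
#' @export
classify_quadrants <- function(records, rna_alpha = 0.05, meth_alpha = 0.05,
                               meth_sig = c("lg_fdr", "fdr")) {
  meth_sig <- match.arg(meth_sig)
  lg <- if (meth_sig == "lg_fdr") records$meth_lg_fdr
        else log10(records$meth_fdr)
  n <- nrow(records)
  group <- rep("Excluded", n)
  reason <- rep("", n)
  have <- complete.cases(records$rna_log2fc, records$rna_padj,
                         records$meth_diff_log2fc, lg)
  reason[!have] <- "missing_statistic"
  sig <- have & records$rna_padj <= rna_alpha & lg <= log10(meth_alpha)
  reason[have & !sig] <- "not_significant"
  zero <- sig & (records$meth_diff_log2fc == 0 | records$rna_log2fc == 0)
  reason[zero] <- "zero_effect"
  cls <- sig & !zero
  hyper <- records$meth_diff_log2fc > 0
  up <- records$rna_log2fc > 0
  group[cls & hyper & up] <- "Hyper-up"
  group[cls & hyper & !up] <- "Hyper-down"
  group[cls & !hyper & up] <- "Hypo-up"
  group[cls & !hyper & !up] <- "Hypo-down"
  records$group <- group
  records$reason <- reason
  lv <- c("Hyper-up", "Hyper-down", "Hypo-up", "Hypo-down", "Excluded")
  counts <- setNames(vapply(lv, function(g) sum(group == g), 0L), lv)
  list(records = records, counts = counts)
}

#' Pearson correlation of methylation change with expression change
#'
#' @param records As for [classify_quadrants()].
#' @param subset `"significant"` (both layers significant, the quadrant
#'   population) or `"nonsignificant"` (all remaining complete records).
#' @param rna_alpha,meth_alpha,meth_sig Thresholds as in
#'   [classify_quadrants()].
#' @return List with `r`, `p` (two-sided, t distribution with n-2 df; `NA`
#'   when n < 3) and `n`.
#' @export
meth_expr_correlation <- function(records,
                                  subset = c("significant", "nonsignificant"),
                                  rna_alpha = 0.05, meth_alpha = 0.05,
                                  meth_sig = c("lg_fdr", "fdr")) {
  subset <- match.arg(subset)
  meth_sig <- match.arg(meth_sig)
  lg <- if (meth_sig == "lg_fdr") records$meth_lg_fdr
        else log10(records$meth_fdr)
  have <- complete.cases(records$rna_log2fc, records$rna_padj,
                         records$meth_diff_log2fc, lg)
  sig <- have & records$rna_padj <= rna_alpha & lg <= log10(meth_alpha)
  keep <- if (subset == "significant") sig else have & !sig
  x <- records$meth_diff_log2fc[keep]
  y <- records$rna_log2fc[keep]
  n <- length(x)
  if (n < 3)
    return(list(r = if (n == 2) cor(x, y) else NA_real_, p = NA_real_, n = n))
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = n)
}

#' Kolmogorov-Smirnov comparison of expression change by methylation status
#'
#' Two-sample KS test of the log2 fold-change distributions of methylated
#' versus unmethylated genes; D is the sup-distance between the two ECDFs
#' and the p-value is the asymptotic two-sample approximation (treated as
#' approximate below ~10 observations per group).
#'
#' @param log2fc Numeric vector of expression log2 fold changes.
#' @param methylated Logical vector, same length: does the gene carry a
#'   peak?
#' @return List with `D`, `p`, `n_methylated`, `n_unmethylated`.
#' @export
ks_by_methylation <- function(log2fc, methylated) {
  stopifnot(length(log2fc) == length(methylated))
  x <- log2fc[methylated]; y <- log2fc[!methylated]
  if (!length(x) || !length(y))
    stop("both methylated and unmethylated groups must be non-empty")
  kt <- suppressWarnings(ks.test(x, y, exact = FALSE))
  list(D = unname(kt$statistic), p = kt$p.value,
       n_methylated = length(x), n_unmethylated = length(y))
}

TABLE1_HEADER <- c("Ensembl_ID", "Gene_Name", "Expression", "log2FoldChange",
                   "meanfpkm", "padj")
TABLE2_HEADER <- c("Chr", "Peak_start", "Peak_end", "Strand", "Ensembl_ID",
                   "Gene_Name", "RNA-seq_log2FoldChange", "RNA-seq_padj",
                   "MeRIP-seq_diff.log2.fc", "MeRIP-seq_diff.lg.fdr",
                   "Gene_Type", "Group")

#' Load a packaged worked-example table
#'
#' Reads the transcribed differential-expression (table 1) or
#' differential-peak (table 2) worked example, checks the header verbatim,
#' and (for table 2) returns integration-ready records whose methylation
#' significance is flagged as log10(FDR).
#'
#' @param path Path to the fixture TSV (see [lncm6a_example()]).
#' @return The typed table; for table 2 with the standardized record
#'   columns (`gene_id`, `rna_log2fc`, `rna_padj`, `meth_diff_log2fc`,
#'   `meth_lg_fdr`) appended and attribute `meth_sig = "lg_fdr"`.
#' @export
load_worked_example <- function(path) {
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  hdr <- names(tab)
  if (identical(hdr, TABLE1_HEADER)) {
    attr(tab, "table") <- "de"
    return(tab)
  }
  if (identical(hdr, TABLE2_HEADER)) {
    tab$gene_id <- tab$Ensembl_ID
    tab$rna_log2fc <- tab[["RNA-seq_log2FoldChange"]]
    tab$rna_padj <- tab[["RNA-seq_padj"]]
    tab$meth_diff_log2fc <- tab[["MeRIP-seq_diff.log2.fc"]]
    tab$meth_lg_fdr <- tab[["MeRIP-seq_diff.lg.fdr"]]
    attr(tab, "table") <- "diff_peaks"
    attr(tab, "meth_sig") <- "lg_fdr"
    return(tab)
  }
  stop("unrecognized worked-example header.\n  expected: ",
       paste(TABLE1_HEADER, collapse = ", "), "\n        or: ",
       paste(TABLE2_HEADER, collapse = ", "), "\n     found: ",
       paste(hdr, collapse = ", "))
}
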