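#' Gene-level count container
#'
#' @param counts Non-negative integer matrix, genes x samples, with gene ids
#'   as rownames.
#' @param condition Character vector (or factor) of condition labels, one
#'   per column, e.g. `"GM"`/`"D4"`.
#' @param lib_size Optional per-sample library sizes; defaults to column
#'   sums.
#' @return List of class `gene_counts`.
#' @export
gene_counts <- function(counts, condition, lib_size = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) stop("counts must have gene ids as rownames")
  condition <- as.character(condition)
  stopifnot(length(condition) == ncol(counts), all(counts >= 0))
  if (length(unique(condition)) < 1L) stop("need >= 1 condition")
  if (is.null(lib_size)) lib_size <- colSums(counts)
  stopifnot(length(lib_size) == ncol(counts), all(lib_size > 0))
  structure(list(counts = counts, condition = condition,
                 lib_size = unname(lib_size)),
            class = "gene_counts")
}

#' RPKM normalization
#'
#' RPKM = count * 1e9 / (library_size * exonic_length), with the exonic
#' length taken as the spliced length of each gene's canonical transcript.
#'
#' @param gc A [gene_counts()].
#' @param ann A [genome_annotation()] supplying exonic lengths.
#' @return List with `rpkm` (matrix) and `mean_rpkm` (named vector, the
#'   arithmetic mean over all samples).
#' @export
rpkm <- function(gc, ann) {
  canon <- canonical_transcripts(ann)
  len <- setNames(canon$spliced_length, canon$gene_id)
  missing <- setdiff(rownames(gc$counts), names(len))
  if (length(missing))
    stop("genes missing from annotation: ", paste(missing, collapse = ", "))
  l <- len[rownames(gc$counts)]
  m <- sweep(gc$counts, 2, gc$lib_size, "/") * 1e9 / l
  list(rpkm = m, mean_rpkm = rowMeans(m))
}

#' Median-of-ratios size factors
#'
#' For each sample, the median over genes (with positive counts in every
#' sample) of the ratio of the gene's count to its geometric mean across
#' samples. A matrix with identical columns gets factors of 1.
#'
#' @param gc A [gene_counts()] or a count matrix.
#' @return Positive numeric vector, one factor per sample.
#' @export
size_factors <- function(gc) {
  counts <- if (inherits(gc, "gene_counts")) gc$counts else as.matrix(gc)
  if (ncol(counts) == 1L) return(1)
  loggeo <- rowMeans(log(counts))
  ok <- is.finite(loggeo)
  if (!any(ok))
    stop("no gene has positive counts in every sample; consider total-count ",
         "normalization (lib_size override)")
  apply(counts, 2, function(x) exp(median(log(x[ok]) - loggeo[ok])))
}

#' Differential expression: moderated negative-binomial Wald test
#'
#' A deliberately simple two-condition test operating on median-of-ratios
#' normalized counts: `log2FoldChange = log2((mean_D4 + 0.5)/(mean_GM + 0.5))`,
#' a per-gene method-of-moments dispersion estimate squeezed toward the
#' common (median) dispersion with `prior_df` degrees of freedom, a
#' delta-method standard error, a two-sided normal p-value, and
#' Benjamini-Hochberg adjustment across all tested genes. Genes below
#' `rpkm_floor` mean RPKM are excluded before adjustment.
#'
#' @param gc A [gene_counts()] with >= 2 samples in each of exactly two
#'   conditions.
#' @param ann Optional [genome_annotation()]; needed for `meanRPKM` and any
#'   non-zero `rpkm_floor`.
#' @param ref,alt Condition labels; the fold change is `alt` versus `ref`.
#' @param rpkm_floor Minimum mean RPKM for a gene to be tested (default 0 =
#'   no filter).
#' @param prior_df Prior degrees of freedom for the dispersion squeeze.
#' @return data.frame with columns `gene_id`, `log2FoldChange`, `pvalue`,
#'   `padj`, `meanRPKM`, `direction` (`Up`/`Down`/`NS`).
#' @export
differential_expression <- function(gc, ann = NULL, ref = "GM", alt = "D4",
                                    rpkm_floor = 0, prior_df = 10) {
  cond <- gc$condition
  for (cc in c(ref, alt)) {
    if (!any(cond == cc)) stop("condition ", cc, " absent from the matrix")
    if (sum(cond == cc) < 2L)
      stop("need >= 2 samples in condition ", cc, " for dispersion estimation")
  }
  mean_rpkm <- rep(NA_real_, nrow(gc$counts))
  if (!is.null(ann)) mean_rpkm <- rpkm(gc, ann)$mean_rpkm
  keep <- if (rpkm_floor > 0) {
    if (is.null(ann)) stop("rpkm_floor requires an annotation")
    mean_rpkm >= rpkm_floor
  } else rep(TRUE, nrow(gc$counts))

  counts <- gc$counts[keep, , drop = FALSE]
  sf <- size_factors(counts)
  nc <- sweep(counts, 2, sf, "/")
  i1 <- cond == ref; i2 <- cond == alt
  n1 <- sum(i1); n2 <- sum(i2)
  m1 <- rowMeans(nc[, i1, drop = FALSE]); m2 <- rowMeans(nc[, i2, drop = FALSE])
  lfc <- log2((m2 + 0.5) / (m1 + 0.5))

  v1 <- apply(nc[, i1, drop = FALSE], 1, var)
  v2 <- apply(nc[, i2, drop = FALSE], 1, var)
  vpool <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  mbar <- (m1 + m2) / 2
  alpha <- pmax((vpool - mbar) / mbar^2, 1e-8)
  df <- n1 + n2 - 2
  a0 <- median(alpha[mbar > 5])
  if (is.na(a0)) a0 <- median(alpha)
  alpha <- pmax((prior_df * a0 + df * alpha) / (prior_df + df), 1e-8)

  V1 <- (m1 + alpha * m1^2) / n1
  V2 <- (m2 + alpha * m2^2) / n2
  se <- sqrt((V1 / (m1 + 0.5)^2 + V2 / (m2 + 0.5)^2) / log(2)^2)
  p <- 2 * pnorm(-abs(lfc / se))
  padj <- p.adjust(p, "BH")
  direction <- rep("NS", length(p))
  direction[padj <= 0.05 & lfc > 0] <- "Up"
  direction[padj <= 0.05 & lfc < 0] <- "Down"

  res <- data.frame(gene_id = rownames(counts), log2FoldChange = lfc,
                    pvalue = p, padj = padj,
                    meanRPKM = unname(mean_rpkm[keep]),
                    direction = direction,
                    stringsAsFactors = FALSE, row.names = NULL)
  stage_log("differential_expression", "%d genes tested, %d Up, %d Down",
            nrow(res), sum(direction == "Up"), sum(direction == "Down"))
  res
}

#' Partition differential-expression results by gene biotype
#'
#' lncRNAs are `lincRNA`, `antisense` and `processed_transcript` (plus any
#' `extra_lnc_types`); mRNAs are `protein_coding`; genes of other types are
#' dropped with a logged count.
#'
#' @param results A [differential_expression()] table.
#' @param ann A [genome_annotation()].
#' @param extra_lnc_types Additional gene_type values to treat as lncRNA.
#' @return List with elements `lnc`, `mrna` (subsets of `results`) and
#'   `n_dropped`.
#' @export
split_by_biotype <- function(results, ann,
                             extra_lnc_types = character(0)) {
  lnc_types <- c("lincRNA", "antisense", "processed_transcript",
                 extra_lnc_types)
  type <- setNames(ann$genes$gene_type, ann$genes$gene_id)[results$gene_id]
  lnc <- results[!is.na(type) & type %in% lnc_types, , drop = FALSE]
  mrna <- results[!is.na(type) & type == "protein_coding", , drop = FALSE]
  n_dropped <- nrow(results) - nrow(lnc) - nrow(mrna)
  if (n_dropped)
    stage_log("split_by_biotype", "%d genes of other/unknown type dropped",
              n_dropped)
  list(lnc = lnc, mrna = mrna, n_dropped = n_dropped)
}

#' Count genes expressed in at least one condition
#'
#' A gene counts as expressed when its mean raw count is >= `min_mean` in at
#' least one condition.
#'
#' @param gc A [gene_counts()].
#' @param min_mean Expression floor on the per-condition mean raw count.
#' @return Logical vector, one element per gene.
#' @export
expressed_genes <- function(gc, min_mean = 1) {
  conds <- unique(gc$condition)
  means <- sapply(conds, function(cc)
    rowMeans(gc$counts[, gc$condition == cc, drop = FALSE]))
  apply(as.matrix(means) >= min_mean, 1, any)
}

#' Write a differential-expression table in the worked-example layout
#'
#' Columns: `Ensembl_ID`, `Gene_Name`, `Expression`, `log2FoldChange`,
#' `meanfpkm`, `padj`.
#'
#' @param results A [differential_expression()] table.
#' @param ann A [genome_annotation()] (for gene names).
#' @param path Output TSV path.
#' @return The written data.frame, invisibly.
#' @export
write_de_table <- function(results, ann, path) {
  nm <- setNames(ann$genes$gene_name, ann$genes$gene_id)
  out <- data.frame(Ensembl_ID = results$gene_id,
                    Gene_Name = unname(nm[results$gene_id]),
                    Expression = results$direction,
                    log2FoldChange = results$log2FoldChange,
                    meanfpkm = results$meanRPKM,
                    padj = results$padj,
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}
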