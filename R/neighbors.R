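#' Nearest protein-coding neighbors of a lncRNA
#'
#' Finds up to `k` protein-coding genes per side of the lncRNA on the same
#' chromosome. Upstream/downstream are in chromosome orientation (smaller /
#' larger coordinates), not lncRNA strand; distance is the gap between
#' closest gene-span edges (0 when overlapping, in which case the side is
#' taken from the coding gene's start coordinate). Ties in distance break
#' toward the smaller start coordinate.
#'
#' @param lnc_id Gene id of the lncRNA.
#' @param ann A [genome_annotation()].
#' @param k Neighbors per side (default 5).
#' @param strand_aware If `TRUE`, upstream/downstream follow the lncRNA's
#'   strand instead of chromosome orientation.
#' @return data.frame: `lnc_gene_id`, `coding_gene_id`, `side`, `rank`,
#'   `distance`.
#' @export
find_neighbors <- function(lnc_id, ann, k = 5L, strand_aware = FALSE) {
  g <- ann$genes
  li <- g[g$gene_id == lnc_id, ]
  if (!nrow(li)) stop("gene ", lnc_id, " not in annotation")
  cand <- g[g$gene_type == "protein_coding" & g$chrom == li$chrom &
            g$gene_id != lnc_id, , drop = FALSE]
  if (!nrow(cand))
    return(data.frame(lnc_gene_id = character(), coding_gene_id = character(),
                      side = character(), rank = integer(),
                      distance = integer(), stringsAsFactors = FALSE))
  dist <- pmax(0L, pmax(li$start - cand$end, cand$start - li$end))
  side <- ifelse(dist == 0,
                 ifelse(cand$start < li$start, "upstream", "downstream"),
                 ifelse(cand$end <= li$start, "upstream", "downstream"))
  if (strand_aware && li$strand == "-")
    side <- ifelse(side == "upstream", "downstream", "upstream")
  out <- list()
  for (s in c("upstream", "downstream")) {
    i <- which(side == s)
    i <- i[order(dist[i], cand$start[i])]
    i <- head(i, k)
    if (!length(i)) next
    out[[s]] <- data.frame(lnc_gene_id = lnc_id,
                           coding_gene_id = cand$gene_id[i],
                           side = s, rank = seq_along(i),
                           distance = as.integer(dist[i]),
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Neighbors for a set of lncRNAs
#'
#' @param lnc_ids Character vector of lncRNA gene ids.
#' @inheritParams find_neighbors
#' @return Row-bound [find_neighbors()] tables.
#' @export
find_neighbors_all <- function(lnc_ids, ann, k = 5L, strand_aware = FALSE) {
  do.call(rbind, lapply(lnc_ids, find_neighbors, ann = ann, k = k,
                        strand_aware = strand_aware))
}

#' Filter neighbor pairs by dual significance and classify concordance
#'
#' Keeps pairs whose coding gene is significantly differentially expressed,
#' whose lncRNA is significantly differentially expressed, and whose lncRNA
#' carries at least one differential m6A peak at `FDR <= alpha`. Surviving
#' pairs are `positive` when the two expression changes share a sign,
#' `retrograde` when they oppose.
#'
#' @param pairs A [find_neighbors_all()] table.
#' @param de A [differential_expression()] table covering both gene classes.
#' @param diff_peaks A [differential_peaks()] table.
#' @param alpha Significance threshold for all three filters.
#' @return Filtered pairs with `lnc_log2fc`, `coding_log2fc`, `concordance`
#'   columns; attrition is logged.
#' @export
pair_filter <- function(pairs, de, diff_peaks, alpha = 0.05) {
  if (!nrow(pairs)) return(cbind(pairs, lnc_log2fc = numeric(0),
                                 coding_log2fc = numeric(0),
                                 concordance = character(0)))
  idx <- match(pairs$lnc_gene_id, de$gene_id)
  jdx <- match(pairs$coding_gene_id, de$gene_id)
  lnc_sig <- !is.na(idx) & de$padj[idx] <= alpha
  cod_sig <- !is.na(jdx) & de$padj[jdx] <= alpha
  meth_ok <- if (nrow(diff_peaks)) {
    sig_genes <- unique(diff_peaks$gene_id[diff_peaks$diff_fdr <= alpha])
    pairs$lnc_gene_id %in% sig_genes
  } else rep(FALSE, nrow(pairs))
  keep <- lnc_sig & cod_sig & meth_ok
  out <- pairs[keep, , drop = FALSE]
  out$lnc_log2fc <- de$log2FoldChange[idx[keep]]
  out$coding_log2fc <- de$log2FoldChange[jdx[keep]]
  out$concordance <- ifelse(sign(out$lnc_log2fc) == sign(out$coding_log2fc),
                            "positive", "retrograde")
  stage_log("pair_filter", "%d/%d pairs retained (%d positive, %d retrograde)",
            nrow(out), nrow(pairs), sum(out$concordance == "positive"),
            sum(out$concordance == "retrograde"))
  rownames(out) <- NULL
  out
}

#' Read a GMT gene-set collection
#'
#' @param path GMT file (set name, description, members per line).
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  sets <- fgsea::gmtPathways(path)
  if (any(lengths(sets) == 0)) stop("GMT contains an empty set")
  sets
}

#' Hypergeometric over-representation analysis
#'
#' For each set, the upper-tail hypergeometric probability of observing at
#' least the seen overlap between the query and the set, given the
#' universe; BH-adjusted across sets.
#'
#' @param query Character vector of query gene ids (must lie in `universe`).
#' @param sets Named list of gene sets (members must lie in `universe`).
#' @param universe Character vector defining the population.
#' @return data.frame sorted by p: `set`, `set_size`, `overlap`, `fold`,
#'   `pvalue`, `padj`.
#' @export
ora <- function(query, sets, universe) {
  query <- unique(query); universe <- unique(universe)
  out_q <- setdiff(query, universe)
  if (length(out_q))
    stop("query genes outside the universe: ", paste(out_q, collapse = ", "))
  bad <- names(sets)[vapply(sets, function(s) length(setdiff(s, universe)) > 0,
                            logical(1))]
  if (length(bad))
    stop("sets with members outside the universe: ", paste(bad, collapse = ", "))
  N <- length(universe); n <- length(query)
  res <- do.call(rbind, lapply(names(sets), function(nm) {
    K <- length(unique(sets[[nm]]))
    ov <- length(intersect(query, sets[[nm]]))
    data.frame(set = nm, set_size = K, overlap = ov,
               fold = (ov / n) / (K / N),
               pvalue = phyper(ov - 1, K, N - K, n, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  }))
  res$padj <- p.adjust(res$pvalue, "BH")
  res <- res[order(res$pvalue, res$set), ]
  rownames(res) <- NULL
  res
}
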