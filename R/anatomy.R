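#' Peak distribution over exon elements
#'
#' Classifies each peak to the first, internal or last exon of its host
#' gene's canonical transcript (midpoint rule, transcript orientation) and
#' compares the share of peaks per element with the share of exonic length
#' those elements contribute: `relative_enrichment = peak_share /
#' length_share`, so peaks falling proportionally to element length give
#' enrichment 1 everywhere. Peaks on single-exon hosts are excluded from the
#' three-way tally and counted separately.
#'
#' @param peaks A [call_peaks()]-style table (`gene_id`, `start`, `end`).
#' @param ann A [genome_annotation()].
#' @return List of class `element_summary`: `counts`, `proportions`,
#'   `length_share`, `relative_enrichment` (each over the three elements),
#'   `n_single_exon`, `n_unclassified`.
#' @export
element_summary <- function(peaks, ann) {
  canon <- canonical_transcripts(ann)
  rownames(canon) <- canon$gene_id
  elements <- c("first_exon", "internal_exon", "last_exon")
  cls <- character(nrow(peaks))
  n_single <- 0L
  for (i in seq_len(nrow(peaks))) {
    tx <- canon[peaks$gene_id[i], "transcript_id"]
    ex <- tx_exons(ann, tx)
    if (nrow(ex) < 2L) { cls[i] <- "single"; n_single <- n_single + 1L; next }
    cls[i] <- exon_element(ann, tx, peaks$start[i], peaks$end[i])
  }
  counts <- setNames(vapply(elements, function(e) sum(cls == e), 0L), elements)
  n_unclassified <- sum(cls == "none")

  # exonic length share, over the multi-exon canonical transcripts hosting
  # classified peaks (each host counted once)
  hosts <- unique(peaks$gene_id[cls %in% elements])
  len <- setNames(numeric(3), elements)
  for (gid in hosts) {
    ex <- tx_exons(ann, canon[gid, "transcript_id"])
    w <- ex$end - ex$start
    if (ex$strand[1] == "-") w <- rev(w)
    len["first_exon"] <- len["first_exon"] + w[1]
    len["last_exon"] <- len["last_exon"] + w[length(w)]
    if (length(w) > 2) len["internal_exon"] <- len["internal_exon"] + sum(w[-c(1, length(w))])
  }
  prop <- counts / max(sum(counts), 1L)
  lshare <- len / max(sum(len), 1)
  structure(list(counts = counts, proportions = prop, length_share = lshare,
                 relative_enrichment = ifelse(lshare > 0, prop / lshare, NA),
                 n_single_exon = n_single, n_unclassified = n_unclassified),
            class = "element_summary")
}

#' @export
print.element_summary <- function(x, ...) {
  df <- data.frame(counts = x$counts, proportion = round(x$proportions, 4),
                   length_share = round(x$length_share, 4),
                   rel_enrichment = round(x$relative_enrichment, 3))
  print(df)
  cat(sprintf("(%d single-exon peaks tallied separately, %d unclassified)\n",
              x$n_single_exon, x$n_unclassified))
  invisible(x)
}

#' Transcript-scaled metagene profile of peak summits
#'
#' Each peak contributes its summit once; the summit's transcript coordinate
#' is rescaled to `[0, 1)` over the host transcript's spliced length and
#' binned. Densities sum to 1.
#'
#' @param peaks A [call_peaks()]-style table with a `summit` column.
#' @param ann A [genome_annotation()].
#' @param n_bins Number of bins (default 100).
#' @return data.frame with columns `bin` (1-based), `density`; attribute
#'   `n_skipped` counts summits not mappable to an exonic position.
#' @export
metagene <- function(peaks, ann, n_bins = 100L) {
  if (!nrow(peaks)) stop("empty peak list: no peaks to profile (empty-input)")
  canon <- canonical_transcripts(ann)
  rownames(canon) <- canon$gene_id
  bins <- integer(0)
  n_skipped <- 0L
  for (i in seq_len(nrow(peaks))) {
    tx <- canon[peaks$gene_id[i], "transcript_id"]
    tc <- genomic_to_transcript(ann, tx, peaks$summit[i])
    if (is.na(tc)) { n_skipped <- n_skipped + 1L; next }
    L <- canon[peaks$gene_id[i], "spliced_length"]
    bins <- c(bins, min(floor(n_bins * tc / L) + 1L, n_bins))
  }
  if (n_skipped) stage_log("metagene", "%d intronic summits skipped", n_skipped)
  tab <- tabulate(bins, nbins = n_bins)
  out <- data.frame(bin = seq_len(n_bins), density = tab / sum(tab))
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Peaks-per-lncRNA distribution
#'
#' Histogram and median of peak counts over methylated genes only (those
#' with at least one peak).
#'
#' @param peaks A peak table with a `gene_id` column.
#' @param gene_ids Optional restriction (e.g. lncRNA ids).
#' @return List: `histogram` (table of peak counts), `median`, `n_genes`.
#'   The median is `NA` when no gene is methylated.
#' @export
peaks_per_gene <- function(peaks, gene_ids = NULL) {
  ids <- peaks$gene_id
  if (!is.null(gene_ids)) ids <- ids[ids %in% gene_ids]
  if (!length(ids))
    return(list(histogram = table(integer(0)), median = NA_real_, n_genes = 0L))
  counts <- table(ids)
  list(histogram = table(as.integer(counts)),
       median = median(as.integer(counts)),
       n_genes = length(counts))
}

#' Extract peak (summit-flank) transcript sequences
#'
#' Returns the sense-strand (transcript) sequence of a window of
#' `2 * flank` nt centred on each peak summit, spliced if the window crosses
#' a junction.
#'
#' @param peaks A peak table with `gene_id` and `summit` columns.
#' @param ann A [genome_annotation()].
#' @param genome A [Biostrings::DNAStringSet].
#' @param flank Half-width of the extracted window (default 100 nt).
#' @return A [Biostrings::DNAStringSet] of peak sequences.
#' @export
peak_sequences <- function(peaks, ann, genome, flank = 100L) {
  canon <- canonical_transcripts(ann)
  rownames(canon) <- canon$gene_id
  seqs <- character(nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    gid <- peaks$gene_id[i]
    tx <- canon[gid, "transcript_id"]
    ex <- tx_exons(ann, tx)
    strand <- ex$strand[1]
    L <- canon[gid, "spliced_length"]
    tc <- g2t_exons(ex, strand, peaks$summit[i])
    if (is.na(tc)) next
    a <- max(0L, tc - flank); b <- min(L, tc + flank)
    pieces <- spliced_to_genomic(ex, strand, a, b)
    chunk <- Biostrings::DNAStringSet(vapply(seq_len(nrow(pieces)), function(j)
      as.character(Biostrings::subseq(genome[[ex$chrom[1]]],
                                      pieces$start[j] + 1L, pieces$end[j])),
      character(1)))
    s <- Biostrings::DNAString(paste(as.character(chunk), collapse = ""))
    if (strand == "-") s <- Biostrings::reverseComplement(s)
    seqs[i] <- as.character(s)
  }
  Biostrings::DNAStringSet(seqs[nzchar(seqs)])
}

#' Sample non-peak exonic background sequences
#'
#' Draws sense-strand windows of the same width as the peak extraction from
#' exonic positions at least one window away from any peak of the same gene;
#' the standard background for peak-versus-transcriptome motif comparisons.
#'
#' @param peaks Peak table (used to mask peak neighbourhoods).
#' @param ann A [genome_annotation()].
#' @param genome A [Biostrings::DNAStringSet].
#' @param n Number of background windows to draw.
#' @param width Window width (match `2 * flank` of [peak_sequences()]).
#' @param seed Integer seed for the draw.
#' @return A [Biostrings::DNAStringSet].
#' @export
nonpeak_background <- function(peaks, ann, genome, n = 500L, width = 200L,
                               seed = 1L) {
  set.seed(seed)
  canon <- canonical_transcripts(ann)
  canon <- canon[canon$spliced_length >= width, , drop = FALSE]
  rownames(canon) <- canon$gene_id
  out <- character(0)
  guard <- 0L
  while (length(out) < n && guard < 50L * n) {
    guard <- guard + 1L
    i <- sample.int(nrow(canon), 1L)
    gid <- canon$gene_id[i]
    L <- canon$spliced_length[i]
    a <- sample.int(L - width + 1L, 1L) - 1L
    pk <- peaks[peaks$gene_id == gid, , drop = FALSE]
    if (nrow(pk) && any(a < pk$s_end + width & a + width > pk$s_start - width))
      next
    ex <- tx_exons(ann, canon$transcript_id[i])
    pieces <- spliced_to_genomic(ex, ex$strand[1], a, a + width)
    s <- paste(vapply(seq_len(nrow(pieces)), function(j)
      as.character(Biostrings::subseq(genome[[ex$chrom[1]]],
                                      pieces$start[j] + 1L, pieces$end[j])),
      character(1)), collapse = "")
    s <- Biostrings::DNAString(s)
    if (ex$strand[1] == "-") s <- Biostrings::reverseComplement(s)
    out <- c(out, as.character(s))
  }
  Biostrings::DNAStringSet(out)
}
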