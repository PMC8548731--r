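#' Map genomic positions to transcript (spliced) coordinates
#'
#' Transcript coordinates count exonic nucleotides from the transcript's 5'
#' end: for a plus-strand transcript, the number of exonic bases preceding
#' the position; for a minus-strand transcript, `L - 1 - plus_value` where
#' `L` is the spliced length. Intronic or outside positions map to `NA`.
#'
#' @param ann A [genome_annotation()].
#' @param transcript_id Transcript whose coordinate system to use.
#' @param pos Integer vector of genomic positions (0-based).
#' @return Integer vector of transcript coordinates in `[0, L)`, `NA` for
#'   positions not exonic in this transcript.
#' @export
genomic_to_transcript <- function(ann, transcript_id, pos) {
  ex <- tx_exons(ann, transcript_id)
  if (!nrow(ex)) stop("transcript ", transcript_id, " has no exons")
  g2t_exons(ex, ex$strand[1], pos)
}

# vectorised core on a sorted exon table
g2t_exons <- function(ex, strand, pos) {
  widths <- ex$end - ex$start
  L <- sum(widths)
  cum <- cumsum(c(0L, widths[-length(widths)]))
  idx <- findInterval(pos, ex$start)
  out <- rep(NA_integer_, length(pos))
  ok <- idx >= 1L & idx <= nrow(ex)
  inside <- ok
  inside[ok] <- pos[ok] < ex$end[idx[ok]]
  plus <- cum[idx[inside]] + (pos[inside] - ex$start[idx[inside]])
  out[inside] <- if (strand == "-") L - 1L - plus else plus
  as.integer(out)
}

# inverse: transcript coordinate -> genomic position (single values, vectorised)
t2g_exons <- function(ex, strand, tpos) {
  widths <- ex$end - ex$start
  L <- sum(widths)
  stopifnot(all(tpos >= 0 & tpos < L))
  p <- if (strand == "-") L - 1L - tpos else tpos
  cum <- cumsum(c(0L, widths[-length(widths)]))
  idx <- findInterval(p, cum)
  as.integer(ex$start[idx] + (p - cum[idx]))
}

#' Map a spliced interval to its genomic pieces
#'
#' A half-open interval `[a, b)` in transcript coordinates is projected onto
#' the genome; it may split across exon junctions.
#'
#' @param ex Sorted exon table of one transcript (`start`, `end`).
#' @param strand `"+"` or `"-"`.
#' @param a,b Spliced interval bounds, 0-based half-open.
#' @return data.frame with columns `start`, `end` (genomic, 0-based
#'   half-open), in genomic order.
#' @keywords internal
spliced_to_genomic <- function(ex, strand, a, b) {
  widths <- ex$end - ex$start
  L <- sum(widths)
  stopifnot(a >= 0, b <= L, a < b)
  if (strand == "-") { tmp <- a; a <- L - b; b <- L - tmp }
  cum <- cumsum(c(0L, widths[-length(widths)]))
  pieces <- lapply(seq_len(nrow(ex)), function(i) {
    lo <- max(a, cum[i]); hi <- min(b, cum[i] + widths[i])
    if (lo >= hi) return(NULL)
    data.frame(start = ex$start[i] + (lo - cum[i]),
               end = ex$start[i] + (hi - cum[i]))
  })
  do.call(rbind, pieces)
}

#' Classify an interval against a transcript's exon elements
#'
#' The classification uses the interval midpoint. "First" and "last" exon
#' are in transcript orientation, so the genomically last exon of a
#' minus-strand transcript is its first exon. Transcripts with fewer than
#' two exons are not classified here (callers tally them separately).
#'
#' @param ann A [genome_annotation()].
#' @param transcript_id Host transcript.
#' @param start,end Genomic interval, 0-based half-open.
#' @return One of `"first_exon"`, `"internal_exon"`, `"last_exon"`, `"none"`.
#' @export
exon_element <- function(ann, transcript_id, start, end) {
  ex <- tx_exons(ann, transcript_id)
  if (nrow(ex) < 2L)
    stop("exon_element requires a transcript with >= 2 exons")
  mid <- (start + end) %/% 2
  idx <- findInterval(mid, ex$start)
  if (idx < 1L || mid >= ex$end[idx]) return("none")
  if (ex$strand[1] == "-") idx <- nrow(ex) + 1L - idx
  if (idx == 1L) "first_exon"
  else if (idx == nrow(ex)) "last_exon"
  else "internal_exon"
}
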