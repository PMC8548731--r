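#' Tile exonic (spliced) windows over canonical transcripts
#'
#' Windows of fixed width and step are laid over the spliced coordinates of
#' each gene's canonical transcript, mirroring counting on fragmented RNA:
#' a window spanning an exon junction is one counting unit whose genomic
#' footprint splits across the junction. Genes whose spliced length is
#' shorter than one window are skipped (and counted in the log line).
#'
#' @param ann A [genome_annotation()].
#' @param width Window width in nt (default 100, the fragment size of the
#'   assay being emulated).
#' @param step Step between window starts (default `width / 2`).
#' @param gene_ids Optional subset of genes to tile (default: all).
#' @return data.frame of class `window_tiling`: `window_id`, `gene_id`,
#'   `transcript_id`, `chrom`, `strand`, `s_start`, `s_end` (spliced,
#'   half-open), `g_start`, `g_end` (genomic footprint bounds).
#' @export
tile_windows <- function(ann, width = 100L, step = width %/% 2L,
                         gene_ids = NULL) {
  width <- as.integer(width); step <- as.integer(step)
  stopifnot(width >= 2L, step >= 1L)
  canon <- canonical_transcripts(ann)
  if (!is.null(gene_ids)) canon <- canon[canon$gene_id %in% gene_ids, ]
  skipped <- sum(canon$spliced_length < width)
  canon <- canon[canon$spliced_length >= width, , drop = FALSE]
  out <- vector("list", nrow(canon))
  for (i in seq_len(nrow(canon))) {
    tx <- canon$transcript_id[i]
    L <- canon$spliced_length[i]
    ex <- tx_exons(ann, tx)
    strand <- ex$strand[1]
    s_start <- seq.int(0L, L - width, by = step)
    g <- t(vapply(s_start, function(a) {
      p <- spliced_to_genomic(ex, strand, a, a + width)
      c(min(p$start), max(p$end))
    }, integer(2)))
    out[[i]] <- data.frame(gene_id = canon$gene_id[i], transcript_id = tx,
                           chrom = ex$chrom[1], strand = strand,
                           s_start = s_start, s_end = s_start + width,
                           g_start = g[, 1], g_end = g[, 2],
                           stringsAsFactors = FALSE)
  }
  win <- do.call(rbind, out)
  if (is.null(win)) win <- data.frame(gene_id = character(), transcript_id = character(),
                                      chrom = character(), strand = character(),
                                      s_start = integer(), s_end = integer(),
                                      g_start = integer(), g_end = integer())
  win <- cbind(window_id = sprintf("W%06d", seq_len(nrow(win))), win,
               stringsAsFactors = FALSE)
  attr(win, "width") <- width
  attr(win, "step") <- step
  attr(win, "annotation") <- ann
  if (skipped) stage_log("tile_windows", "%d genes shorter than one window skipped", skipped)
  class(win) <- c("window_tiling", "data.frame")
  win
}

#' Window count matrix container
#'
#' @param windows A [tile_windows()] table.
#' @param counts Integer matrix, rows matching `windows`, one column per
#'   library.
#' @param libs data.frame with columns `lib_id`, `condition`, `assay`
#'   (`"ip"` or `"input"`), `replicate`; `lib_id` must match the columns of
#'   `counts`.
#' @return List of class `window_counts`.
#' @export
window_counts <- function(windows, counts, libs) {
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) == nrow(windows),
            identical(colnames(counts), libs$lib_id),
            all(libs$assay %in% c("ip", "input")),
            all(counts >= 0))
  # IP and input libraries must pair one-to-one within a condition
  for (cond in unique(libs$condition)) {
    sub <- libs[libs$condition == cond, ]
    if (sum(sub$assay == "ip") != sum(sub$assay == "input"))
      stop("condition ", cond, ": IP and input libraries do not pair one-to-one")
  }
  structure(list(windows = windows, counts = counts, libs = libs),
            class = "window_counts")
}

#' @export
print.window_counts <- function(x, ...) {
  cat(sprintf("window_counts: %d windows x %d libraries (%s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(unique(x$libs$condition), collapse = ", ")))
  invisible(x)
}
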