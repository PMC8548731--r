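#' Count IUPAC motif matches on the given strand
#'
#' Scans each sequence (RNA-style: no reverse-complement matching) for an
#' IUPAC pattern such as `DRACH` (D = A/G/U, R = A/G, H = A/C/U). Input may
#' use U or T; U is converted to T before scanning.
#'
#' @param seqs Character vector or [Biostrings::DNAStringSet] over
#'   A/C/G/T/U.
#' @param pattern IUPAC string (default `"DRACH"`).
#' @return Integer vector of match counts per sequence.
#' @export
scan_motif <- function(seqs, pattern = "DRACH") {
  seqs <- as_dna(seqs)
  pattern <- chartr("U", "T", toupper(pattern))
  Biostrings::vcountPattern(pattern, seqs, fixed = FALSE)
}

as_dna <- function(seqs) {
  if (is(seqs, "DNAStringSet")) return(seqs)
  seqs <- toupper(as.character(seqs))
  bad <- grepl("[^ACGTU]", seqs)
  if (any(bad))
    stop("sequence ", which(bad)[1], " contains letters outside A/C/G/T/U")
  Biostrings::DNAStringSet(chartr("U", "T", seqs))
}

#' Dinucleotide-preserving sequence shuffle
#'
#' Altschul-Erikson shuffle: returns sequences with exactly the same
#' dinucleotide counts as the input, in random order. Used as the default
#' motif background.
#'
#' @param seq A single sequence (character).
#' @param n Number of shuffles.
#' @return Character vector of `n` shuffled sequences.
#' @export
dinuc_shuffle <- function(seq, n = 10L) {
  ch <- strsplit(toupper(chartr("U", "T", seq)), "")[[1]]
  len <- length(ch)
  if (len < 3L) return(rep(seq, n))
  verts <- unique(ch)
  last <- ch[len]
  edges0 <- split(ch[-1], factor(ch[-len], levels = verts))
  vapply(seq_len(n), function(k) {
    repeat {
      fin <- vapply(verts, function(v) {
        e <- edges0[[v]]
        if (v == last || !length(e)) NA_character_ else sample(e, 1L)
      }, character(1))
      names(fin) <- verts
      ok <- TRUE
      for (v in verts) {          # every vertex must reach the terminal one
        if (v == last || is.na(fin[[v]])) next
        seen <- character(0); cur <- v
        while (cur != last) {
          if (cur %in% seen || is.na(fin[[cur]])) { ok <- FALSE; break }
          seen <- c(seen, cur); cur <- fin[[cur]]
        }
        if (!ok) break
      }
      if (ok) break
    }
    edges <- edges0
    for (v in verts) {
      e <- edges[[v]]
      if (!length(e)) next
      if (!is.na(fin[[v]])) e <- e[-match(fin[[v]], e)]
      e <- if (length(e)) sample(e) else character(0)
      if (!is.na(fin[[v]])) e <- c(e, fin[[v]])
      edges[[v]] <- e
    }
    out <- character(len); out[1] <- ch[1]
    ptr <- setNames(rep(1L, length(verts)), verts)
    for (i in 2:len) {
      v <- out[i - 1L]
      out[i] <- edges[[v]][ptr[[v]]]
      ptr[[v]] <- ptr[[v]] + 1L
    }
    paste(out, collapse = "")
  }, character(1))
}

#' Motif enrichment of peak sequences against a background
#'
#' In pattern mode, counts IUPAC matches per position in foreground and
#' background and reports the rate ratio with a one-sided binomial p-value.
#' In de-novo mode, ranks exact k-mers (k in `kmer_lengths`) by
#' over-representation, BH-adjusted across all tested k-mers. The default
#' background is a set of seeded dinucleotide-preserving shuffles of the
#' foreground; pass explicit `bg_seqs` (e.g. [nonpeak_background()]) for a
#' peak-versus-transcriptome comparison.
#'
#' @param fg_seqs Foreground sequences (character or DNAStringSet).
#' @param bg_seqs Optional background sequences.
#' @param pattern IUPAC pattern for pattern mode (default `"DRACH"`); set to
#'   `NULL` for de-novo mode.
#' @param kmer_lengths k values for de-novo mode (default `5:8`).
#' @param n_shuffle Shuffles per foreground sequence when `bg_seqs` is
#'   absent.
#' @param seed Seed for the shuffle background.
#' @param top In de-novo mode, number of top k-mers to return per k.
#' @return data.frame with columns `pattern`, `fg_hits`, `fg_n`, `bg_hits`,
#'   `bg_n`, `fold`, `pvalue`, `padj`.
#' @export
motif_enrichment <- function(fg_seqs, bg_seqs = NULL, pattern = "DRACH",
                             kmer_lengths = 5:8, n_shuffle = 10L, seed = 1L,
                             top = 10L) {
  fg <- as_dna(fg_seqs)
  if (is.null(bg_seqs)) {
    set.seed(seed)
    bg <- as_dna(unlist(lapply(as.character(fg), dinuc_shuffle, n = n_shuffle)))
  } else bg <- as_dna(bg_seqs)

  if (!is.null(pattern)) {
    k <- nchar(pattern)
    fg_hits <- sum(scan_motif(fg, pattern))
    bg_hits <- sum(scan_motif(bg, pattern))
    fg_n <- sum(pmax(Biostrings::width(fg) - k + 1L, 0L))
    bg_n <- sum(pmax(Biostrings::width(bg) - k + 1L, 0L))
    bg_rate <- bg_hits / bg_n
    res <- data.frame(pattern = pattern, fg_hits = fg_hits, fg_n = fg_n,
                      bg_hits = bg_hits, bg_n = bg_n,
                      fold = (fg_hits / fg_n) / bg_rate,
                      pvalue = pbinom(fg_hits - 1, fg_n, bg_rate,
                                      lower.tail = FALSE),
                      stringsAsFactors = FALSE)
    res$padj <- res$pvalue
    return(res)
  }

  out <- list()
  for (k in kmer_lengths) {
    fg_tab <- colSums(Biostrings::oligonucleotideFrequency(fg, width = k))
    bg_tab <- colSums(Biostrings::oligonucleotideFrequency(bg, width = k))
    fg_n <- sum(fg_tab); bg_n <- sum(bg_tab)
    keep <- fg_tab > 0
    kmers <- names(fg_tab)[keep]
    bg_rate <- (bg_tab[kmers] + 0.5) / (bg_n + 0.5)
    out[[as.character(k)]] <- data.frame(
      pattern = kmers, fg_hits = as.integer(fg_tab[kmers]), fg_n = fg_n,
      bg_hits = as.integer(bg_tab[kmers]), bg_n = bg_n,
      fold = (fg_tab[kmers] / fg_n) / bg_rate,
      pvalue = pbinom(fg_tab[kmers] - 1L, fg_n, bg_rate, lower.tail = FALSE),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res$padj <- p.adjust(res$pvalue, "BH")
  res <- res[order(res$pvalue), ]
  rownames(res) <- NULL
  if (is.finite(top)) {
    res <- do.call(rbind, lapply(split(res, nchar(res$pattern)),
                                 function(d) head(d, top)))
    res <- res[order(res$pvalue), ]
    rownames(res) <- NULL
  }
  res
}
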