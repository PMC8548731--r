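#' Genome annotation container
#'
#' A light container for gene models. All coordinates are internal 0-based
#' half-open; conversion to/from the 1-based inclusive GTF convention happens
#' only in [read_gtf()] and [write_gtf()].
#'
#' @param genes data.frame with columns `gene_id`, `gene_name`, `gene_type`,
#'   `chrom`, `strand`, `start`, `end`.
#' @param transcripts data.frame with columns `transcript_id`, `gene_id`.
#' @param exons data.frame with columns `transcript_id`, `chrom`, `start`,
#'   `end`, `strand`; exons of a transcript must be disjoint. They are sorted
#'   by genomic start on construction.
#' @return An object of class `genome_annotation`.
#' @export
genome_annotation <- function(genes, transcripts, exons) {
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  transcripts <- as.data.frame(transcripts, stringsAsFactors = FALSE)
  exons <- as.data.frame(exons, stringsAsFactors = FALSE)
  if (nrow(exons)) {
    if (any(exons$end <= exons$start))
      stop("exon with end <= start (0-based half-open coordinates expected)")
    exons <- exons[order(exons$transcript_id, exons$start), , drop = FALSE]
    rownames(exons) <- NULL
    # disjointness within transcript
    by_tx <- split(seq_len(nrow(exons)), exons$transcript_id)
    for (idx in by_tx) {
      if (length(idx) > 1L &&
          any(exons$start[idx][-1] < exons$end[idx][-length(idx)]))
        stop("overlapping exons in transcript ", exons$transcript_id[idx[1]])
    }
    bad <- setdiff(exons$transcript_id, transcripts$transcript_id)
    if (length(bad)) stop("exons reference unknown transcripts: ",
                          paste(bad, collapse = ", "))
  }
  bad <- setdiff(transcripts$gene_id, genes$gene_id)
  if (length(bad)) stop("transcripts reference unknown genes: ",
                        paste(bad, collapse = ", "))
  structure(list(genes = genes, transcripts = transcripts, exons = exons),
            class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf("genome_annotation: %d genes, %d transcripts, %d exons\n",
              nrow(x$genes), nrow(x$transcripts), nrow(x$exons)))
  if (nrow(x$genes)) {
    tt <- table(x$genes$gene_type)
    cat("  gene_type:", paste(names(tt), tt, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

empty_annotation <- function() {
  genome_annotation(
    genes = data.frame(gene_id = character(), gene_name = character(),
                       gene_type = character(), chrom = character(),
                       strand = character(), start = integer(),
                       end = integer(), stringsAsFactors = FALSE),
    transcripts = data.frame(transcript_id = character(),
                             gene_id = character(), stringsAsFactors = FALSE),
    exons = data.frame(transcript_id = character(), chrom = character(),
                       start = integer(), end = integer(),
                       strand = character(), stringsAsFactors = FALSE))
}

# exons of one transcript, sorted by genomic start
tx_exons <- function(ann, transcript_id) {
  ex <- ann$exons[ann$exons$transcript_id == transcript_id, , drop = FALSE]
  ex[order(ex$start), , drop = FALSE]
}

#' Spliced (exonic) length of each transcript
#'
#' @param ann A [genome_annotation()].
#' @return Named integer vector of summed exon lengths per transcript.
#' @export
spliced_lengths <- function(ann) {
  if (!nrow(ann$exons))
    return(setNames(integer(0), character(0)))
  len <- tapply(ann$exons$end - ann$exons$start, ann$exons$transcript_id, sum)
  setNames(as.integer(len), names(len))
}

#' Canonical transcript per gene
#'
#' The transcript with the longest spliced length represents its gene
#' throughout the pipeline (peak annotation, exon elements, metagene, RPKM
#' lengths); ties break lexicographically on transcript_id.
#'
#' @param ann A [genome_annotation()].
#' @return data.frame with columns `gene_id`, `transcript_id`, `spliced_length`.
#' @export
canonical_transcripts <- function(ann) {
  if (!nrow(ann$transcripts))
    return(data.frame(gene_id = character(), transcript_id = character(),
                      spliced_length = integer(), stringsAsFactors = FALSE))
  len <- spliced_lengths(ann)
  tx <- ann$transcripts
  tx$spliced_length <- as.integer(len[tx$transcript_id])
  tx$spliced_length[is.na(tx$spliced_length)] <- 0L
  tx <- tx[order(tx$gene_id, -tx$spliced_length, tx$transcript_id), ]
  tx <- tx[!duplicated(tx$gene_id), c("gene_id", "transcript_id", "spliced_length")]
  rownames(tx) <- NULL
  tx
}

#' Read a GTF file into a genome_annotation
#'
#' Only `exon` features are used. Coordinates are converted from the GTF
#' 1-based inclusive convention to the internal 0-based half-open one.
#' Records without a `gene_type` attribute are assigned `"unknown"` and the
#' count is reported in the load summary.
#'
#' @param path Path to a GTF file (plain text).
#' @param strip_chr_prefix If `TRUE`, a leading `"chr"` is removed from
#'   sequence names.
#' @return A [genome_annotation()].
#' @export
read_gtf <- function(path, strip_chr_prefix = FALSE) {
  lines <- readLines(path)
  body <- !startsWith(lines, "#") & nzchar(lines)
  nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nf < 9)) {
    bad <- which(body)[which(nf < 9)[1]]
    stop("malformed GTF line ", bad, ": expected 9 tab-separated fields")
  }
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  if (!length(gr)) {
    warning("no exon features in ", path, "; returning empty annotation")
    return(empty_annotation())
  }
  chrom <- as.character(GenomeInfoDb::seqnames(gr))
  if (strip_chr_prefix) chrom <- sub("^chr", "", chrom)
  start1 <- BiocGenerics::start(gr)   # 1-based inclusive
  end1 <- BiocGenerics::end(gr)
  if (any(end1 < start1)) stop("GTF exon with end < start")
  md <- as.data.frame(S4Vectors::mcols(gr))
  gene_type <- if ("gene_type" %in% names(md)) as.character(md$gene_type)
               else rep(NA_character_, length(gr))
  n_missing <- sum(is.na(gene_type))
  gene_type[is.na(gene_type)] <- "unknown"
  gene_name <- if ("gene_name" %in% names(md)) as.character(md$gene_name)
               else as.character(md$gene_id)
  gene_name[is.na(gene_name)] <- as.character(md$gene_id)[is.na(gene_name)]
  exons <- data.frame(transcript_id = as.character(md$transcript_id),
                      chrom = chrom,
                      start = start1 - 1L, end = end1,
                      strand = as.character(BiocGenerics::strand(gr)),
                      stringsAsFactors = FALSE)
  key <- !duplicated(md$transcript_id)
  transcripts <- data.frame(transcript_id = as.character(md$transcript_id)[key],
                            gene_id = as.character(md$gene_id)[key],
                            stringsAsFactors = FALSE)
  gkey <- !duplicated(md$gene_id)
  span_start <- tapply(exons$start, as.character(md$gene_id), min)
  span_end <- tapply(exons$end, as.character(md$gene_id), max)
  gid <- as.character(md$gene_id)[gkey]
  genes <- data.frame(gene_id = gid,
                      gene_name = gene_name[gkey],
                      gene_type = gene_type[gkey],
                      chrom = chrom[gkey],
                      strand = as.character(BiocGenerics::strand(gr))[gkey],
                      start = as.integer(span_start[gid]),
                      end = as.integer(span_end[gid]),
                      stringsAsFactors = FALSE)
  genes <- genes[order(genes$chrom, genes$start), ]
  rownames(genes) <- NULL
  stage_log("read_gtf", "%d genes, %d transcripts, %d exons (%d without gene_type)",
            nrow(genes), nrow(transcripts), nrow(exons), n_missing)
  genome_annotation(genes, transcripts, exons)
}

#' Write a genome_annotation to GTF
#'
#' Emits one `exon` feature per exon with `gene_id`, `transcript_id`,
#' `gene_type` and `gene_name` attributes, converting back to 1-based
#' inclusive coordinates. Writing is deterministic (exons sorted by
#' chromosome, start, transcript).
#'
#' @param ann A [genome_annotation()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(ann, path) {
  ex <- ann$exons
  if (nrow(ex)) {
    tx2gene <- setNames(ann$transcripts$gene_id, ann$transcripts$transcript_id)
    g <- ann$genes
    type <- setNames(g$gene_type, g$gene_id)
    name <- setNames(g$gene_name, g$gene_id)
    gid <- tx2gene[ex$transcript_id]
    ex <- ex[order(ex$chrom, ex$start, ex$transcript_id), ]
    gid <- tx2gene[ex$transcript_id]
    attrs <- sprintf(
      'gene_id "%s"; transcript_id "%s"; gene_type "%s"; gene_name "%s";',
      gid, ex$transcript_id, type[gid], name[gid])
    lines <- paste(ex$chrom, "lncm6a", "exon", ex$start + 1L, ex$end, ".",
                   ex$strand, ".", attrs, sep = "\t")
  } else lines <- character(0)
  writeLines(lines, path)
  invisible(path)
}

#' Write intervals as BED6
#'
#' 0-based half-open, name = gene_id, score = 0.
#'
#' @param intervals data.frame with columns `chrom`, `start`, `end`,
#'   `gene_id`, `strand` (extra columns appended after the 6 BED fields).
#' @param path Output path.
#' @param extra Character vector of extra column names to append (BED6+n).
#' @return `path`, invisibly.
#' @export
write_bed6 <- function(intervals, path, extra = character(0)) {
  df <- data.frame(chrom = intervals$chrom,
                   start = intervals$start,
                   end = intervals$end,
                   name = intervals$gene_id,
                   score = 0L,
                   strand = intervals$strand,
                   stringsAsFactors = FALSE)
  for (col in extra) df[[col]] <- intervals[[col]]
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
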