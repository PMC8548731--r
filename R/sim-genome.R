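#' Generate a synthetic genome and annotation
#'
#' Places non-overlapping multi-exon gene models on random-sequence
#' chromosomes. Gene biotypes are `protein_coding` for the coding class and
#' a mix of `lincRNA`, `antisense` and `processed_transcript` (50/30/20) for
#' the lncRNA class, mirroring the gene_type categories used to select
#' lncRNAs from real annotation. Each transcript carries at least one exon
#' of >= 450 nt so a planted peak always fits inside a single exon. Strand
#' is drawn uniformly per gene. With a fixed seed the sequence and
#' annotation are reproduced exactly.
#'
#' @param config A [sim_config()].
#' @return A list with elements `genome` (a [Biostrings::DNAStringSet]) and
#'   `annotation` (a [genome_annotation()]).
#' @export
generate_genome <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  chroms <- sprintf("chr%d", seq_len(config$n_chromosomes))
  n <- config$n_lnc + config$n_coding

  if (n == 0L) {
    genome <- random_chromosomes(chroms, config$chrom_length)
    return(list(genome = genome, annotation = empty_annotation()))
  }

  biotype <- c(sample(c("lincRNA", "antisense", "processed_transcript"),
                      config$n_lnc, replace = TRUE, prob = c(0.5, 0.3, 0.2)),
               rep("protein_coding", config$n_coding))
  is_lnc <- c(rep(TRUE, config$n_lnc), rep(FALSE, config$n_coding))
  ord <- sample.int(n)              # interleave classes along the genome
  biotype <- biotype[ord]; is_lnc <- is_lnc[ord]

  # draw gene structures
  k <- sample(seq(config$exon_count_range[1], config$exon_count_range[2]),
              n, replace = TRUE)
  structures <- lapply(seq_len(n), function(i) {
    ex_len <- sample(150:400, k[i], replace = TRUE)
    ex_len[sample.int(k[i], 1L)] <- sample(450:700, 1L)  # peak-capable exon
    intron_len <- if (k[i] > 1L) sample(100:400, k[i] - 1L, replace = TRUE)
                  else integer(0)
    list(ex_len = ex_len, intron_len = intron_len,
         footprint = sum(ex_len) + sum(intron_len))
  })

  chrom_of <- rep_len(chroms, n)    # round-robin assignment
  cursor <- setNames(rep(0L, length(chroms)), chroms)
  genes <- transcripts <- exons <- vector("list", n)
  for (i in seq_len(n)) {
    st <- structures[[i]]
    gap <- sample(200:1000, 1L)
    chrom <- chrom_of[i]
    gstart <- cursor[[chrom]] + gap
    gend <- gstart + st$footprint
    gid <- sprintf("SYNG%05d", i)
    if (gend > config$chrom_length)
      stop("chromosome ", chrom, " too short to place gene ", gid,
           " (need end ", gend, " > chrom_length ", config$chrom_length, ")")
    cursor[[chrom]] <- gend
    starts <- gstart + cumsum(c(0L, head(st$ex_len, -1) + st$intron_len))
    tid <- sprintf("%s.T1", gid)
    strand <- sample(c("+", "-"), 1L)
    genes[[i]] <- data.frame(
      gene_id = gid,
      gene_name = sprintf("%s%05d", if (is_lnc[i]) "LNC" else "PC", i),
      gene_type = biotype[i], chrom = chrom, strand = strand,
      start = gstart, end = gend, stringsAsFactors = FALSE)
    transcripts[[i]] <- data.frame(transcript_id = tid, gene_id = gid,
                                   stringsAsFactors = FALSE)
    exons[[i]] <- data.frame(transcript_id = tid, chrom = chrom,
                             start = starts, end = starts + st$ex_len,
                             strand = strand, stringsAsFactors = FALSE)
  }

  ann <- genome_annotation(do.call(rbind, genes),
                           do.call(rbind, transcripts),
                           do.call(rbind, exons))
  genome <- random_chromosomes(chroms, config$chrom_length)
  stage_log("generate_genome", "%d genes (%d lncRNA, %d coding) on %d chromosomes",
            n, config$n_lnc, config$n_coding, length(chroms))
  list(genome = genome, annotation = ann)
}

random_chromosomes <- function(chroms, len) {
  seqs <- vapply(chroms, function(ch)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))
  Biostrings::DNAStringSet(setNames(seqs, chroms))
}
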