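# four genes, each with three equal 200-nt exons, alternating strand
equal_element_annotation <- function(n_genes = 4L) {
  rows_g <- rows_t <- rows_e <- list()
  for (i in seq_len(n_genes)) {
    off <- (i - 1L) * 2000L
    strand <- if (i %% 2 == 0) "-" else "+"
    gid <- sprintf("g%02d", i)
    rows_g[[i]] <- data.frame(gene_id = gid, gene_name = gid,
                              gene_type = "lincRNA", chrom = "chr1",
                              strand = strand, start = off, end = off + 1000L)
    rows_t[[i]] <- data.frame(transcript_id = paste0(gid, ".t"), gene_id = gid)
    rows_e[[i]] <- data.frame(transcript_id = paste0(gid, ".t"), chrom = "chr1",
                              start = off + c(0L, 400L, 800L),
                              end = off + c(200L, 600L, 1000L),
                              strand = strand)
  }
  genome_annotation(do.call(rbind, rows_g), do.call(rbind, rows_t),
                    do.call(rbind, rows_e))
}

peak_at <- function(gene_id, start, end, summit = (start + end) %/% 2L) {
  data.frame(gene_id = gene_id, chrom = "chr1", strand = "+",
             start = start, end = end, summit = summit,
             stringsAsFactors = FALSE)
}

test_that("element summary reproduces the hand-computed 2/1/1 case", {
  ann <- equal_element_annotation(1L)
  peaks <- rbind(peak_at("g01", 20L, 120L), peak_at("g01", 60L, 160L),
                 peak_at("g01", 420L, 520L), peak_at("g01", 820L, 920L))
  es <- element_summary(peaks, ann)
  expect_equal(unname(es$counts), c(2L, 1L, 1L))
  expect_equal(unname(es$proportions), c(0.5, 0.25, 0.25))
  expect_equal(unname(es$relative_enrichment), c(1.5, 0.75, 0.75))
  expect_equal(sum(es$proportions), 1)
})

test_that("all peaks in last exons give a last-exon proportion of 1", {
  ann <- equal_element_annotation(2L)
  # gene 2 is minus strand: its transcript-orientation last exon is the
  # genomically first one
  peaks <- rbind(peak_at("g01", 820L, 920L), peak_at("g02", 2020L, 2120L))
  es <- element_summary(peaks, ann)
  expect_equal(unname(es$proportions["last_exon"]), 1)
})

test_that("single-exon hosts are tallied separately", {
  ann <- genome_annotation(
    genes = data.frame(gene_id = "s1", gene_name = "s1", gene_type = "lincRNA",
                       chrom = "chr1", strand = "+", start = 0L, end = 500L),
    transcripts = data.frame(transcript_id = "s1.t", gene_id = "s1"),
    exons = data.frame(transcript_id = "s1.t", chrom = "chr1", start = 0L,
                       end = 500L, strand = "+"))
  es <- element_summary(peak_at("s1", 100L, 200L), ann)
  expect_equal(es$n_single_exon, 1L)
  expect_equal(sum(es$counts), 0L)
})

test_that("uniform peak placement gives near-flat element enrichment", {
  set.seed(40)
  cfg <- quick_config(seed = 40, n_lnc = 60, n_coding = 0,
                      n_chromosomes = 2, chrom_length = 400000L,
                      exon_count_range = c(3L, 5L), frac_lnc_with_peak = 0)
  ann <- generate_genome(cfg)$annotation
  canon <- canonical_transcripts(ann)
  # place 600 peak midpoints uniformly over each transcript's spliced length
  peaks <- do.call(rbind, lapply(1:600, function(i) {
    j <- sample.int(nrow(canon), 1)
    ex <- lncm6a:::tx_exons(ann, canon$transcript_id[j])
    tc <- sample.int(canon$spliced_length[j], 1) - 1L
    g <- lncm6a:::t2g_exons(ex, ex$strand[1], tc)
    peak_at(canon$gene_id[j], g, g + 1L, g)
  }))
  es <- element_summary(peaks, ann)
  expect_true(all(es$relative_enrichment >= 0.8 &
                  es$relative_enrichment <= 1.25))
  mg <- metagene(peaks, ann)
  expect_equal(sum(mg$density), 1, tolerance = 1e-9)
  expect_lte(max(mg$density), 3 * mean(mg$density))
})

test_that("metagene puts a midpoint summit into the middle bin", {
  ann <- equal_element_annotation(1L)
  # spliced length 600; transcript coordinate 300 = genomic 500 on + strand
  mg <- metagene(peak_at("g01", 450L, 550L, summit = 500L), ann)
  expect_equal(mg$density[mg$bin == 51L], 1)
  expect_equal(sum(mg$density), 1)
  expect_error(metagene(peak_at("g01", 1L, 2L)[0, ], ann), "empty")
})

test_that("peaks-per-gene histogram and median follow the definition", {
  pk <- data.frame(gene_id = c("a", "b", "c", "c", "d", "d", "d"))
  res <- peaks_per_gene(pk)
  expect_equal(res$median, 1.5)          # counts 1,1,2,3
  expect_equal(res$n_genes, 4L)
  one_each <- peaks_per_gene(data.frame(gene_id = c("a", "b", "c")))
  expect_equal(one_each$median, 1)
  expect_true(is.na(peaks_per_gene(data.frame(gene_id = character()))$median))
})

test_that("IUPAC scanning follows the DRACH definition", {
  expect_equal(scan_motif("GGACU"), 1L)
  expect_equal(scan_motif("GGACA"), 1L)
  expect_equal(scan_motif("GGACG"), 0L)   # H excludes G
  expect_equal(scan_motif("TTGGACTTT"), 1L)
  expect_error(scan_motif("GGXCT"), "letters")
})

test_that("the motif scan equals a regular-expression oracle on random sequences", {
  set.seed(17)
  seqs <- rand_seq(1000, 60)
  for (pattern in c("DRACH", "GGACU", "RRACH")) {
    got <- scan_motif(seqs, pattern)
    want <- vapply(seqs, oracle_motif_count, 0L, pattern = pattern,
                   USE.NAMES = FALSE)
    expect_equal(got, want, label = pattern)
  }
})

test_that("dinucleotide shuffles preserve dinucleotide counts exactly", {
  set.seed(2)
  for (s in rand_seq(5, 120)) {
    sh <- dinuc_shuffle(s, n = 3)
    dn <- function(x) Biostrings::dinucleotideFrequency(Biostrings::DNAString(x))
    for (t in sh) expect_equal(dn(t), dn(s))
    expect_equal(substr(sh[1], 1, 1), substr(s, 1, 1))
  }
})

test_that("a planted motif cluster is detected as enriched over background", {
  set.seed(23)
  fg <- vapply(rand_seq(120, 200), function(s) {
    for (p in c(60, 80, 100, 120, 140)) substr(s, p, p + 4) <- "GGACT"
    s
  }, character(1), USE.NAMES = FALSE)
  bg <- rand_seq(400, 200)
  res <- motif_enrichment(fg, bg)
  expect_gt(res$fold, 2)
  expect_lte(res$padj, 0.05)
  # de-novo mode ranks the planted 5-mer first
  dn <- motif_enrichment(fg, bg, pattern = NULL, kmer_lengths = 5L)
  expect_equal(dn$pattern[1], "GGACT")
  expect_lte(dn$padj[1], 0.05)
})

test_that("anatomy statistics are strand-flip invariant", {
  cfg <- quick_config(seed = 31, n_lnc = 25, n_coding = 5,
                      frac_lnc_with_peak = 0.8)
  sim <- simulate_dataset(cfg)
  pk <- call_peaks(sim$wcm, "GM")
  es1 <- element_summary(pk, sim$annotation)
  mg1 <- metagene(pk, sim$annotation)
  len <- cfg$chrom_length
  mir <- mirror_annotation(sim$annotation, len)
  pk2 <- pk
  pk2$start <- len - pk$end; pk2$end <- len - pk$start
  pk2$summit <- len - 1L - pk$summit
  es2 <- element_summary(pk2, mir)
  mg2 <- metagene(pk2, mir)
  expect_equal(es2$counts, es1$counts)
  expect_equal(es2$relative_enrichment, es1$relative_enrichment)
  expect_equal(mg2$density, mg1$density)
})
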