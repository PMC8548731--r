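test_that("GTF coordinates convert between 1-based inclusive and internal 0-based", {
  gtf <- tempfile(fileext = ".gtf")
  writeLines(paste("chr1", "src", "exon", 101, 200, ".", "+", ".",
                   'gene_id "g1"; transcript_id "t1"; gene_type "lincRNA"; gene_name "G1";',
                   sep = "\t"), gtf)
  ann <- read_gtf(gtf)
  expect_equal(ann$exons$start, 100L)
  expect_equal(ann$exons$end, 200L)
  expect_equal(ann$genes$gene_type, "lincRNA")
})

test_that("GTF round trip preserves the annotation", {
  gen <- generate_genome(quick_config(seed = 3))
  path <- tempfile(fileext = ".gtf")
  write_gtf(gen$annotation, path)
  back <- read_gtf(path)
  ord <- function(a) {
    e <- a$exons[order(a$exons$chrom, a$exons$start, a$exons$transcript_id), ]
    rownames(e) <- NULL
    e
  }
  expect_equal(ord(back), ord(gen$annotation))
  expect_setequal(back$genes$gene_id, gen$annotation$genes$gene_id)
  g1 <- gen$annotation$genes[order(gen$annotation$genes$gene_id), ]
  g2 <- back$genes[order(back$genes$gene_id), ]
  expect_equal(g2$gene_type, g1$gene_type)
  expect_equal(g2$strand, g1$strand)
})

test_that("empty and malformed GTFs are handled", {
  gtf <- tempfile(fileext = ".gtf")
  writeLines(paste("chr1", "src", "gene", 1, 100, ".", "+", ".",
                   'gene_id "g"; transcript_id "t";', sep = "\t"), gtf)
  expect_warning(ann <- read_gtf(gtf), "no exon features")
  expect_equal(nrow(ann$genes), 0L)

  bad <- tempfile(fileext = ".gtf")
  writeLines(c("chr1\tsrc\texon\t1\t100", "only two\tfields"), bad)
  expect_error(read_gtf(bad), "line 1")
})

test_that("records without gene_type become 'unknown'", {
  gtf <- tempfile(fileext = ".gtf")
  writeLines(paste("chr1", "src", "exon", 1, 100, ".", "+", ".",
                   'gene_id "g1"; transcript_id "t1";', sep = "\t"), gtf)
  ann <- read_gtf(gtf)
  expect_equal(ann$genes$gene_type, "unknown")
})

test_that("canonical transcript is the longest spliced, ties by id", {
  ann <- genome_annotation(
    genes = data.frame(gene_id = "g1", gene_name = "G1", gene_type = "lincRNA",
                       chrom = "chr1", strand = "+", start = 0L, end = 1000L),
    transcripts = data.frame(transcript_id = c("tB", "tA"),
                             gene_id = c("g1", "g1")),
    exons = data.frame(transcript_id = c("tB", "tA", "tA"), chrom = "chr1",
                       start = c(0L, 0L, 300L), end = c(150L, 100L, 350L),
                       strand = "+"))
  canon <- canonical_transcripts(ann)
  expect_equal(canon$transcript_id, "tA")   # both 150 nt spliced; tA < tB
  expect_equal(canon$spliced_length, 150L)
})

test_that("genomic_to_transcript follows the spliced coordinate definition", {
  plus <- two_exon_annotation("+")
  minus <- two_exon_annotation("-")
  expect_equal(genomic_to_transcript(plus, "t1", 150L), 50L)
  expect_equal(genomic_to_transcript(minus, "t1", 150L), 149L)
  expect_true(is.na(genomic_to_transcript(plus, "t1", 250L)))   # intron
  expect_true(is.na(genomic_to_transcript(plus, "t1", 50L)))    # outside
})

test_that("genomic_to_transcript is a bijection onto [0, L)", {
  for (strand in c("+", "-")) {
    ann <- two_exon_annotation(strand)
    pos <- c(100:199, 300:399)
    tc <- genomic_to_transcript(ann, "t1", pos)
    expect_false(any(is.na(tc)))
    expect_setequal(tc, 0:199)
    # and the inverse map recovers the genomic positions
    ex <- ann$exons
    back <- lncm6a:::t2g_exons(ex, strand, tc)
    expect_equal(back, pos)
  }
})

test_that("exon_element is strand-aware and uses the midpoint", {
  plus <- three_exon_annotation("+")
  minus <- three_exon_annotation("-")
  expect_equal(exon_element(plus, "t1", 420L, 480L), "internal_exon")
  expect_equal(exon_element(plus, "t1", 120L, 180L), "first_exon")
  expect_equal(exon_element(minus, "t1", 120L, 180L), "last_exon")
  expect_equal(exon_element(minus, "t1", 720L, 780L), "first_exon")
  expect_equal(exon_element(plus, "t1", 220L, 280L), "none")   # intronic mid
  two_minus <- two_exon_annotation("-")
  expect_equal(exon_element(two_minus, "t1", 120L, 180L), "last_exon")
})

test_that("mirroring the genome leaves element labels and spliced coords invariant", {
  len <- 1000L
  for (strand in c("+", "-")) {
    ann <- three_exon_annotation(strand)
    mir <- mirror_annotation(ann, len)
    # spliced coordinate of a genomic position equals that of its mirror
    pos <- c(150L, 450L, 750L)
    for (p in pos) {
      expect_equal(genomic_to_transcript(ann, "t1", p),
                   genomic_to_transcript(mir, "t1", len - 1L - p))
    }
    expect_equal(exon_element(ann, "t1", 120L, 180L),
                 exon_element(mir, "t1", len - 180L, len - 120L))
    expect_equal(exon_element(ann, "t1", 420L, 480L),
                 exon_element(mir, "t1", len - 480L, len - 420L))
  }
})

test_that("annotation constructor rejects inconsistent structures", {
  expect_error(genome_annotation(
    genes = data.frame(gene_id = "g1", gene_name = "G", gene_type = "x",
                       chrom = "chr1", strand = "+", start = 0L, end = 10L),
    transcripts = data.frame(transcript_id = "t1", gene_id = "g1"),
    exons = data.frame(transcript_id = "t1", chrom = "chr1",
                       start = c(0L, 5L), end = c(8L, 12L), strand = "+")),
    "overlapping exons")
  expect_error(genome_annotation(
    genes = data.frame(gene_id = "g1", gene_name = "G", gene_type = "x",
                       chrom = "chr1", strand = "+", start = 0L, end = 10L),
    transcripts = data.frame(transcript_id = "t1", gene_id = "g2"),
    exons = data.frame(transcript_id = character(), chrom = character(),
                       start = integer(), end = integer(), strand = character())),
    "unknown genes")
})
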