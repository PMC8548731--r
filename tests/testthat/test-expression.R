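make_gc <- function(counts, cond = c("GM", "GM", "D4", "D4")) {
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("g%03d", seq_len(nrow(counts)))
  gene_counts(counts, cond)
}

# annotation giving every listed gene one single-exon transcript of length len
flat_annotation <- function(gene_ids, len = 1000L, gene_type = "lincRNA") {
  n <- length(gene_ids)
  starts <- seq(0L, by = len + 100L, length.out = n)
  genome_annotation(
    genes = data.frame(gene_id = gene_ids, gene_name = gene_ids,
                       gene_type = rep_len(gene_type, n), chrom = "chr1",
                       strand = "+", start = starts, end = starts + len),
    transcripts = data.frame(transcript_id = paste0(gene_ids, ".t"),
                             gene_id = gene_ids),
    exons = data.frame(transcript_id = paste0(gene_ids, ".t"), chrom = "chr1",
                       start = starts, end = starts + len, strand = "+"))
}

test_that("rpkm satisfies the unit case and scale invariance", {
  ann <- flat_annotation("g001")
  gc <- gene_counts(matrix(10L, 1, 1, dimnames = list("g001", "s1")),
                    "GM", lib_size = 1e6)
  expect_equal(unname(rpkm(gc, ann)$rpkm[1, 1]), 10)

  counts <- matrix(rpois(80, 40), 20, 4,
                   dimnames = list(sprintf("g%03d", 1:20), NULL))
  ann <- flat_annotation(sprintf("g%03d", 1:20))
  r1 <- rpkm(make_gc(counts), ann)$rpkm
  r2 <- rpkm(make_gc(counts * 2L), ann)$rpkm
  expect_equal(r1, r2)
})

test_that("rpkm equals an independently coded formula on a random matrix", {
  set.seed(11)
  counts <- matrix(rpois(80, 100), 20, 4,
                   dimnames = list(sprintf("g%03d", 1:20), paste0("s", 1:4)))
  lens <- 1000L
  ann <- flat_annotation(sprintf("g%03d", 1:20))
  gc <- make_gc(counts)
  got <- rpkm(gc, ann)
  lib <- colSums(counts)
  want <- counts
  for (j in 1:4) for (i in 1:20)
    want[i, j] <- counts[i, j] * 1e9 / (lib[j] * lens)
  expect_equal(got$rpkm, want)
  expect_equal(got$mean_rpkm, rowMeans(want))
  expect_error(rpkm(make_gc(rbind(counts, gX = 1L)), ann), "gX")
})

test_that("size factors: identity, known two-column case, single sample", {
  m <- matrix(rpois(20, 50) + 1L, 10, 2)
  m[, 2] <- m[, 1]
  expect_equal(unname(size_factors(m)), c(1, 1))

  m2 <- cbind(m[, 1], m[, 1] * 2L)
  sf <- size_factors(m2)
  expect_equal(unname(sf[2] / sf[1]), 2)
  expect_equal(unname(exp(mean(log(sf)))), 1)

  expect_equal(size_factors(m[, 1, drop = FALSE]), 1)
  zero <- matrix(c(1L, 0L, 0L, 1L), 2, 2)
  expect_error(size_factors(zero), "no gene")
})

test_that("a null gene has log2FC 0 and p near 1", {
  set.seed(3)
  counts <- matrix(rnbinom(400 * 4, mu = 100, size = 10), 400, 4)
  counts[1, ] <- c(80L, 80L, 80L, 80L)
  gc <- make_gc(counts)
  de <- differential_expression(gc)
  expect_equal(de$log2FoldChange[1], 0, tolerance = 0.15)
  expect_gt(de$pvalue[1], 0.5)
  expect_equal(de$direction[1], "NS")
})

test_that("direction labels follow the padj/sign rule exactly", {
  set.seed(4)
  counts <- matrix(rnbinom(300 * 4, mu = 150, size = 10), 300, 4)
  counts[1, 3:4] <- counts[1, 3:4] * 30L
  counts[2, 3:4] <- pmax(counts[2, 3:4] %/% 30L, 0L)
  de <- differential_expression(make_gc(counts))
  expect_equal(de$direction[1], "Up")
  expect_equal(de$direction[2], "Down")
  expect_true(all((de$direction == "NS") == (de$padj > 0.05 |
                                             de$log2FoldChange == 0)))
  expect_true(all(de$padj >= de$pvalue))
})

test_that("a strong planted effect is recovered with the right sign", {
  # emulates a top upregulated lncRNA: log2FC +4 at high counts
  set.seed(5)
  hits <- logical(40)
  for (k in 1:40) {
    ng <- 150
    mu <- 100 * exp(rnorm(ng, 0, 0.5))
    counts <- cbind(rnbinom(ng, mu = mu, size = 10),
                    rnbinom(ng, mu = mu, size = 10),
                    rnbinom(ng, mu = mu * c(2^4, rep(1, ng - 1)), size = 10),
                    rnbinom(ng, mu = mu * c(2^4, rep(1, ng - 1)), size = 10))
    de <- differential_expression(make_gc(counts))
    hits[k] <- de$log2FoldChange[1] > 0 && de$padj[1] <= 0.05
  }
  expect_gte(mean(hits), 0.95)
})

test_that("conditions with too few samples are rejected", {
  counts <- matrix(rpois(30, 50), 10, 3,
                   dimnames = list(sprintf("g%02d", 1:10), NULL))
  expect_error(differential_expression(gene_counts(counts, c("GM", "GM", "D4"))),
               ">= 2 samples")
  expect_error(differential_expression(gene_counts(counts[, 1:2], c("GM", "GM"))),
               "absent")
})

test_that("biotype partition conserves genes and routes lncRNA classes", {
  ids <- sprintf("g%02d", 1:10)
  types <- c("lincRNA", "antisense", "processed_transcript",
             "protein_coding", "protein_coding", "snoRNA", "lincRNA",
             "protein_coding", "antisense", "miRNA")
  ann <- flat_annotation(ids)
  ann$genes$gene_type <- types
  res <- data.frame(gene_id = ids, log2FoldChange = 0, pvalue = 1, padj = 1,
                    meanRPKM = 1, direction = "NS", stringsAsFactors = FALSE)
  sp <- split_by_biotype(res, ann)
  expect_equal(nrow(sp$lnc), 5L)
  expect_equal(nrow(sp$mrna), 3L)
  expect_equal(sp$n_dropped, 2L)
  expect_equal(nrow(sp$lnc) + nrow(sp$mrna) + sp$n_dropped, 10L)

  all_pc <- ann
  all_pc$genes$gene_type <- "protein_coding"
  expect_equal(nrow(split_by_biotype(res, all_pc)$lnc), 0L)
})

test_that("expressed_genes applies the per-condition mean floor", {
  counts <- rbind(a = c(0L, 0L, 3L, 3L), b = c(0L, 1L, 0L, 0L),
                  c = c(0L, 0L, 0L, 0L), d = c(5L, 5L, 5L, 5L))
  gc <- make_gc(counts)
  expect_equal(unname(expressed_genes(gc)), c(TRUE, FALSE, FALSE, TRUE))
})
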