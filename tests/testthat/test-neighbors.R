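# a chromosome layout from gene spans; types: "L" lncRNA, "P" coding
layout_annotation <- function(spans, types, chrom = "chr1") {
  n <- nrow(spans)
  ids <- sprintf("%s%02d", types, seq_len(n))
  genome_annotation(
    genes = data.frame(gene_id = ids, gene_name = ids,
                       gene_type = ifelse(types == "L", "lincRNA",
                                          "protein_coding"),
                       chrom = chrom, strand = "+",
                       start = spans[, 1], end = spans[, 2]),
    transcripts = data.frame(transcript_id = paste0(ids, ".t"), gene_id = ids),
    exons = data.frame(transcript_id = paste0(ids, ".t"), chrom = chrom,
                       start = spans[, 1], end = spans[, 2], strand = "+"))
}

test_that("the A,B,L,C,D layout ranks neighbors by proximity per side", {
  ann <- layout_annotation(cbind(c(0, 200, 400, 600, 800),
                                 c(100, 300, 500, 700, 900)),
                           c("P", "P", "L", "P", "P"))
  nb <- find_neighbors("L03", ann, k = 5)
  up <- nb[nb$side == "upstream", ]
  down <- nb[nb$side == "downstream", ]
  expect_equal(up$coding_gene_id[up$rank == 1], "P02")
  expect_equal(up$coding_gene_id[up$rank == 2], "P01")
  expect_equal(down$coding_gene_id[down$rank == 1], "P04")
  expect_equal(down$coding_gene_id[down$rank == 2], "P05")
  expect_equal(up$distance[up$rank == 1], 100L)
})

test_that("a lncRNA first on its chromosome has no upstream neighbors", {
  ann <- layout_annotation(cbind(c(0, 200, 400), c(100, 300, 500)),
                           c("L", "P", "P"))
  nb <- find_neighbors("L01", ann)
  expect_equal(sum(nb$side == "upstream"), 0L)
  expect_equal(sum(nb$side == "downstream"), 2L)
})

test_that("overlapping genes get distance 0 and side from their start", {
  ann <- layout_annotation(cbind(c(100, 50, 150), c(300, 160, 400)),
                           c("L", "P", "P"))
  nb <- find_neighbors("L01", ann)
  expect_equal(nb$distance, c(0L, 0L))
  expect_equal(nb$side[nb$coding_gene_id == "P02"], "upstream")
  expect_equal(nb$side[nb$coding_gene_id == "P03"], "downstream")
  expect_error(find_neighbors("missing", ann), "not in annotation")
})

test_that("neighbors equal the brute-force oracle on random genomes", {
  for (seed in 1:10) {
    cfg <- quick_config(seed = seed, n_lnc = 8, n_coding = 25,
                        chrom_length = 300000L)
    ann <- generate_genome(cfg)$annotation
    lnc <- ann$genes$gene_id[ann$genes$gene_type != "protein_coding"]
    for (id in lnc) {
      got <- find_neighbors(id, ann, k = 5)
      want <- oracle_neighbors(id, ann, k = 5)
      if (is.null(want)) { expect_equal(nrow(got), 0L); next }
      key <- function(d) d[order(d$side, d$rank),
                           c("coding_gene_id", "side", "distance")]
      g <- key(got); rownames(g) <- NULL
      w <- key(want[, c("coding_gene_id", "side", "distance", "rank")])
      rownames(w) <- NULL
      expect_equal(g, w, label = paste("seed", seed, id))
    }
  }
})

test_that("mirroring the chromosome swaps sides but keeps pairs and distances", {
  cfg <- quick_config(seed = 99, n_lnc = 6, n_coding = 20,
                      chrom_length = 300000L)
  ann <- generate_genome(cfg)$annotation
  mir <- mirror_annotation(ann, cfg$chrom_length)
  lnc <- ann$genes$gene_id[ann$genes$gene_type != "protein_coding"]
  for (id in lnc) {
    a <- find_neighbors(id, ann)
    b <- find_neighbors(id, mir)
    expect_setequal(a$coding_gene_id, b$coding_gene_id)
    m <- merge(a, b, by = "coding_gene_id")
    expect_true(all(m$side.x != m$side.y))
    expect_equal(m$distance.x, m$distance.y)
  }
})

test_that("pair filtering requires dual significance plus a differential peak", {
  pairs <- data.frame(lnc_gene_id = c("L1", "L1", "L2"),
                      coding_gene_id = c("P1", "P2", "P3"),
                      side = "upstream", rank = 1L, distance = 10L,
                      stringsAsFactors = FALSE)
  de <- data.frame(gene_id = c("L1", "L2", "P1", "P2", "P3"),
                   log2FoldChange = c(-2, 2, 3, -1, 2),
                   pvalue = 0.001,
                   padj = c(0.01, 0.01, 0.04, 0.2, 0.01),
                   meanRPKM = 1,
                   direction = c("Down", "Up", "Up", "NS", "Up"))
  dp <- data.frame(gene_id = c("L1", "L2"), diff_log2_fc = c(-1, 1),
                   diff_fdr = c(0.01, 0.3), diff_lg_fdr = log10(c(0.01, 0.3)))
  kept <- pair_filter(pairs, de, dp)
  # P2 dropped (coding padj 0.2); L2-P3 dropped (no significant peak)
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$coding_gene_id, "P1")
  expect_equal(kept$concordance, "retrograde")   # lnc down, coding up
  # same-sign pair is positive
  de$log2FoldChange[de$gene_id == "P1"] <- -3
  expect_equal(pair_filter(pairs, de, dp)$concordance, "positive")
})

test_that("ora matches closed forms and enumeration", {
  universe <- sprintf("u%02d", 1:20)
  sets <- list(hit = universe[1:5], other = universe[6:15])
  res <- ora(universe[1:5], sets, universe)
  expect_equal(res$pvalue[res$set == "hit"], 1 / choose(20, 5),
               tolerance = 1e-12)
  # query = universe -> every set fully overlaps, p = 1
  res2 <- ora(universe, sets, universe)
  expect_true(all(res2$pvalue == 1))
  expect_true(all(res2$overlap == res2$set_size))
  expect_error(ora(c("zz"), sets, universe), "outside the universe")

  set.seed(19)
  for (i in 1:25) {
    N <- sample(10:30, 1)
    uni <- sprintf("x%02d", 1:N)
    K <- sample(2:(N - 2), 1); n <- sample(2:(N - 2), 1)
    s <- list(s = sample(uni, K))
    q <- sample(uni, n)
    got <- ora(q, s, uni)$pvalue
    ov <- length(intersect(q, s$s))
    expect_equal(got, oracle_hyper_upper(ov, N, K, n), tolerance = 1e-12)
  }
})

test_that("gmt round trip preserves the collection", {
  path <- tempfile(fileext = ".gmt")
  writeLines(c("setA\tdesc\tg1\tg2\tg3", "setB\tdesc\tg4\tg5"), path)
  sets <- read_gmt(path)
  expect_equal(sets$setA, c("g1", "g2", "g3"))
  expect_equal(lengths(sets), c(setA = 3L, setB = 2L))
})
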