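test_that("features follow their definitions on a worked example", {
  g <- data.frame(gene_id = "g1", chrom = "chr1", start = 1, end = 300,
                  strand = "+", gc_fraction = 0.5)
  tx <- list(g1 = list(cbind(start = c(1, 201), end = c(100, 300))))
  feats <- extract_features(gene_annotation(g, tx))
  expect_equal(feats$gene_length, 300)
  expect_equal(feats$transcript_length, 200)
  expect_equal(feats$exon_count, 2)
  expect_equal(feats$exon_length, 100)
  expect_equal(feats$intron_length, 100)
})

test_that("single-exon genes have no intron length", {
  ann <- toy_annotation(3)
  feats <- extract_features(ann)
  expect_true(all(is.na(feats$intron_length)))
  expect_equal(feats$exon_count, rep(1, 3))
})

test_that("identical transcripts average to the single-transcript values", {
  g <- data.frame(gene_id = "g1", chrom = "chr1", start = 1, end = 300,
                  strand = "+", gc_fraction = 0.5)
  one <- list(g1 = list(cbind(start = c(1, 201), end = c(100, 300))))
  two <- list(g1 = rep(one$g1, 2))
  f1 <- extract_features(gene_annotation(g, one))
  f2 <- extract_features(gene_annotation(g, two))
  expect_equal(f1[, -1], f2[, -1])
})

test_that("pooled and per-transcript intron averaging differ as defined", {
  g <- data.frame(gene_id = "g1", chrom = "chr1", start = 1, end = 1000,
                  strand = "+", gc_fraction = 0.5)
  tx <- list(g1 = list(
    cbind(start = c(1, 101), end = c(50, 200)),          # intron 50
    cbind(start = c(1, 301, 601), end = c(100, 400, 700))))  # introns 200, 200
  ann <- gene_annotation(g, tx)
  pooled <- extract_features(ann, intron_mode = "pooled")
  per_tx <- extract_features(ann, intron_mode = "per_transcript")
  expect_equal(pooled$intron_length, mean(c(50, 200, 200)))
  expect_equal(per_tx$intron_length, mean(c(50, 200)))
})

test_that("genes with overlapping exons are skipped with a warning", {
  g <- data.frame(gene_id = c("ok", "bad"), chrom = "chr1",
                  start = c(1, 500), end = c(100, 700), strand = "+",
                  gc_fraction = 0.5)
  tx <- list(bad = list(cbind(start = c(500, 550), end = c(600, 700))))
  expect_warning(feats <- extract_features(gene_annotation(g, tx)),
                 "overlapping exons")
  expect_equal(feats$gene_id, "ok")
})

test_that("the rank-sum test matches its exact small-sample values", {
  feats <- structure(
    data.frame(gene_id = sprintf("g%d", 1:6),
               gene_length = c(1, 2, 3, 4, 5, 6),
               intron_length = NA_real_, gc_fraction = 0.5,
               transcript_length = 1, exon_count = 1, exon_length = 1),
    class = c("feature_table", "data.frame"))
  cmp <- compare_groups(feats, sprintf("g%d", 1:3), sprintf("g%d", 4:6),
                        "gene_length", labels = c("A", "B"))
  expect_equal(cmp$p, 0.1)           # enumeration over C(6,3) = 20 splits
  expect_equal(cmp$direction, "A lower")
  expect_equal(cmp$method, "exact")
  # identical samples: symmetric statistic, p = 1
  same <- compare_groups(feats, sprintf("g%d", 1:3), sprintf("g%d", 1:3),
                         "gene_length")
  expect_equal(same$p, 1)
  # swapping the groups mirrors the direction but not the p-value
  rev <- compare_groups(feats, sprintf("g%d", 4:6), sprintf("g%d", 1:3),
                        "gene_length", labels = c("A", "B"))
  expect_equal(rev$p, cmp$p)
  expect_equal(rev$direction, "A higher")
  expect_error(compare_groups(feats, character(0), "g1", "gene_length"),
               "non-empty")
})

test_that("exact and approximate p agree for tie-free mid-size samples", {
  set.seed(31)
  for (rep in 1:5) {
    x <- rnorm(15); y <- rnorm(15, 0.5)
    p_exact <- stats::wilcox.test(x, y, exact = TRUE)$p.value
    p_approx <- stats::wilcox.test(x, y, exact = FALSE,
                                   correct = TRUE)$p.value
    expect_lt(abs(p_exact - p_approx), 0.01)
  }
})

test_that("simulated RIDGE genes are shorter than anti-RIDGE genes", {
  sim <- simulate_genome(n_chrom = 5, genes_per_chrom = 400, seed = 71)
  cl <- sim$truth$classes
  feats <- extract_features(sim$annotation)
  rg <- cl$gene_id[cl$region == "RIDGE"]
  ag <- cl$gene_id[cl$region == "ANTIRIDGE"]
  expect_gt(length(rg), 200)
  expect_gt(length(ag), 150)
  cmp <- compare_groups(feats, rg, ag, "gene_length",
                        labels = c("RIDGE", "antiRIDGE"))
  expect_equal(cmp$direction, "RIDGE lower")
  expect_lt(cmp$p, 0.01)
  gc <- compare_groups(feats, rg, ag, "gc_fraction",
                       labels = c("RIDGE", "antiRIDGE"))
  expect_equal(gc$direction, "RIDGE higher")
  expect_lt(gc$p, 0.01)
})
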