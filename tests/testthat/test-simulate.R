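test_that("the generator is deterministic given a seed", {
  a <- simulate_genome(n_chrom = 2, genes_per_chrom = 80, seed = 7)
  b <- simulate_genome(n_chrom = 2, genes_per_chrom = 80, seed = 7)
  expect_identical(a$annotation$genes, b$annotation$genes)
  expect_identical(a$annotation$transcripts, b$annotation$transcripts)
  expect_identical(a$truth$regions, b$truth$regions)
  expect_identical(a$truth$classes, b$truth$classes)
  ea <- simulate_expression(a$annotation, a$truth, seed = 9)
  eb <- simulate_expression(b$annotation, b$truth, seed = 9)
  expect_identical(ea$values, eb$values)
  expect_identical(ea$negative_controls, eb$negative_controls)
  # written artifacts are byte-identical too
  fa <- tempfile(); fb <- tempfile()
  write_annotation(a$annotation, fa); write_annotation(b$annotation, fb)
  expect_identical(readLines(fa), readLines(fb))
})

test_that("planted coverage lands within 10% of the target", {
  for (s in 1:3) {
    sim <- simulate_genome(seed = s, coverage_target = 0.10)
    expect_true(all(sim$truth$coverage >= 0.09 & sim$truth$coverage <= 0.11))
    # oracle: recompute coverage from the planted intervals
    tr <- sim$truth$regions
    for (k in c("RIDGE", "ANTIRIDGE")) {
      r <- tr[tr$kind == k, ]
      expect_equal(sum(r$end - r$start + 1) /
                     sum(sim$annotation$chrom_lengths),
                   unname(sim$truth$coverage[k]))
    }
  }
})

test_that("planted domains never overlap and classes partition the genes", {
  sim <- simulate_genome(n_chrom = 3, genes_per_chrom = 200, seed = 13)
  tr <- sim$truth$regions
  for (chrom in unique(tr$chrom)) {
    rc <- tr[tr$chrom == chrom, ]
    rc <- rc[order(rc$start), ]
    expect_true(all(rc$start[-1] > rc$end[-nrow(rc)]))
  }
  cl <- sim$truth$classes
  expect_setequal(cl$gene_id, sim$annotation$genes$gene_id)
  expect_true(all(cl$class %in% c("HK", "TS", "intermediate", "silent")))
  expect_error(simulate_genome(seed = 1, coverage_target = 0.45), "overlap")
})

test_that("planted-RIDGE genes have higher GC and shorter structures", {
  sim <- simulate_genome(n_chrom = 5, genes_per_chrom = 400, seed = 17)
  cl <- sim$truth$classes
  feats <- extract_features(sim$annotation)
  rownames(feats) <- feats$gene_id
  rg <- cl$gene_id[cl$region == "RIDGE"]
  ag <- cl$gene_id[cl$region == "ANTIRIDGE"]
  expect_gt(median(feats[rg, "gc_fraction"]),
            median(feats[ag, "gc_fraction"]))
  expect_lt(median(feats[rg, "gene_length"]),
            median(feats[ag, "gene_length"]))
  expect_lt(median(feats[rg, "intron_length"], na.rm = TRUE),
            median(feats[ag, "intron_length"], na.rm = TRUE))
})

test_that("expression values honour clipping and the intensity scale", {
  sim <- simulate_genome(n_chrom = 2, genes_per_chrom = 100, seed = 23)
  expr <- simulate_expression(sim$annotation, sim$truth, seed = 24)
  expect_true(all(expr$values >= 8 & expr$values <= 15))
  expect_true(all(expr$negative_controls >= 8))
  expect_equal(ncol(expr$values), 5)
  expect_error(simulate_expression(sim$annotation, sim$truth, n_tissues = 0),
               "n_tissues")
})

test_that("a null simulation yields no regions at the study fold thresholds", {
  # delta = 0 and a single expression class: the map is flat within noise
  sim <- simulate_genome(n_chrom = 2, genes_per_chrom = 200, seed = 29,
                         hk_prob_ridge = 0, hk_prob_background = 0,
                         hk_prob_antiridge = 0, ts_prob = 0,
                         silent_prob = 0, silent_prob_antiridge = 0)
  expr <- simulate_expression(sim$annotation, sim$truth, seed = 30, delta = 0)
  fit <- ridge_scan(expr, sim$annotation, fold_up = 1.25, fold_down = 1.45)
  expect_equal(nrow(fit$regions), 0)
})

test_that("constructed HK genes classify as HK", {
  sim <- simulate_genome(n_chrom = 1, genes_per_chrom = 60, seed = 41)
  expr <- simulate_expression(sim$annotation, sim$truth, seed = 42)
  tau <- expression_threshold(expr$negative_controls, 0.999)
  # construct a gene whose class term clears the threshold in every tissue
  expr$values[1, ] <- tau + 1
  cls <- classify_genes(expr, tau)
  expect_equal(cls$class[1], "HK")
})

test_that("truth JSON serialises the planted structure", {
  sim <- simulate_genome(n_chrom = 1, genes_per_chrom = 40, seed = 51)
  f <- tempfile(fileext = ".json")
  write_truth(sim$truth, f)
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  # regions are serialised column-wise
  expect_equal(length(back$regions$chrom), nrow(sim$truth$regions))
  expect_equal(back$regions$start, sim$truth$regions$start)
  expect_equal(back$coverage$RIDGE, unname(sim$truth$coverage["RIDGE"]))
})
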