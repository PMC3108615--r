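test_that("maps are produced for chromosomes smaller than the window", {
  ann <- toy_annotation(5)
  expr <- toy_expression(ann, c(1, 9, 2, 8, 3))
  map <- build_map(expr, ann, tissue = "T1", window = 39)
  ch <- map$chroms$chr1
  expect_length(ch$smoothed, 5)
  # window shrinks to the series; equals brute-force oracle
  expect_equal(ch$smoothed, brute_running_median(c(1, 9, 2, 8, 3), 39))
})

test_that("a single-gene chromosome keeps its raw value", {
  ann <- toy_annotation(1)
  expr <- toy_expression(ann, 11.5)
  map <- build_map(expr, ann, tissue = "T1")
  expect_equal(map$chroms$chr1$smoothed, 11.5)
})

test_that("genes without expression are excluded from the map only", {
  ann <- toy_annotation(4)
  ids <- ann$genes$gene_id
  expr <- expression_matrix(matrix(c(10, 11, 12), ncol = 1,
                                   dimnames = list(ids[1:3], "T1")))
  map <- build_map(expr, ann, tissue = "T1", window = 1)
  expect_equal(map$chroms$chr1$gene_id, ids[1:3])
  expect_equal(nrow(ann$genes), 4)
  expect_error(build_map(expr, ann, tissue = "nope"), "unknown tissue")
})

test_that("the average map is the per-gene mean across tissues", {
  ann <- toy_annotation(3)
  ids <- ann$genes$gene_id
  vals <- matrix(c(10, 11, 12, 14, 13, 12), ncol = 2,
                 dimnames = list(ids, c("A", "B")))
  expr <- expression_matrix(vals)
  map <- build_map(expr, ann, tissue = "average", window = 1)
  expect_equal(map$chroms$chr1$raw, c(12, 12, 12))
})

test_that("smoothed values inside planted RIDGEs exceed the genomic median", {
  sim <- simulate_genome(n_chrom = 2, genes_per_chrom = 300, seed = 11)
  expr <- simulate_expression(sim$annotation, sim$truth, seed = 12)
  map <- build_map(expr, sim$annotation)
  m <- genomic_median(map)
  tr <- sim$truth$regions
  inside <- unlist(lapply(names(map$chroms), function(chrom) {
    ch <- map$chroms[[chrom]]
    r <- tr[tr$chrom == chrom & tr$kind == "RIDGE", ]
    # clear of the block edges, where the window mixes in background genes
    ch$smoothed[ch$start >= r$start + 2e5 & ch$end <= r$end - 2e5]
  }))
  expect_gt(length(inside), 20)
  expect_true(all(inside > m))
})

test_that("map TSV write/read round trip preserves the map", {
  sim <- simulate_genome(n_chrom = 2, genes_per_chrom = 60, seed = 2)
  expr <- simulate_expression(sim$annotation, sim$truth, seed = 3)
  map <- build_map(expr, sim$annotation)
  f <- tempfile(fileext = ".tsv")
  write_map(map, f)
  back <- read_map(f)
  expect_equal(back$window, map$window)
  expect_equal(back$tissue, map$tissue)
  expect_equal(back$chrom_lengths, map$chrom_lengths, tolerance = 1e-11)
  for (chrom in names(map$chroms)) {
    expect_equal(back$chroms[[chrom]]$smoothed, map$chroms[[chrom]]$smoothed,
                 tolerance = 1e-11)
  }
})

test_that("map correlation is 1 against itself and -1 for reversed ranks", {
  ann <- toy_annotation(3)
  a <- build_map(toy_expression(ann, c(1, 2, 3)), ann, "T1", window = 1)
  b <- build_map(toy_expression(ann, c(3, 2, 1)), ann, "T1", window = 1)
  expect_equal(map_correlation(a, a)$rho, 1)
  expect_equal(map_correlation(a, b)$rho, -1)
  ann2 <- toy_annotation(2)
  s <- build_map(toy_expression(ann2, c(1, 2)), ann2, "T1", window = 1)
  expect_error(map_correlation(s, s), "at least 3")
})

test_that("shared per-gene effects induce high inter-tissue map correlation", {
  sim <- simulate_genome(n_chrom = 2, genes_per_chrom = 250, seed = 21)
  expr <- simulate_expression(sim$annotation, sim$truth, seed = 22,
                              sigma_gene = 0.8, sigma_bg = 0.5)
  tis <- tissues(expr)
  maps <- lapply(tis, function(tn) build_map(expr, sim$annotation, tn))
  rhos <- c()
  for (i in seq_along(tis)) for (j in seq_along(tis)) if (i < j)
    rhos <- c(rhos, map_correlation(maps[[i]], maps[[j]])$rho)
  expect_gt(mean(rhos), 0.5)
})
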