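test_that("genomic median handles odd, even and constant inputs", {
  expect_equal(genomic_median(c(9, 10, 11)), 10)
  expect_equal(genomic_median(c(9, 10, 11, 12)), 10.5)
  expect_equal(genomic_median(rep(11, 7)), 11)
})

# a 1-tissue map whose smoothed values equal the supplied vector (window 1)
flat_map <- function(values, gene_width = 10, chrom_length = NULL) {
  ann <- toy_annotation(length(values), gene_width = gene_width,
                        chrom_length = chrom_length)
  list(map = build_map(toy_expression(ann, values), ann, "T1", window = 1),
       ann = ann)
}

test_that("qualifying runs become regions only at the minimum stretch", {
  vals <- c(rep(10, 5), rep(13, 12), rep(10, 10))
  fm <- flat_map(vals)
  reg <- call_regions(fm$map, m = 10, fold = 1.2, "up", min_stretch = 10)
  expect_equal(nrow(reg), 1)
  expect_equal(reg$n_gene_positions, 12L)
  expect_equal(reg$kind, "RIDGE")
  # interval spans the qualifying genes (positions 6..17, width 10 each)
  expect_equal(reg$start, 51)
  expect_equal(reg$end, 170)

  short <- flat_map(c(rep(10, 5), rep(13, 8), rep(10, 10)))
  reg2 <- call_regions(short$map, 10, 1.2, "up", min_stretch = 10)
  expect_equal(nrow(reg2), 0)
})

test_that("ties at the threshold never qualify", {
  fm <- flat_map(rep(10, 30))
  expect_equal(nrow(call_regions(fm$map, 10, 1.0001, "up", 1)), 0)
  expect_equal(nrow(call_regions(fm$map, 10, 1.0001, "down", 1)), 0)
  # all equal to the median itself: strict inequality excludes everything
  up <- call_regions(fm$map, 10, 1.2, "up", 10)
  down <- call_regions(fm$map, 10, 1.2, "down", 10)
  expect_equal(nrow(up) + nrow(down), 0)
})

test_that("member genes include the run genes and any-overlap neighbours", {
  vals <- c(rep(10, 5), rep(13, 12), rep(10, 10))
  fm <- flat_map(vals)
  reg <- call_regions(fm$map, 10, 1.2, "up", 10, annotation = fm$ann)
  expect_true(all(reg$position_genes[[1]] %in% reg$member_genes[[1]]))
  expect_setequal(reg$member_genes[[1]], fm$ann$genes$gene_id[6:17])
})

test_that("coverage adds disjoint regions over total genome length", {
  regions <- data.frame(chrom = c("chr1", "chr1"),
                        start = c(1, 50e6), end = c(3e6, 57e6 - 1),
                        kind = "RIDGE", n_gene_positions = c(12L, 15L))
  expect_equal(region_coverage(regions, c(chr1 = 100e6)), 0.10)
  empty <- regions[0, ]
  expect_equal(region_coverage(empty, c(chr1 = 100e6)), 0)
  expect_error(region_coverage(regions, c(chr1 = 0)), "genome length")
  # invariant under chromosome relabeling
  relab <- regions; relab$chrom <- c("chrA", "chrA")
  expect_equal(region_coverage(relab, c(chrA = 100e6)),
               region_coverage(regions, c(chr1 = 100e6)))
})

test_that("calibration picks the grid fold closest to the target coverage", {
  # constructed coverage curve on a 1000 bp genome, m = 10:
  #   fold 1.20 -> genes 1..13 qualify, span 130 bp -> 0.13
  #   fold 1.25 -> genes 4..13, span 97 bp -> 0.097
  #   fold 1.30 -> genes 8..13, span 60 bp -> 0.06
  widths <- c(11, 11, 11, 7, rep(10, 9))
  starts <- cumsum(c(1, widths[-13]))
  g <- data.frame(gene_id = sprintf("g%02d", 1:13), chrom = "chr1",
                  start = starts, end = starts + widths - 1, strand = "+",
                  gc_fraction = 0.5)
  ann <- gene_annotation(g, chrom_lengths = c(chr1 = 1000))
  vals <- c(rep(12.4, 3), rep(12.8, 4), rep(13.35, 6))
  map <- build_map(toy_expression(ann, vals), ann, "T1", window = 1)
  cal <- calibrate_fold(map, m = 10, "up", target = 0.10, step = 0.05,
                        min_stretch = 1)
  expect_equal(cal$fold, 1.25)
  expect_equal(cal$coverage, 0.097)
  grid <- cal$grid
  expect_equal(grid$coverage[which(abs(grid$fold - 1.20) < 1e-9)], 0.13)
  expect_equal(grid$coverage[which(abs(grid$fold - 1.30) < 1e-9)], 0.06)
  # oracle: the returned fold minimises |coverage - target| on the grid
  expect_equal(min(abs(grid$coverage - 0.10)), abs(cal$coverage - 0.10))
  # up-direction coverage is non-increasing in the fold
  expect_true(all(diff(grid$coverage) <= 1e-12))
  # a target of ~1 is best approximated by the maximal achievable coverage
  # (reached at the least stringent folds; ties resolve to the largest fold
  # that still attains it)
  cal_max <- calibrate_fold(map, 10, "up", target = 0.99, step = 0.05,
                            min_stretch = 1)
  expect_equal(cal_max$coverage, max(cal_max$grid$coverage))
  expect_equal(cal_max$coverage, 0.13)
})

test_that("calibration warns and returns the smallest fold when nothing is called", {
  fm <- flat_map(rep(10, 30))
  expect_warning(cal <- calibrate_fold(fm$map, 10, "up", target = 0.1,
                                       step = 0.05, min_stretch = 10),
                 "smallest fold")
  expect_equal(cal$fold, 1.05)
})

test_that("regions of one kind are disjoint and separated on simulated data", {
  sim <- simulate_genome(n_chrom = 3, genes_per_chrom = 300, seed = 31)
  expr <- simulate_expression(sim$annotation, sim$truth, seed = 32)
  fit <- ridge_scan(expr, sim$annotation, calibrate = TRUE)
  for (k in c("RIDGE", "ANTIRIDGE")) {
    r <- fit$regions[fit$regions$kind == k, ]
    for (chrom in unique(r$chrom)) {
      rc <- r[r$chrom == chrom, ]
      rc <- rc[order(rc$start), ]
      if (nrow(rc) > 1)
        expect_true(all(rc$start[-1] > rc$end[-nrow(rc)]))
    }
    # every member list contains the genes of the qualifying run
    for (i in seq_len(nrow(r)))
      expect_true(all(r$position_genes[[i]] %in% r$member_genes[[i]]))
  }
  # both kinds together never overlap
  expect_true(interval_jaccard(fit$regions[fit$regions$kind == "RIDGE", ],
                               fit$regions[fit$regions$kind == "ANTIRIDGE", ])
              == 0)
})

test_that("BED export uses 0-based half-open coordinates and sorted rows", {
  regions <- data.frame(chrom = c("chr1", "chr1", "chr2"),
                        start = c(5000, 100, 700), end = c(6000, 400, 900),
                        kind = c("ANTIRIDGE", "RIDGE", "RIDGE"),
                        n_gene_positions = c(11L, 12L, 13L))
  f <- tempfile(fileext = ".bed")
  write_regions_bed(regions, f)
  lines <- readLines(f)
  expect_match(lines[1], "^track")
  expect_equal(lines[2], "chr1\t99\t400\tRIDGE_1\t12\t.")
  # BED span equals end - start + 1 of the internal interval
  parts <- strsplit(lines[-1], "\t")
  spans <- vapply(parts, function(p) as.numeric(p[3]) - as.numeric(p[2]),
                  numeric(1))
  expect_equal(sort(spans), sort(regions$end - regions$start + 1))
  back <- read_regions_bed(f)
  expect_equal(back$start, c(100, 5000, 700))
  expect_equal(back$end, c(400, 6000, 900))
  expect_equal(back$kind, c("RIDGE", "ANTIRIDGE", "RIDGE"))
  expect_equal(back$n_gene_positions, c(12L, 11L, 13L))
})

test_that("an empty region set writes just the track header", {
  f <- tempfile(fileext = ".bed")
  write_regions_bed(data.frame(chrom = character(0), start = numeric(0),
                               end = numeric(0), kind = character(0),
                               n_gene_positions = integer(0)), f)
  expect_length(readLines(f), 1)
  expect_equal(nrow(read_regions_bed(f)), 0)
})
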