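test_that("TSV annotation rows parse to gene models", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tchrom\tstart\tend\tstrand\tgc_fraction",
               "g1\tchr1\t100\t400\t+\t0.52"), f)
  ann <- read_annotation(f)
  expect_equal(ann$genes$start, 100)
  expect_equal(ann$genes$end, 400)
  expect_equal(ann$genes$gc_fraction, 0.52)
  expect_equal(ann$genes$strand, "+")
  # default transcript spans the gene
  expect_equal(ann$transcripts$g1[[1]][1, ], c(start = 100, end = 400))
})

test_that("gene order breaks ties by end then gene id", {
  g <- data.frame(gene_id = c("b", "a", "c"), chrom = "chr1",
                  start = c(100, 100, 100), end = c(300, 500, 300),
                  strand = "+", gc_fraction = NA)
  ann <- gene_annotation(g)
  # equal start: order by end (b/c before a), then id (b before c)
  expect_equal(ann$order$chr1, c("b", "c", "a"))
})

test_that("malformed records are rejected with a warning; duplicates error", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tchrom\tstart\tend\tstrand\tgc_fraction",
               "g1\tchr1\t100\t400\t+\t0.5",
               "g2\tchr1\t900\t500\t+\t0.5"), f)
  expect_warning(ann <- read_annotation(f), "malformed")
  expect_equal(ann$genes$gene_id, "g1")
  g <- data.frame(gene_id = c("g1", "g1"), chrom = "chr1",
                  start = c(1, 50), end = c(10, 60), strand = "+",
                  gc_fraction = 0.5)
  expect_error(gene_annotation(g), "duplicate")
})

test_that("GFF3 with gene/mRNA/exons yields the transcript structure", {
  g <- data.frame(gene_id = c("g1", "g2"), chrom = "chr1",
                  start = c(100, 500), end = c(400, 900),
                  strand = c("+", "-"), gc_fraction = c(0.52, 0.4))
  tx <- list(g1 = list(cbind(start = c(100, 201), end = c(150, 400))))
  ann <- gene_annotation(g, tx, chrom_lengths = c(chr1 = 5000))
  f <- tempfile(fileext = ".gff3")
  write_annotation(ann, f, format = "gff3")
  ann2 <- read_annotation(f)
  expect_equal(nrow(ann2$genes), 2)
  expect_equal(nrow(ann2$transcripts$g1[[1]]), 2)
  expect_equal(unname(ann2$transcripts$g1[[1]][, "start"]), c(100, 201))
  expect_equal(ann2$genes["g1", "gc_fraction"], 0.52)
  expect_equal(unname(ann2$chrom_lengths["chr1"]), 5000)
})

test_that("annotation TSV write/read round trip is lossless", {
  sim <- simulate_genome(n_chrom = 2, genes_per_chrom = 40, seed = 5)
  f <- tempfile(fileext = ".tsv")
  write_annotation(sim$annotation, f)
  back <- read_annotation(f)
  expect_equal(back$genes, sim$annotation$genes, tolerance = 1e-10)
  expect_equal(back$transcripts, sim$annotation$transcripts)
  expect_equal(back$chrom_lengths, sim$annotation$chrom_lengths)
  expect_equal(back$order, sim$annotation$order)
})

test_that("chromosome lengths default to the maximum gene end", {
  g <- data.frame(gene_id = c("g1", "g2"), chrom = c("chr1", "chr2"),
                  start = c(1, 10), end = c(100, 250), strand = "+",
                  gc_fraction = 0.5)
  ann <- gene_annotation(g)
  expect_equal(ann$chrom_lengths, c(chr1 = 100, chr2 = 250))
})

test_that("exons outside the gene interval are rejected", {
  g <- data.frame(gene_id = "g1", chrom = "chr1", start = 100, end = 200,
                  strand = "+", gc_fraction = 0.5)
  expect_error(
    gene_annotation(g, list(g1 = list(cbind(start = 50, end = 150)))),
    "outside")
})
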