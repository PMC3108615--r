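# Independent oracles and fixture builders used across the suite.

# brute-force running median: explicit symmetric shrinking windows,
# median of an even-size set = mean of the two central order statistics
brute_running_median <- function(x, w) {
  n <- length(x)
  if (n == 0) return(numeric(0))
  h <- (w - 1) / 2
  vapply(seq_len(n), function(i) {
    hi <- min(i - 1, n - i, h)
    win <- sort(x[(i - hi):(i + hi)])
    k <- length(win)
    if (k %% 2 == 1) win[(k + 1) / 2] else mean(win[k / 2 + 0:1])
  }, numeric(1))
}

# bp-level Jaccard between two interval sets (data.frames chrom/start/end);
# intervals within each set are assumed disjoint
interval_jaccard <- function(a, b) {
  inter <- 0
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      if (a$chrom[i] == b$chrom[j])
        inter <- inter +
          max(0, min(a$end[i], b$end[j]) - max(a$start[i], b$start[j]) + 1)
    }
  }
  ua <- sum(a$end - a$start + 1)
  ub <- sum(b$end - b$start + 1)
  inter / (ua + ub - inter)
}

# exhaustive Fisher's exact test for a 2 x c table: enumerate every first row
# compatible with the margins; two-sided p sums the probabilities of tables
# no more probable than the observed one
brute_fisher <- function(tab) {
  cs <- colSums(tab)
  r1 <- sum(tab[1, ])
  n <- sum(tab)
  rows <- expand.grid(lapply(cs, function(cj) 0:cj))
  rows <- rows[rowSums(rows) == r1, , drop = FALSE]
  logp <- apply(rows, 1, function(a) sum(lchoose(cs, a)) - lchoose(n, r1))
  logp_obs <- sum(lchoose(cs, tab[1, ])) - lchoose(n, r1)
  sum(exp(logp)[exp(logp) <= exp(logp_obs) * (1 + 1e-7)])
}

# tiny deterministic annotation: n genes of width `gene_width` bp laid
# end-to-end on one chromosome, single-exon transcripts
toy_annotation <- function(n = 30, chrom = "chr1", gene_width = 10,
                           chrom_length = NULL) {
  starts <- (seq_len(n) - 1) * gene_width + 1
  g <- data.frame(gene_id = sprintf("%s_g%03d", chrom, seq_len(n)),
                  chrom = chrom, start = starts,
                  end = starts + gene_width - 1, strand = "+",
                  gc_fraction = 0.5, stringsAsFactors = FALSE)
  gene_annotation(g, chrom_lengths = stats::setNames(
    chrom_length %||% (n * gene_width), chrom))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# expression matrix with a single tissue holding the given per-gene values
toy_expression <- function(ann, values, tissue = "T1", controls = numeric(0)) {
  ids <- ann$genes$gene_id
  stopifnot(length(values) == length(ids))
  expression_matrix(matrix(values, ncol = 1,
                           dimnames = list(ids, tissue)),
                    negative_controls = controls)
}
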