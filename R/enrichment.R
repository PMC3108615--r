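#' Resampling test for gene-set overlap with region genes
#'
#' Tests whether a query gene set (e.g. the housekeeping genes) overlaps the
#' RIDGE gene set more (or less) than expected. Each of `n_samp` replicates
#' draws `|query|` genes from the universe **without replacement** and records
#' the percentage falling in the region gene set; the observed percentage is
#' compared against this Monte-Carlo null. Sampling without replacement makes
#' the null exactly hypergeometric, with standard deviation
#' `100 * sqrt(p (1 - p) / n * (N - n) / (N - 1))` for region fraction `p`,
#' draw size `n` and universe size `N`.
#'
#' Empirical p-values use the add-one correction:
#' enrichment `(#\{null >= observed\} + 1) / (n_samp + 1)`, depletion with
#' `<=`. The reported `direction` and `p` follow the sign of the deviation
#' from the null mean.
#'
#' @param query Character vector of gene ids, a subset of `universe`.
#' @param region_genes Character vector of gene ids in regions (ids outside
#'   the universe are ignored).
#' @param universe Character vector of all candidate gene ids.
#' @param n_samp Number of resampling replicates (study default 10,000).
#' @param seed Optional integer seed.
#' @return An object of class `overlap_test`: list with `observed_percent`,
#'   `null_mean`, `null_sd`, `direction` (`"enrichment"`/`"depletion"`),
#'   `p`, `p_enrich`, `p_deplete`, `n_samp`, `values` (the replicate
#'   percentages) and the set sizes.
#' @export
overlap_resampling_test <- function(query, region_genes, universe,
                                    n_samp = 10000L, seed = NULL) {
  query <- unique(as.character(query))
  universe <- unique(as.character(universe))
  region_genes <- unique(as.character(region_genes))
  if (!length(query)) stopf("`query` must be non-empty")
  extra <- setdiff(query, universe)
  if (length(extra))
    stopf("%d query gene(s) are not in the universe (e.g. %s)",
          length(extra), extra[1])
  if (length(query) > length(universe))
    stopf("query larger than universe")
  n_samp <- as.integer(n_samp)
  if (is.na(n_samp) || n_samp < 1L) stopf("`n_samp` must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  in_region <- universe %in% region_genes
  n <- length(query)
  N <- length(universe)
  observed <- 100 * sum(query %in% region_genes) / n
  vals <- numeric(n_samp)
  for (b in seq_len(n_samp)) {
    vals[b] <- 100 * sum(in_region[sample.int(N, n)]) / n
  }
  ge <- sum(vals >= observed)
  le <- sum(vals <= observed)
  p_enrich <- (ge + 1) / (n_samp + 1)
  p_deplete <- (le + 1) / (n_samp + 1)
  nm <- mean(vals)
  direction <- if (observed >= nm) "enrichment" else "depletion"
  structure(list(observed_percent = observed, null_mean = nm,
                 null_sd = stats::sd(vals), direction = direction,
                 p = if (direction == "enrichment") p_enrich else p_deplete,
                 p_enrich = p_enrich, p_deplete = p_deplete,
                 n_samp = n_samp, values = vals,
                 n_query = n, n_universe = N,
                 n_region = sum(in_region)),
            class = "overlap_test")
}

#' @export
print.overlap_test <- function(x, ...) {
  cat(sprintf("Gene-set overlap test (%d of %d universe genes in regions):\n",
              x$n_region, x$n_universe))
  cat(sprintf("  observed %.2f%% of %d genes in regions; null mean %.2f%% (s.d. = %.2f) over %d draws\n",
              x$observed_percent, x$n_query, x$null_mean, x$null_sd, x$n_samp))
  cat(sprintf("  %s p = %.4g\n", x$direction, x$p))
  invisible(x)
}

#' Assign genes to region categories
#'
#' Each gene is `RIDGE` or `ANTIRIDGE` when its interval overlaps a region of
#' that kind by at least 1 bp, otherwise `INTERMEDIATE`. A gene overlapping
#' regions of both kinds (possible only when gene spans straddle adjacent
#' regions) takes the kind with the larger bp overlap. Genes on chromosomes
#' that carry no transcriptome map are `INTERMEDIATE` with a warning.
#'
#' @param genes A `gene_annotation`, or a data.frame with columns `gene_id`,
#'   `chrom`, `start`, `end`.
#' @param regions A `region_calls` data.frame (kinds disjoint).
#' @return Named character vector (by gene id) with values `RIDGE`,
#'   `ANTIRIDGE` or `INTERMEDIATE`.
#' @export
assign_region_category <- function(genes, regions) {
  g <- if (inherits(genes, "gene_annotation")) genes$genes else genes
  map_chroms <- attr(regions, "map_chroms")
  out <- rep("INTERMEDIATE", nrow(g))
  names(out) <- g$gene_id
  if (!is.null(map_chroms)) {
    off_map <- !g$chrom %in% map_chroms
    if (any(off_map))
      warnf("%d gene(s) lie on chromosomes without a map; categorised INTERMEDIATE",
            sum(off_map))
  }
  if (!nrow(regions)) return(out)
  for (i in seq_len(nrow(g))) {
    r <- regions[regions$chrom == g$chrom[i], , drop = FALSE]
    if (!nrow(r)) next
    ov <- interval_overlap_bp(g$start[i], g$end[i], r$start, r$end)
    if (!any(ov > 0)) next
    by_kind <- tapply(ov, r$kind, sum)
    by_kind <- by_kind[by_kind > 0]
    out[i] <- names(by_kind)[which.max(by_kind)]
  }
  out
}

#' Fisher's exact test of region-category distribution
#'
#' Tests whether a query gene list (e.g. positively selected genes) is
#' distributed across the `RIDGE` / `ANTIRIDGE` / `INTERMEDIATE` categories
#' differently from the rest of the background universe. The primary
#' statistic is the exact p of the 2x3 table (query vs background-minus-query
#' by category); the 2x2 collapse (anti-RIDGE vs rest) is reported as a
#' secondary statistic. Degenerate tables (an empty row or column margin
#' after removing all-zero categories) give p = 1 with a warning.
#'
#' @param query_categories Character vector of categories for the query genes
#'   (values among `RIDGE`, `ANTIRIDGE`, `INTERMEDIATE`), e.g. from
#'   [assign_region_category()].
#' @param background_categories Categories for the background universe,
#'   *including* the query genes (they are subtracted to form the second
#'   row).
#' @return An object of class `region_distribution_test`: list with `table`
#'   (2x3 counts), `p` (2x3 exact), `p_antiridge_vs_rest` (2x2 exact),
#'   `counts` (query counts per category).
#' @export
fisher_region_distribution <- function(query_categories,
                                       background_categories) {
  lev <- c("RIDGE", "ANTIRIDGE", "INTERMEDIATE")
  q <- table(factor(query_categories, levels = lev))
  u <- table(factor(background_categories, levels = lev))
  bg <- u - q
  if (any(bg < 0))
    stopf("background must include the query genes (negative cell after subtraction)")
  tab <- rbind(query = as.integer(q), background = as.integer(bg))
  colnames(tab) <- lev
  keep <- colSums(tab) > 0
  p <- NA_real_
  if (sum(keep) < 2L || any(rowSums(tab) == 0)) {
    warnf("degenerate margins in region-distribution table; p set to 1")
    p <- 1
  } else {
    p <- stats::fisher.test(tab[, keep, drop = FALSE])$p.value
  }
  tab2 <- cbind(ANTIRIDGE = tab[, "ANTIRIDGE"],
                rest = tab[, "RIDGE"] + tab[, "INTERMEDIATE"])
  p2 <- if (any(rowSums(tab2) == 0) || any(colSums(tab2) == 0)) 1
        else stats::fisher.test(tab2)$p.value
  structure(list(table = tab, p = p, p_antiridge_vs_rest = p2,
                 counts = q),
            class = "region_distribution_test")
}

#' @export
print.region_distribution_test <- function(x, ...) {
  cat("Region distribution of query genes vs background:\n")
  print(x$table)
  cat(sprintf("  Fisher exact p (2x3) = %.4g; anti-RIDGE vs rest (2x2) p = %.4g\n",
              x$p, x$p_antiridge_vs_rest))
  invisible(x)
}
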