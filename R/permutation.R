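#' Position-permutation null for the region count
#'
#' Tests whether the observed number of RIDGEs (or anti-RIDGEs) exceeds
#' chance expectation. Gene positions stay fixed; each permutation reassigns
#' the per-gene expression values uniformly at random to the positions
#' genome-wide, rebuilds the running-median map per chromosome with the same
#' window, and re-calls regions with the same fold threshold and minimum
#' stretch as the observed scan. The genomic median is unchanged by
#' permutation (same value multiset), so the threshold is held fixed.
#'
#' The empirical p-value for observing at least the actual region count is
#' reported both with the add-one correction,
#' `(#\{null >= observed\} + 1) / (n_perm + 1)`, and as the plain proportion
#' `#\{null >= observed\} / n_perm`.
#'
#' @param scan A [ridge_scan()] fit; its map, thresholds, window and minimum
#'   stretch define the analysis being permuted.
#' @param direction `"up"` (RIDGE count) or `"down"` (anti-RIDGE count).
#' @param n_perm Number of permutations (study default 10,000).
#' @param seed Optional integer seed for the permutation stream.
#' @return An object of class `null_distribution`: list with `values` (the
#'   per-permutation region counts), `n_perm`, `observed`, `mean`, `sd`
#'   (denominator `n - 1`), `p` (add-one) and `p_plain`.
#' @export
permutation_test <- function(scan, direction = c("up", "down"),
                             n_perm = 10000L, seed = NULL) {
  direction <- match.arg(direction)
  stopifnot(inherits(scan, "ridge_scan"))
  n_perm <- as.integer(n_perm)
  if (is.na(n_perm) || n_perm < 1L) stopf("`n_perm` must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  kind <- if (direction == "up") "RIDGE" else "ANTIRIDGE"
  fold <- if (direction == "up") scan$fold_up else scan$fold_down
  thr <- fold_threshold(scan$genomic_median, fold, direction, scan$fold_scale)
  above <- direction == "up"
  k <- scan$min_stretch
  w <- scan$window
  values <- unlist(lapply(scan$map$chroms, `[[`, "raw"), use.names = FALSE)
  sizes <- vapply(scan$map$chroms, function(ch) length(ch$raw), integer(1))
  stops <- cumsum(sizes)
  starts <- stops - sizes + 1L
  observed <- sum(scan$regions$kind == kind)
  counts <- integer(n_perm)
  for (b in seq_len(n_perm)) {
    perm <- sample(values)
    total <- 0L
    for (ci in seq_along(sizes)) {
      sm <- running_median(perm[starts[ci]:stops[ci]], w)
      qual <- if (above) sm > thr else sm < thr
      r <- rle(qual)
      total <- total + sum(r$values & r$lengths >= k)
    }
    counts[b] <- total
  }
  ge <- sum(counts >= observed)
  structure(list(statistic = "region_count", direction = direction,
                 kind = kind, n_perm = n_perm, observed = observed,
                 values = counts, mean = mean(counts),
                 sd = stats::sd(counts),
                 p = (ge + 1) / (n_perm + 1), p_plain = ge / n_perm),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("Permutation null (%s, %s): observed %d, null mean %.2f, s.d. %.2f over %d permutations\n",
              x$statistic, x$kind, x$observed, x$mean, x$sd, x$n_perm))
  cat(sprintf("  empirical p (add-one) = %.4g; plain proportion = %.4g\n",
              x$p, x$p_plain))
  invisible(x)
}
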