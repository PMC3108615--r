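#' Expression threshold from negative controls
#'
#' The threshold above which a gene counts as expressed is a high quantile
#' (study default 99.9%) of the negative-control log-intensities, computed by
#' linear interpolation of order statistics: with sorted controls
#' `x(1..n)` and `h = (n - 1) q + 1`, the threshold is
#' `x(floor(h)) + (h - floor(h)) * (x(floor(h) + 1) - x(floor(h)))`
#' (the type-7 quantile).
#'
#' @param controls Non-empty numeric vector of control log-intensities.
#' @param q Quantile in (0, 1), default 0.999.
#' @return The threshold, a scalar.
#' @export
#' @examples
#' expression_threshold(1:1000, 0.999)  # 999.001
expression_threshold <- function(controls, q = 0.999) {
  controls <- as.numeric(controls)
  if (!length(controls)) stopf("`controls` must be non-empty")
  if (any(!is.finite(controls))) stopf("`controls` must be finite")
  if (!is_scalar_number(q) || q <= 0 || q >= 1)
    stopf("`q` must lie in (0, 1)")
  stats::quantile(controls, probs = q, type = 7, names = FALSE)
}

#' Classify genes as housekeeping / tissue-specific / intermediate / silent
#'
#' A gene is expressed in a tissue when its value is strictly above the
#' threshold. Genes expressed in all tissues of the panel are housekeeping
#' (HK), in exactly one tissue tissue-specific (TS), in none silent, and
#' otherwise intermediate. The labels are explicitly relative to the supplied
#' tissue panel.
#'
#' @param expr An [expression_matrix()].
#' @param tau Expression threshold, typically from [expression_threshold()].
#' @return An object of class `expression_classes`: a data.frame with one row
#'   per gene (`gene_id`, `n_expressed`, `class`, `ts_tissue` — the tissue of
#'   a TS gene, otherwise `NA`) and attributes `tau` and `tissues`.
#' @export
classify_genes <- function(expr, tau) {
  stopifnot(inherits(expr, "expression_matrix"))
  if (!is_scalar_number(tau)) stopf("`tau` must be a finite scalar")
  expressed <- expr$values > tau
  n_exp <- rowSums(expressed)
  n_tis <- ncol(expr$values)
  cls <- ifelse(n_exp == n_tis, "HK",
                ifelse(n_exp == 1L, "TS",
                       ifelse(n_exp == 0L, "silent", "intermediate")))
  ts_tissue <- rep(NA_character_, nrow(expr$values))
  is_ts <- cls == "TS"
  if (any(is_ts))
    ts_tissue[is_ts] <- colnames(expr$values)[
      apply(expressed[is_ts, , drop = FALSE], 1, which.max)]
  out <- data.frame(gene_id = rownames(expr$values),
                    n_expressed = as.integer(n_exp),
                    class = cls, ts_tissue = ts_tissue,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("expression_classes", "data.frame"),
            tau = tau, tissues = colnames(expr$values))
}

#' @export
summary.expression_classes <- function(object, ...) {
  counts <- table(factor(object$class,
                         levels = c("HK", "TS", "intermediate", "silent")))
  ts_by_tissue <- table(object$ts_tissue[object$class == "TS"])
  structure(list(tau = attr(object, "tau"), counts = counts,
                 ts_by_tissue = ts_by_tissue, total = nrow(object)),
            class = "summary.expression_classes")
}

#' @export
print.summary.expression_classes <- function(x, ...) {
  cat(sprintf("Expression classes at threshold %.4g (%d genes):\n",
              x$tau, x$total))
  print(x$counts)
  if (length(x$ts_by_tissue)) {
    cat("TS genes per tissue:\n")
    print(x$ts_by_tissue)
  }
  invisible(x)
}
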