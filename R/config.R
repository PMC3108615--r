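#' Pipeline configuration
#'
#' Collects every tunable of the region-detection pipeline in one validated
#' object. Defaults are the settings of the bovine brain study design this
#' package implements: a 39-gene running-median window, regions of at least 10
#' consecutive qualifying gene positions, fold thresholds 1.25 (up) and 1.45
#' (down) around the genomic median, a 10% genome-coverage target for
#' calibration, a 99.9% negative-control quantile expression threshold, and
#' 10,000 replicates for both the position-permutation null and the gene-set
#' resampling null.
#'
#' @param window Odd integer, running-median window in gene positions.
#' @param min_stretch Minimum number of consecutive qualifying gene positions
#'   for a region call.
#' @param coverage_target Genome fraction each region kind should cover when
#'   thresholds are calibrated, in (0, 1).
#' @param fold_up,fold_down Fold thresholds (> 1) applied to the genomic
#'   median: positions qualify as RIDGE when smoothed value exceeds
#'   `median * fold_up`, as anti-RIDGE when below `median / fold_down`
#'   (multiplicative scale; see `fold_scale`).
#' @param control_quantile Quantile of the negative-control intensities used
#'   as the expression threshold, in (0, 1).
#' @param n_perm Number of position permutations for the region-count null.
#' @param n_samp Number of gene-set resampling replicates.
#' @param seed Integer seed driving every stochastic stage of
#'   [run_ridge_pipeline()].
#' @param calibrate Logical; when `TRUE` the fold thresholds are re-calibrated
#'   to `coverage_target` before calling regions.
#' @param fold_step,fold_max Calibration grid: folds
#'   `1 + fold_step, 1 + 2*fold_step, ..., fold_max`.
#' @param fold_scale `"multiplicative"` applies the fold directly to the
#'   (log-scale) genomic median; `"additive"` adds/subtracts `log2(fold)`,
#'   i.e. a true fold change on raw intensities expressed in log2 units.
#' @param coverage_unit `"bp"` measures coverage in base pairs of called
#'   regions over total chromosome length; `"genes"` in qualifying gene
#'   positions over mapped genes (sensitivity analysis).
#' @param tissue Tissue used for the map: a tissue name or `"average"`.
#'
#' @return An object of class `ridge_config` (a validated named list).
#' @seealso [read_ridge_config()] to load the same fields from YAML.
#' @export
#' @examples
#' cfg <- ridge_config(n_perm = 100, n_samp = 100)
#' cfg$window
ridge_config <- function(window = 39L, min_stretch = 10L,
                         coverage_target = 0.10,
                         fold_up = 1.25, fold_down = 1.45,
                         control_quantile = 0.999,
                         n_perm = 10000L, n_samp = 10000L,
                         seed = 1L, calibrate = TRUE,
                         fold_step = 0.01, fold_max = 3,
                         fold_scale = c("multiplicative", "additive"),
                         coverage_unit = c("bp", "genes"),
                         tissue = "average") {
  fold_scale <- match.arg(fold_scale)
  coverage_unit <- match.arg(coverage_unit)
  window <- as.integer(window)
  min_stretch <- as.integer(min_stretch)
  if (is.na(window) || window < 1L || window %% 2L == 0L)
    stopf("`window` must be an odd integer >= 1, got %s", window)
  if (is.na(min_stretch) || min_stretch < 1L)
    stopf("`min_stretch` must be a positive integer")
  if (!is_scalar_number(coverage_target) ||
      coverage_target <= 0 || coverage_target >= 1)
    stopf("`coverage_target` must lie in (0, 1)")
  if (!is_scalar_number(fold_up) || fold_up <= 1)
    stopf("`fold_up` must be > 1")
  if (!is_scalar_number(fold_down) || fold_down <= 1)
    stopf("`fold_down` must be > 1")
  if (!is_scalar_number(control_quantile) ||
      control_quantile <= 0 || control_quantile >= 1)
    stopf("`control_quantile` must lie in (0, 1)")
  n_perm <- as.integer(n_perm)
  n_samp <- as.integer(n_samp)
  if (is.na(n_perm) || n_perm < 1L) stopf("`n_perm` must be >= 1")
  if (is.na(n_samp) || n_samp < 1L) stopf("`n_samp` must be >= 1")
  if (!is_scalar_number(fold_step) || fold_step <= 0)
    stopf("`fold_step` must be > 0")
  if (!is_scalar_number(fold_max) || fold_max <= 1 + fold_step)
    stopf("`fold_max` must exceed 1 + fold_step")
  cfg <- list(window = window, min_stretch = min_stretch,
              coverage_target = coverage_target,
              fold_up = fold_up, fold_down = fold_down,
              control_quantile = control_quantile,
              n_perm = n_perm, n_samp = n_samp,
              seed = as.integer(seed), calibrate = isTRUE(calibrate),
              fold_step = fold_step, fold_max = fold_max,
              fold_scale = fold_scale, coverage_unit = coverage_unit,
              tissue = tissue)
  class(cfg) <- "ridge_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' The file holds any subset of the fields of [ridge_config()]; missing fields
#' take their defaults, unknown fields are an error.
#'
#' @param path Path to a YAML file.
#' @return A `ridge_config` object.
#' @export
read_ridge_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  vals <- yaml::read_yaml(path)
  if (!is.list(vals)) stopf("config file %s does not hold a mapping", path)
  known <- names(formals(ridge_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stopf("unknown config field(s) in %s: %s", path, paste(bad, collapse = ", "))
  do.call(ridge_config, vals)
}

#' @export
print.ridge_config <- function(x, ...) {
  cat("Pipeline configuration\n")
  cat(sprintf("  window %d | min stretch %d | folds up %.3g / down %.3g (%s)\n",
              x$window, x$min_stretch, x$fold_up, x$fold_down, x$fold_scale))
  cat(sprintf("  calibrate %s to coverage %.3g (%s), grid step %.3g up to %.3g\n",
              x$calibrate, x$coverage_target, x$coverage_unit,
              x$fold_step, x$fold_max))
  cat(sprintf("  control quantile %.4g | n_perm %d | n_samp %d | seed %d | tissue %s\n",
              x$control_quantile, x$n_perm, x$n_samp, x$seed, x$tissue))
  invisible(x)
}
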