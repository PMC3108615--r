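#' Detect RIDGEs and anti-RIDGEs from an expression matrix
#'
#' The central estimator of the package. It builds a gene-ordered
#' running-median transcriptome map ([build_map()]), takes the genomic median
#' of the mapped genes as reference level, optionally calibrates the two fold
#' thresholds so each region kind covers a target fraction of the genome
#' ([calibrate_fold()]), and calls regions of increased (RIDGE) and decreased
#' (anti-RIDGE) expression as maximal runs of at least `min_stretch`
#' qualifying gene positions ([call_regions()]).
#'
#' @inheritParams build_map
#' @inheritParams call_regions
#' @param fold_up,fold_down Fold thresholds used when `calibrate = FALSE`
#'   (study values 1.25 and 1.45; the asymmetry is a consequence of coverage
#'   calibration, not a choice).
#' @param calibrate When `TRUE`, `fold_up` and `fold_down` are replaced by the
#'   grid folds whose coverage is closest to `coverage_target` per direction.
#' @param coverage_target,fold_step,fold_max Calibration settings, see
#'   [calibrate_fold()].
#' @param coverage_unit `"bp"` (genome length, default) or `"genes"`.
#' @return An object of class `ridge_scan` with elements `map`,
#'   `genomic_median`, `fold_up`, `fold_down`, `calibration` (list of
#'   `fold_calibration` objects or `NULL`), `regions` (a `region_calls`
#'   data.frame holding both kinds), `coverage` (named fractions per kind),
#'   `n_map_genes`, `chrom_lengths` and the call parameters.
#' @seealso [permutation_test()] for the chance expectation of the region
#'   count, [plot.ridge_scan()] for per-chromosome maps.
#' @export
#' @examples
#' sim <- simulate_genome(n_chrom = 2, genes_per_chrom = 150, seed = 1)
#' expr <- simulate_expression(sim$annotation, sim$truth, seed = 2)
#' fit <- ridge_scan(expr, sim$annotation, calibrate = TRUE)
#' fit
ridge_scan <- function(expr, annotation, tissue = "average", window = 39L,
                       min_stretch = 10L, fold_up = 1.25, fold_down = 1.45,
                       calibrate = FALSE, coverage_target = 0.10,
                       fold_step = 0.01, fold_max = 3,
                       fold_scale = c("multiplicative", "additive"),
                       coverage_unit = c("bp", "genes")) {
  fold_scale <- match.arg(fold_scale)
  coverage_unit <- match.arg(coverage_unit)
  map <- build_map(expr, annotation, tissue = tissue, window = window)
  m <- genomic_median(map)
  n_pos <- sum(vapply(map$chroms, function(ch) length(ch$raw), integer(1)))
  calibration <- NULL
  if (isTRUE(calibrate)) {
    cal_up <- calibrate_fold(map, m, "up", target = coverage_target,
                             step = fold_step, fold_max = fold_max,
                             min_stretch = min_stretch,
                             fold_scale = fold_scale, unit = coverage_unit)
    cal_down <- calibrate_fold(map, m, "down", target = coverage_target,
                               step = fold_step, fold_max = fold_max,
                               min_stretch = min_stretch,
                               fold_scale = fold_scale, unit = coverage_unit)
    fold_up <- cal_up$fold
    fold_down <- cal_down$fold
    calibration <- list(up = cal_up, down = cal_down)
  }
  reg_up <- call_regions(map, m, fold_up, "up", min_stretch,
                         annotation = annotation, fold_scale = fold_scale)
  reg_down <- call_regions(map, m, fold_down, "down", min_stretch,
                           annotation = annotation, fold_scale = fold_scale)
  regions <- rbind(reg_up, reg_down)
  regions <- regions[order(regions$chrom, regions$start), , drop = FALSE]
  rownames(regions) <- NULL
  class(regions) <- c("region_calls", "data.frame")
  attr(regions, "map_chroms") <- names(map$chroms)
  coverage <- c(
    RIDGE = region_coverage(reg_up, map$chrom_lengths,
                            unit = coverage_unit, n_positions = n_pos),
    ANTIRIDGE = region_coverage(reg_down, map$chrom_lengths,
                                unit = coverage_unit, n_positions = n_pos))
  structure(list(map = map, genomic_median = m,
                 fold_up = fold_up, fold_down = fold_down,
                 calibration = calibration, regions = regions,
                 coverage = coverage, n_map_genes = n_pos,
                 chrom_lengths = map$chrom_lengths,
                 tissue = tissue, window = as.integer(window),
                 min_stretch = as.integer(min_stretch),
                 fold_scale = fold_scale, coverage_unit = coverage_unit,
                 calibrated = isTRUE(calibrate)),
            class = "ridge_scan")
}

# region subset helpers
scan_kind <- function(x, kind) x$regions[x$regions$kind == kind, , drop = FALSE]

#' Member genes of one region kind
#'
#' Union of the member gene ids over all regions of the given kind.
#'
#' @param x A `ridge_scan` object.
#' @param kind `"RIDGE"` or `"ANTIRIDGE"`.
#' @return Character vector of gene ids.
#' @export
region_genes <- function(x, kind = c("RIDGE", "ANTIRIDGE")) {
  kind <- match.arg(kind)
  unique(unlist(scan_kind(x, kind)$member_genes, use.names = FALSE))
}

#' @export
print.ridge_scan <- function(x, ...) {
  n_up <- sum(x$regions$kind == "RIDGE")
  n_down <- sum(x$regions$kind == "ANTIRIDGE")
  cat(sprintf("RIDGE scan (%s tissue, window %d, min stretch %d)\n",
              x$tissue, x$window, x$min_stretch))
  cat(sprintf("  genomic median %.4g; folds%s: up %.4g, down %.4g (%s)\n",
              x$genomic_median,
              if (x$calibrated) " (calibrated)" else "",
              x$fold_up, x$fold_down, x$fold_scale))
  cat(sprintf("  %d RIDGEs (%d genes, coverage %.3f) | %d anti-RIDGEs (%d genes, coverage %.3f)\n",
              n_up, length(region_genes(x, "RIDGE")), x$coverage[["RIDGE"]],
              n_down, length(region_genes(x, "ANTIRIDGE")),
              x$coverage[["ANTIRIDGE"]]))
  invisible(x)
}

#' @export
summary.ridge_scan <- function(object, ...) {
  per_chrom <- do.call(rbind, lapply(names(object$map$chroms), function(chrom) {
    r <- object$regions[object$regions$chrom == chrom, ]
    data.frame(chrom = chrom,
               n_genes = length(object$map$chroms[[chrom]]$gene_id),
               n_ridge = sum(r$kind == "RIDGE"),
               n_antiridge = sum(r$kind == "ANTIRIDGE"),
               stringsAsFactors = FALSE)
  }))
  structure(list(scan = object, per_chrom = per_chrom),
            class = "summary.ridge_scan")
}

#' @export
print.summary.ridge_scan <- function(x, ...) {
  print(x$scan)
  cat("\nPer-chromosome region counts:\n")
  print(x$per_chrom, row.names = FALSE)
  invisible(x)
}

#' @export
coef.ridge_scan <- function(object, ...) {
  c(genomic_median = object$genomic_median,
    fold_up = object$fold_up, fold_down = object$fold_down)
}

#' @export
as.data.frame.ridge_scan <- function(x, ...) {
  as.data.frame.data.frame(x$regions)
}

#' Plot per-chromosome transcriptome maps with called regions
#'
#' Draws the smoothed running-median profile along each requested chromosome,
#' the two fold thresholds (dashed), and shades the called RIDGEs (red) and
#' anti-RIDGEs (blue).
#'
#' @param x A `ridge_scan` object.
#' @param chrom Chromosomes to draw (default: all, one panel each).
#' @param ... Further arguments passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.ridge_scan <- function(x, chrom = NULL, ...) {
  chroms <- chrom %||% names(x$map$chroms)
  old <- graphics::par(mfrow = c(length(chroms), 1),
                       mar = c(3.5, 4, 2, 1))
  on.exit(graphics::par(old))
  thr_up <- fold_threshold(x$genomic_median, x$fold_up, "up", x$fold_scale)
  thr_down <- fold_threshold(x$genomic_median, x$fold_down, "down",
                             x$fold_scale)
  for (ch_name in chroms) {
    ch <- x$map$chroms[[ch_name]]
    if (is.null(ch)) stopf("no map for chromosome '%s'", ch_name)
    graphics::plot(ch$start / 1e6, ch$smoothed, type = "l",
                   xlab = "position (Mb)", ylab = "running median",
                   main = ch_name,
                   ylim = range(c(ch$smoothed, thr_up, thr_down)), ...)
    r <- x$regions[x$regions$chrom == ch_name, ]
    if (nrow(r)) {
      usr <- graphics::par("usr")
      cols <- ifelse(r$kind == "RIDGE",
                     grDevices::adjustcolor("red", 0.2),
                     grDevices::adjustcolor("blue", 0.2))
      graphics::rect(r$start / 1e6, usr[3], r$end / 1e6, usr[4],
                     col = cols, border = NA)
    }
    graphics::abline(h = c(thr_up, thr_down), lty = 2,
                     col = c("red", "blue"))
    graphics::abline(h = x$genomic_median, lty = 3)
  }
  invisible(x)
}
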