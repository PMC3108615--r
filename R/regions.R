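#' Genomic median expression
#'
#' Median of the per-gene raw (unsmoothed) values of all mapped genes
#' genome-wide, the reference level the fold thresholds multiply.
#'
#' @param x A `transcriptome_map` or a numeric vector of per-gene values.
#' @return A scalar median.
#' @export
genomic_median <- function(x) {
  v <- if (inherits(x, "transcriptome_map"))
    unlist(lapply(x$chroms, `[[`, "raw"), use.names = FALSE)
  else as.numeric(x)
  if (!length(v)) stopf("no mapped genes to take a median over")
  stats::median(v)
}

# threshold the smoothed values are compared against
fold_threshold <- function(m, fold, direction, fold_scale) {
  if (fold_scale == "multiplicative") {
    if (direction == "up") m * fold else m / fold
  } else {
    if (direction == "up") m + log2(fold) else m - log2(fold)
  }
}

#' Call RIDGEs or anti-RIDGEs on a transcriptome map
#'
#' A gene position qualifies when its smoothed value is strictly above
#' `m * fold` (direction `"up"`) or strictly below `m / fold` (`"down"`;
#' multiplicative scale — see `fold_scale`). Maximal runs of at least
#' `min_stretch` consecutive qualifying positions on one chromosome become
#' regions; a region's genomic interval spans from the smallest start to the
#' largest end of the genes at its qualifying positions. Member genes are all
#' annotation genes overlapping that interval by at least 1 bp.
#'
#' @param map A [build_map()] result.
#' @param m Genomic median (see [genomic_median()]).
#' @param fold Fold threshold, `> 1`.
#' @param direction `"up"` (RIDGE) or `"down"` (anti-RIDGE).
#' @param min_stretch Minimum qualifying run length in gene positions.
#' @param annotation Optional [gene_annotation()]; when supplied, each region
#'   carries its member gene list.
#' @param fold_scale `"multiplicative"` or `"additive"` (see [ridge_config()]).
#' @return A data.frame of class `region_calls` with columns `chrom`, `start`,
#'   `end` (1-based inclusive bp), `kind` (`RIDGE`/`ANTIRIDGE`),
#'   `n_gene_positions`, and list columns `position_genes` (genes of the
#'   qualifying run) and `member_genes`. May have zero rows.
#' @export
call_regions <- function(map, m, fold, direction = c("up", "down"),
                         min_stretch = 10L, annotation = NULL,
                         fold_scale = c("multiplicative", "additive")) {
  direction <- match.arg(direction)
  fold_scale <- match.arg(fold_scale)
  stopifnot(inherits(map, "transcriptome_map"))
  if (!is_scalar_number(fold) || fold <= 1) stopf("`fold` must be > 1")
  min_stretch <- as.integer(min_stretch)
  if (min_stretch < 1L) stopf("`min_stretch` must be >= 1")
  thr <- fold_threshold(m, fold, direction, fold_scale)
  kind <- if (direction == "up") "RIDGE" else "ANTIRIDGE"
  rows <- list()
  for (chrom in names(map$chroms)) {
    ch <- map$chroms[[chrom]]
    qual <- if (direction == "up") ch$smoothed > thr else ch$smoothed < thr
    runs <- runs_of_true(qual, min_stretch)
    for (r in seq_along(runs$start)) {
      idx <- runs$start[r]:runs$end[r]
      rows[[length(rows) + 1L]] <- list(
        chrom = chrom,
        start = min(ch$start[idx]), end = max(ch$end[idx]),
        n_gene_positions = length(idx),
        position_genes = ch$gene_id[idx])
    }
  }
  df <- if (length(rows)) {
    data.frame(chrom = vapply(rows, `[[`, character(1), "chrom"),
               start = vapply(rows, `[[`, numeric(1), "start"),
               end = vapply(rows, `[[`, numeric(1), "end"),
               kind = kind,
               n_gene_positions = vapply(rows, `[[`, integer(1),
                                         "n_gene_positions"),
               stringsAsFactors = FALSE)
  } else {
    data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
               kind = character(0), n_gene_positions = integer(0),
               stringsAsFactors = FALSE)
  }
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  ord_rows <- if (length(rows))
    order(vapply(rows, `[[`, character(1), "chrom"),
          vapply(rows, `[[`, numeric(1), "start"))
  else integer(0)
  df$position_genes <- I(lapply(rows[ord_rows], `[[`, "position_genes"))
  df$member_genes <- I(if (is.null(annotation)) {
    lapply(rows[ord_rows], `[[`, "position_genes")
  } else {
    lapply(seq_len(nrow(df)), function(i) {
      g <- annotation$genes
      hit <- g$chrom == df$chrom[i] & g$start <= df$end[i] & g$end >= df$start[i]
      g$gene_id[hit]
    })
  })
  rownames(df) <- NULL
  structure(df, class = c("region_calls", "data.frame"),
            direction = direction, fold = fold, genomic_median = m,
            fold_scale = fold_scale, threshold = thr,
            min_stretch = min_stretch,
            map_chroms = names(map$chroms))
}

#' Genome coverage of a region set
#'
#' Fraction of total chromosome length (in bp) spanned by the regions, or —
#' with `unit = "genes"` — the fraction of mapped gene positions inside
#' qualifying runs.
#'
#' @param regions A [call_regions()] result (regions of one kind must be
#'   disjoint, which the caller guarantees).
#' @param chrom_lengths Named numeric vector of chromosome lengths in bp.
#' @param unit `"bp"` or `"genes"`.
#' @param n_positions Total number of mapped gene positions (required for
#'   `unit = "genes"`).
#' @return Coverage fraction in `[0, 1]`.
#' @export
region_coverage <- function(regions, chrom_lengths, unit = c("bp", "genes"),
                            n_positions = NULL) {
  unit <- match.arg(unit)
  if (unit == "genes") {
    if (is.null(n_positions) || n_positions < 1)
      stopf("`n_positions` required for unit = \"genes\"")
    return(sum(regions$n_gene_positions) / n_positions)
  }
  total <- sum(as.numeric(chrom_lengths))
  if (!is.finite(total) || total <= 0) stopf("total genome length must be > 0")
  if (!nrow(regions)) return(0)
  sum(regions$end - regions$start + 1) / total
}

#' Calibrate a fold threshold to a genome-coverage target
#'
#' Evaluates region coverage on the grid of folds
#' `1 + step, 1 + 2*step, ..., fold_max` and returns the fold whose achieved
#' coverage is closest to `target`; ties go to the larger (more stringent)
#' fold. If no fold on the grid yields any region, the smallest grid fold is
#' returned with a warning.
#'
#' @inheritParams call_regions
#' @param target Coverage target in (0, 1), study default 0.10.
#' @param step,fold_max Grid step and upper end.
#' @param unit,n_positions See [region_coverage()].
#' @return An object of class `fold_calibration`: list with `direction`,
#'   `fold`, `coverage` (achieved at that fold), `target`, `step` and the full
#'   `grid` (data.frame of fold and coverage).
#' @export
calibrate_fold <- function(map, m, direction = c("up", "down"),
                           target = 0.10, step = 0.01, fold_max = 3,
                           min_stretch = 10L,
                           fold_scale = c("multiplicative", "additive"),
                           unit = c("bp", "genes")) {
  direction <- match.arg(direction)
  fold_scale <- match.arg(fold_scale)
  unit <- match.arg(unit)
  if (!is_scalar_number(target) || target <= 0 || target >= 1)
    stopf("`target` must lie in (0, 1)")
  n_pos <- sum(vapply(map$chroms, function(ch) length(ch$raw), integer(1)))
  grid <- seq(1 + step, fold_max, by = step)
  cov <- vapply(grid, function(f) {
    reg <- call_regions(map, m, f, direction, min_stretch,
                        fold_scale = fold_scale)
    region_coverage(reg, map$chrom_lengths, unit = unit, n_positions = n_pos)
  }, numeric(1))
  if (all(cov == 0)) {
    warnf("no fold on the grid produced any %s region; returning the smallest fold",
          if (direction == "up") "RIDGE" else "anti-RIDGE")
    best <- 1L
  } else {
    d <- abs(cov - target)
    best_d <- min(d)
    best <- max(which(d <= best_d + 1e-12))  # tie -> larger fold
  }
  structure(list(direction = direction, fold = grid[best],
                 coverage = cov[best], target = target, step = step,
                 grid = data.frame(fold = grid, coverage = cov)),
            class = "fold_calibration")
}

#' @export
print.fold_calibration <- function(x, ...) {
  cat(sprintf("Fold calibration (%s): fold %.4g achieves coverage %.4g (target %.3g, step %.3g)\n",
              x$direction, x$fold, x$coverage, x$target, x$step))
  invisible(x)
}

#' Write regions to BED6 (and read them back)
#'
#' BED uses 0-based half-open coordinates, so an internal interval
#' `[start, end]` becomes `start-1, end`. The name is `RIDGE_n`/`ANTIRIDGE_n`
#' numbered in output order, the score is the number of qualifying gene
#' positions, the strand is `"."`. Output is sorted by chromosome, then
#' start; an empty region set yields just the track header.
#'
#' @param regions A `region_calls` data.frame (or plain data.frame with
#'   columns `chrom`, `start`, `end`, `kind`, `n_gene_positions`).
#' @param path File path.
#' @return `path` (writer) or a data.frame of regions (reader, 1-based
#'   inclusive coordinates again; list columns are not recovered).
#' @export
write_regions_bed <- function(regions, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines('track name=regions description="RIDGE/anti-RIDGE calls"', con)
  if (nrow(regions)) {
    d <- regions[order(regions$chrom, regions$start), , drop = FALSE]
    counts <- stats::ave(seq_len(nrow(d)), d$kind, FUN = seq_along)
    writeLines(sprintf("%s\t%s\t%s\t%s_%d\t%d\t.",
                       d$chrom, fmt_num(d$start - 1), fmt_num(d$end),
                       d$kind, counts, d$n_gene_positions), con)
  }
  invisible(path)
}

#' @rdname write_regions_bed
#' @export
read_regions_bed <- function(path) {
  if (!file.exists(path)) stopf("BED file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^(track|browser|#)", lines) & nzchar(lines)]
  if (!length(lines))
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), kind = character(0),
                      n_gene_positions = integer(0), stringsAsFactors = FALSE))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  data.frame(
    chrom = vapply(parts, `[`, character(1), 1),
    start = as.numeric(vapply(parts, `[`, character(1), 2)) + 1,
    end = as.numeric(vapply(parts, `[`, character(1), 3)),
    kind = sub("_[0-9]+$", "", vapply(parts, `[`, character(1), 4)),
    n_gene_positions = as.integer(vapply(parts, `[`, character(1), 5)),
    stringsAsFactors = FALSE)
}

#' Write regions plus member gene lists to TSV
#'
#' Companion file to the BED export carrying the comma-separated member gene
#' ids per region.
#'
#' @param regions A `region_calls` data.frame with a `member_genes` column.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_regions_tsv <- function(regions, path) {
  d <- data.frame(chrom = regions$chrom,
                  start = fmt_num(regions$start), end = fmt_num(regions$end),
                  kind = regions$kind,
                  n_gene_positions = regions$n_gene_positions,
                  member_genes = vapply(regions$member_genes, paste,
                                        character(1), collapse = ","),
                  stringsAsFactors = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
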