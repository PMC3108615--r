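#' Build a transcriptome map
#'
#' Orders the genes of each chromosome by position and smooths their
#' expression with a running median ([running_median()]) of `window` gene
#' positions. Genes without an expression value stay in the annotation but are
#' excluded from the map. Chromosomes with fewer genes than the window still
#' get a map through the shrinking end windows.
#'
#' @param expr An [expression_matrix()].
#' @param annotation A [gene_annotation()] supplying gene order and positions.
#' @param tissue A tissue name from `tissues(expr)`, or `"average"` for the
#'   per-gene arithmetic mean over all tissues.
#' @param window Odd integer window in gene positions (study default 39: the
#'   gene plus 19 flanking genes on either side).
#' @return An object of class `transcriptome_map`: per chromosome the ordered
#'   gene ids, their start/end anchors (bp), raw and smoothed values, plus the
#'   window and source tissue.
#' @export
build_map <- function(expr, annotation, tissue = "average", window = 39L) {
  stopifnot(inherits(expr, "expression_matrix"),
            inherits(annotation, "gene_annotation"))
  if (identical(tissue, "average")) {
    v <- rowMeans(expr$values)
  } else {
    if (!tissue %in% colnames(expr$values))
      stopf("unknown tissue '%s' (have: %s)", tissue,
            paste(colnames(expr$values), collapse = ", "))
    v <- expr$values[, tissue]
  }
  names(v) <- rownames(expr$values)
  chroms <- list()
  for (chrom in names(annotation$order)) {
    ids <- annotation$order[[chrom]]
    ids <- ids[ids %in% names(v)]
    if (!length(ids)) next
    raw <- unname(v[ids])
    g <- annotation$genes[ids, ]
    chroms[[chrom]] <- list(gene_id = ids,
                            start = g$start, end = g$end,
                            raw = raw,
                            smoothed = running_median(raw, window))
  }
  if (!length(chroms)) stopf("no mapped genes: expression and annotation share no gene ids")
  structure(list(chroms = chroms, window = as.integer(window),
                 tissue = tissue,
                 chrom_lengths = annotation$chrom_lengths),
            class = "transcriptome_map")
}

#' @export
print.transcriptome_map <- function(x, ...) {
  n <- sum(vapply(x$chroms, function(ch) length(ch$gene_id), integer(1)))
  cat(sprintf("Transcriptome map (%s): %d genes on %d chromosome(s), window %d\n",
              x$tissue, n, length(x$chroms), x$window))
  invisible(x)
}

#' @export
as.data.frame.transcriptome_map <- function(x, ...) {
  do.call(rbind, lapply(names(x$chroms), function(chrom) {
    ch <- x$chroms[[chrom]]
    data.frame(chrom = chrom, gene_id = ch$gene_id, start = ch$start,
               end = ch$end, raw = ch$raw, smoothed = ch$smoothed,
               stringsAsFactors = FALSE)
  }))
}

#' Write / read a transcriptome map as TSV
#'
#' Columns `chrom`, `gene_id`, `start`, `end`, `raw`, `smoothed`, preceded by
#' `##window`, `##tissue` and `##chrom_length` pragmas so the map can be
#' reconstructed exactly.
#'
#' @param map A `transcriptome_map`.
#' @param path File path.
#' @return `path` (writer) or a `transcriptome_map` (reader).
#' @export
write_map <- function(map, path) {
  stopifnot(inherits(map, "transcriptome_map"))
  d <- as.data.frame(map)
  d$start <- fmt_num(d$start); d$end <- fmt_num(d$end)
  d$raw <- fmt_num(d$raw); d$smoothed <- fmt_num(d$smoothed)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("##window\t%d", map$window),
               sprintf("##tissue\t%s", map$tissue),
               sprintf("##chrom_length\t%s\t%s", names(map$chrom_lengths),
                       fmt_num(map$chrom_lengths))), con)
  utils::write.table(d, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_map
#' @export
read_map <- function(path) {
  if (!file.exists(path)) stopf("map file not found: %s", path)
  lines <- readLines(path)
  get_pragma <- function(key) {
    hit <- grep(sprintf("^##%s\t", key), lines, value = TRUE)
    lapply(strsplit(hit, "\t", fixed = TRUE), `[`, -1L)
  }
  window <- as.integer(get_pragma("window")[[1]][1])
  tissue <- get_pragma("tissue")[[1]][1]
  cl_parts <- get_pragma("chrom_length")
  chrom_lengths <- vapply(cl_parts, function(p) as.numeric(p[2]), numeric(1))
  names(chrom_lengths) <- vapply(cl_parts, `[`, character(1), 1)
  d <- utils::read.table(text = lines[!grepl("^#", lines)], header = TRUE,
                         sep = "\t", stringsAsFactors = FALSE)
  chroms <- lapply(split(d, d$chrom), function(dd) {
    list(gene_id = dd$gene_id, start = dd$start, end = dd$end,
         raw = dd$raw, smoothed = dd$smoothed)
  })
  structure(list(chroms = chroms[sort(names(chroms), method = "radix")],
                 window = window, tissue = tissue,
                 chrom_lengths = chrom_lengths),
            class = "transcriptome_map")
}

#' Spearman correlation between two transcriptome maps
#'
#' Concatenates the smoothed values of both maps genome-wide (requiring the
#' same gene order) and computes the Spearman rank correlation with midrank
#' ties; the p-value comes from the large-sample t approximation.
#'
#' @param map_a,map_b `transcriptome_map` objects over the same genes.
#' @return A list with `rho`, `p`, and `n` (number of paired positions).
#' @export
map_correlation <- function(map_a, map_b) {
  stopifnot(inherits(map_a, "transcriptome_map"),
            inherits(map_b, "transcriptome_map"))
  if (!identical(names(map_a$chroms), names(map_b$chroms)))
    stopf("maps cover different chromosome sets")
  ids_a <- unlist(lapply(map_a$chroms, `[[`, "gene_id"), use.names = FALSE)
  ids_b <- unlist(lapply(map_b$chroms, `[[`, "gene_id"), use.names = FALSE)
  if (!identical(ids_a, ids_b))
    stopf("maps must share the same gene order")
  a <- unlist(lapply(map_a$chroms, `[[`, "smoothed"), use.names = FALSE)
  b <- unlist(lapply(map_b$chroms, `[[`, "smoothed"), use.names = FALSE)
  if (length(a) < 3L) stopf("need at least 3 paired map positions")
  ct <- suppressWarnings(
    stats::cor.test(a, b, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(a))
}
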