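#' Expression matrix container
#'
#' Per-gene, per-tissue normalised log-intensities (the study's scale is
#' roughly 9-14 log2 units) plus a flat pool of negative-control intensities
#' used to derive the expression threshold.
#'
#' @param values Numeric matrix, one row per gene (rownames = gene ids), one
#'   column per tissue (colnames = tissue names). All values must be finite.
#' @param negative_controls Numeric vector of control log-intensities
#'   (possibly empty).
#' @param unmapped Character vector of gene ids present in the matrix but
#'   absent from the annotation they were checked against.
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, negative_controls = numeric(0),
                              unmapped = character(0)) {
  values <- as.matrix(values)
  if (is.null(rownames(values))) stopf("`values` needs gene ids as rownames")
  if (is.null(colnames(values)) || ncol(values) < 1L)
    stopf("`values` needs a non-empty set of named tissue columns")
  if (anyDuplicated(rownames(values)))
    stopf("duplicate gene rows in expression matrix; average them first")
  if (!is.numeric(values) || any(!is.finite(values)))
    stopf("expression values must all be finite numbers")
  negative_controls <- as.numeric(negative_controls)
  if (any(!is.finite(negative_controls)))
    stopf("negative-control intensities must be finite")
  structure(list(values = values,
                 negative_controls = negative_controls,
                 unmapped = as.character(unmapped)),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("Expression matrix: %d genes x %d tissues (%s), %d negative controls",
              nrow(x$values), ncol(x$values),
              paste(colnames(x$values), collapse = ", "),
              length(x$negative_controls)))
  if (length(x$unmapped))
    cat(sprintf(", %d gene(s) not in annotation", length(x$unmapped)))
  cat("\n")
  invisible(x)
}

#' Tissue names of an expression matrix
#' @param expr An `expression_matrix`.
#' @return Character vector of tissue names.
#' @export
tissues <- function(expr) colnames(expr$values)

#' Read an expression matrix from TSV
#'
#' Expects a header line naming the tissues, a `gene_id` first column and a
#' numeric body. Genes represented by multiple rows (e.g. multiple probes per
#' gene) are averaged per gene with a message. Non-numeric cells are a hard
#' error reporting the offending row and column. When an annotation is given,
#' genes absent from it are retained but flagged in `$unmapped`.
#'
#' @param path Path to the expression TSV.
#' @param annotation Optional [gene_annotation()] used to flag unmapped genes.
#' @param controls Optional negative controls: a numeric vector or the path of
#'   a TSV readable by [read_negative_controls()].
#' @return An [expression_matrix()] object.
#' @export
read_expression <- function(path, annotation = NULL, controls = NULL) {
  if (!file.exists(path)) stopf("expression file not found: %s", path)
  d <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                         stringsAsFactors = FALSE, check.names = FALSE,
                         colClasses = "character", comment.char = "#")
  if (ncol(d) < 2L) stopf("expression TSV %s needs gene_id + tissue columns", path)
  ids <- d[[1]]
  tissue_names <- names(d)[-1]
  vals <- matrix(NA_real_, nrow = nrow(d), ncol = length(tissue_names),
                 dimnames = list(NULL, tissue_names))
  for (j in seq_along(tissue_names)) {
    raw <- d[[j + 1L]]
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(num) & !is.na(raw) & nzchar(raw))
    if (length(bad))
      stopf("non-numeric expression value '%s' at row %d (gene %s), column '%s'",
            raw[bad[1]], bad[1], ids[bad[1]], tissue_names[j])
    if (anyNA(num))
      stopf("missing expression value at row %d, column '%s'",
            which(is.na(num))[1], tissue_names[j])
    vals[, j] <- num
  }
  if (anyDuplicated(ids)) {
    n_dup <- length(ids) - length(unique(ids))
    message(sprintf("averaging expression over duplicate rows for %d gene id(s)",
                    n_dup))
    vals <- rowsum(vals, group = ids, reorder = FALSE) /
      as.vector(table(factor(ids, levels = unique(ids))))
    ids <- unique(ids)
  }
  rownames(vals) <- ids
  unmapped <- character(0)
  if (!is.null(annotation)) {
    stopifnot(inherits(annotation, "gene_annotation"))
    unmapped <- setdiff(ids, annotation$genes$gene_id)
  }
  nc <- numeric(0)
  if (!is.null(controls)) {
    nc <- if (is.character(controls)) read_negative_controls(controls)
          else as.numeric(controls)
  }
  expression_matrix(vals, negative_controls = nc, unmapped = unmapped)
}

#' Read negative-control intensities from TSV
#'
#' Any numeric columns are flattened into one pool; a header line is expected.
#'
#' @param path File path.
#' @return Numeric vector of control log-intensities.
#' @export
read_negative_controls <- function(path) {
  if (!file.exists(path)) stopf("negative-control file not found: %s", path)
  d <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                         stringsAsFactors = FALSE, comment.char = "#")
  num <- unlist(lapply(d, function(col) suppressWarnings(as.numeric(col))),
                use.names = FALSE)
  num <- num[!is.na(num)]
  if (!length(num)) stopf("no numeric control intensities in %s", path)
  num
}

#' Write an expression matrix (and optionally its controls) to TSV
#'
#' Values are written with 12 significant digits so a write/read round trip is
#' lossless up to that precision.
#'
#' @param expr An `expression_matrix`.
#' @param path Output TSV path.
#' @param controls_path Optional path for a one-column TSV of the negative
#'   controls.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path, controls_path = NULL) {
  stopifnot(inherits(expr, "expression_matrix"))
  out <- data.frame(gene_id = rownames(expr$values), stringsAsFactors = FALSE)
  for (tn in colnames(expr$values)) out[[tn]] <- fmt_num(expr$values[, tn])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(controls_path)) {
    utils::write.table(
      data.frame(intensity = fmt_num(expr$negative_controls)),
      controls_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
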