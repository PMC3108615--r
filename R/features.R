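#' Extract genomic features per gene
#'
#' Computes the six features compared between gene groups:
#' \describe{
#'   \item{gene_length}{genomic length, `end - start + 1` bp.}
#'   \item{intron_length}{mean intron length in bp; introns are the gaps
#'     between consecutive exons within a transcript. With
#'     `intron_mode = "pooled"` (default) the mean is over the pooled introns
#'     of all transcripts of the gene; `"per_transcript"` first averages
#'     within each transcript, then across transcripts with introns. `NA`
#'     for intron-less genes (excluded from intron comparisons).}
#'   \item{gc_fraction}{as supplied by the annotation.}
#'   \item{transcript_length}{mean over transcripts of the summed exon
#'     lengths.}
#'   \item{exon_count}{mean exon count over transcripts (may be fractional).}
#'   \item{exon_length}{mean length over the pooled exons of all
#'     transcripts.}
#' }
#' Genes with a transcript whose exons overlap are skipped with a warning.
#'
#' @param annotation A [gene_annotation()].
#' @param intron_mode `"pooled"` or `"per_transcript"`.
#' @return A data.frame of class `feature_table`, one row per retained gene.
#' @export
extract_features <- function(annotation,
                             intron_mode = c("pooled", "per_transcript")) {
  intron_mode <- match.arg(intron_mode)
  stopifnot(inherits(annotation, "gene_annotation"))
  g <- annotation$genes
  n <- nrow(g)
  gene_length <- g$end - g$start + 1
  intron_length <- transcript_length <- exon_count <- exon_length <-
    rep(NA_real_, n)
  skipped <- character(0)
  for (i in seq_len(n)) {
    txs <- annotation$transcripts[[g$gene_id[i]]]
    bad <- any(vapply(txs, function(m) {
      nrow(m) > 1 && any(m[-1, 1] <= m[-nrow(m), 2])
    }, logical(1)))
    if (bad) {
      skipped <- c(skipped, g$gene_id[i])
      next
    }
    t_lens <- vapply(txs, function(m) sum(m[, 2] - m[, 1] + 1), numeric(1))
    e_counts <- vapply(txs, nrow, integer(1))
    pooled_exons <- unlist(lapply(txs, function(m) m[, 2] - m[, 1] + 1))
    introns_by_tx <- lapply(txs, function(m) {
      if (nrow(m) < 2) numeric(0) else m[-1, 1] - m[-nrow(m), 2] - 1
    })
    transcript_length[i] <- mean(t_lens)
    exon_count[i] <- mean(e_counts)
    exon_length[i] <- mean(pooled_exons)
    intron_length[i] <- if (intron_mode == "pooled") {
      pooled <- unlist(introns_by_tx)
      if (length(pooled)) mean(pooled) else NA_real_
    } else {
      per_tx <- vapply(introns_by_tx, function(v)
        if (length(v)) mean(v) else NA_real_, numeric(1))
      if (all(is.na(per_tx))) NA_real_ else mean(per_tx, na.rm = TRUE)
    }
  }
  if (length(skipped))
    warnf("skipped %d gene(s) with overlapping exons: %s", length(skipped),
          paste(utils::head(skipped, 5), collapse = ", "))
  out <- data.frame(gene_id = g$gene_id, gene_length = gene_length,
                    intron_length = intron_length,
                    gc_fraction = g$gc_fraction,
                    transcript_length = transcript_length,
                    exon_count = exon_count, exon_length = exon_length,
                    stringsAsFactors = FALSE)
  out <- out[!out$gene_id %in% skipped, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("feature_table", "data.frame"))
}

#' Names of the comparable genomic features
#' @return Character vector of the six feature column names.
#' @export
feature_names <- function() {
  c("gene_length", "intron_length", "gc_fraction",
    "transcript_length", "exon_count", "exon_length")
}

#' Compare a genomic feature between two gene groups
#'
#' Two-sided Wilcoxon rank-sum test. The exact distribution is used when both
#' groups have at most 20 values and there are no ties; otherwise the normal
#' approximation with midrank ties, tie correction and continuity correction.
#' Values absent for a gene (e.g. intron length of intron-less genes) are
#' dropped before testing.
#'
#' @param features A [extract_features()] table.
#' @param group_a,group_b Character vectors of gene ids (non-overlapping
#'   groups are the caller's responsibility).
#' @param feature One of [feature_names()].
#' @param labels Length-2 character vector naming the groups in the report.
#' @return An object of class `feature_comparison`: list with `feature`,
#'   `labels`, `n` (group sizes after dropping NAs), `medians`, `p`
#'   (two-sided), `direction` (`"<label> lower"`, `"<label> higher"` or
#'   `"equal"`, stated for the first group) and `method`.
#' @export
compare_groups <- function(features, group_a, group_b, feature,
                           labels = c("A", "B")) {
  if (!feature %in% feature_names())
    stopf("unknown feature '%s'", feature)
  rownames(features) <- features$gene_id
  x <- features[intersect(group_a, features$gene_id), feature]
  y <- features[intersect(group_b, features$gene_id), feature]
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  if (!length(x) || !length(y))
    stopf("both groups must be non-empty after dropping missing '%s' values",
          feature)
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- length(x) <= 20 && length(y) <= 20 && !ties
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = !exact))
  med <- c(stats::median(x), stats::median(y))
  names(med) <- labels
  direction <- if (med[1] < med[2]) sprintf("%s lower", labels[1])
               else if (med[1] > med[2]) sprintf("%s higher", labels[1])
               else "equal"
  structure(list(feature = feature, labels = labels,
                 n = c(length(x), length(y)), medians = med,
                 p = wt$p.value, direction = direction,
                 method = if (exact) "exact" else "normal approximation"),
            class = "feature_comparison")
}

#' @export
print.feature_comparison <- function(x, ...) {
  cat(sprintf("%s: %s vs %s (n = %d / %d), medians %.4g / %.4g\n",
              x$feature, x$labels[1], x$labels[2], x$n[1], x$n[2],
              x$medians[1], x$medians[2]))
  cat(sprintf("  Wilcoxon rank-sum (%s), two-sided p = %.4g; %s\n",
              x$method, x$p, x$direction))
  invisible(x)
}
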