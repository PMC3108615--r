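#' Gene annotation container
#'
#' Bundles per-gene coordinates, transcript/exon structure, GC fraction, a
#' deterministic per-chromosome gene order, and chromosome lengths. All
#' internal coordinates are 1-based inclusive (GFF3 convention); interval
#' export to BED converts to 0-based half-open. Strand is carried but ignored
#' by all downstream computations.
#'
#' Gene order on each chromosome is sorted by start, ties broken by end, then
#' by gene id, so the order is strict and reproducible.
#'
#' @param genes A data.frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand` (one of `+`, `-`, `.`), `gc_fraction` (in `[0, 1]`, may be NA).
#' @param transcripts Optional named list (by `gene_id`); each element is a
#'   list of transcripts, each transcript a two-column matrix of exon
#'   `start`/`end` coordinates sorted by start. Genes without an entry get a
#'   single single-exon transcript spanning the gene.
#' @param chrom_lengths Optional named numeric vector of chromosome lengths in
#'   bp; chromosomes not covered (or when `NULL`) default to the maximum gene
#'   end observed on that chromosome.
#'
#' @return An object of class `gene_annotation`: a list with elements `genes`
#'   (the validated data.frame, row order = input order), `transcripts`,
#'   `order` (named list of gene ids per chromosome in map order) and
#'   `chrom_lengths`.
#' @export
#' @examples
#' g <- data.frame(gene_id = c("g1", "g2"), chrom = "chr1",
#'                 start = c(100, 500), end = c(400, 900),
#'                 strand = "+", gc_fraction = c(0.5, 0.4))
#' ann <- gene_annotation(g)
#' ann$order$chr1
gene_annotation <- function(genes, transcripts = NULL, chrom_lengths = NULL) {
  need <- c("gene_id", "chrom", "start", "end", "strand", "gc_fraction")
  miss <- setdiff(need, names(genes))
  if (length(miss))
    stopf("`genes` lacks column(s): %s", paste(miss, collapse = ", "))
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  genes$gene_id <- as.character(genes$gene_id)
  genes$chrom <- as.character(genes$chrom)
  genes$start <- as.numeric(genes$start)
  genes$end <- as.numeric(genes$end)
  genes$strand <- as.character(genes$strand)
  genes$gc_fraction <- as.numeric(genes$gc_fraction)
  dup <- unique(genes$gene_id[duplicated(genes$gene_id)])
  if (length(dup))
    stopf("duplicate gene_id(s): %s", paste(utils::head(dup, 5), collapse = ", "))
  if (any(!is.finite(genes$start)) || any(!is.finite(genes$end)))
    stopf("gene coordinates must be finite numbers")
  bad <- genes$end < genes$start
  if (any(bad))
    stopf("end < start for gene(s): %s",
          paste(utils::head(genes$gene_id[bad], 5), collapse = ", "))
  genes$strand[!genes$strand %in% c("+", "-")] <- "."
  out_of_range <- !is.na(genes$gc_fraction) &
    (genes$gc_fraction < 0 | genes$gc_fraction > 1)
  if (any(out_of_range))
    stopf("gc_fraction outside [0, 1] for gene(s): %s",
          paste(utils::head(genes$gene_id[out_of_range], 5), collapse = ", "))
  rownames(genes) <- genes$gene_id

  tx <- vector("list", nrow(genes))
  names(tx) <- genes$gene_id
  for (gid in genes$gene_id) {
    entry <- transcripts[[gid]]
    if (is.null(entry) || !length(entry)) {
      entry <- list(matrix(c(genes[gid, "start"], genes[gid, "end"]),
                           ncol = 2, dimnames = list(NULL, c("start", "end"))))
    } else {
      entry <- lapply(entry, function(ex) {
        ex <- matrix(as.numeric(ex), ncol = 2,
                     dimnames = list(NULL, c("start", "end")))
        ex <- ex[order(ex[, 1], ex[, 2]), , drop = FALSE]
        if (any(ex[, 2] < ex[, 1]))
          stopf("gene %s: exon with end < start", gid)
        if (min(ex[, 1]) < genes[gid, "start"] || max(ex[, 2]) > genes[gid, "end"])
          stopf("gene %s: exon outside the gene interval", gid)
        ex
      })
    }
    tx[[gid]] <- entry
  }

  ord <- lapply(split(genes, genes$chrom), function(d) {
    d$gene_id[order(d$start, d$end, d$gene_id, method = "radix")]
  })
  ord <- ord[sort(names(ord), method = "radix")]

  max_end <- vapply(split(genes$end, genes$chrom), max, numeric(1))
  cl <- max_end[names(ord)]
  if (!is.null(chrom_lengths)) {
    given <- chrom_lengths[names(cl)]
    has <- !is.na(given)
    cl[has] <- pmax(cl[has], as.numeric(given[has]))
  }

  structure(list(genes = genes, transcripts = tx, order = ord,
                 chrom_lengths = cl),
            class = "gene_annotation")
}

#' @export
print.gene_annotation <- function(x, ...) {
  cat(sprintf("Gene annotation: %d genes on %d chromosome(s), %.4g Mb total\n",
              nrow(x$genes), length(x$order), sum(x$chrom_lengths) / 1e6))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Readers / writers

#' Read a gene annotation (GFF3 or TSV)
#'
#' GFF3 files are parsed with rtracklayer; `gene` features supply coordinates
#' and (via a `gc_fraction` attribute) GC content, `mRNA`/`transcript`
#' features and their `exon` children supply transcript structure. Chromosome
#' lengths are taken from `##sequence-region` directives when present.
#'
#' The TSV dialect has a header line and tab-separated columns `gene_id`,
#' `chrom`, `start`, `end`, `strand`, `gc_fraction`, optionally followed by
#' `exon_starts` and `exon_ends` (transcripts separated by `;`, exons within a
#' transcript by `,`). Lines of the form `##chrom_length<TAB>chrom<TAB>bp`
#' before the header declare chromosome lengths.
#'
#' Records with `end < start` are rejected with a warning; duplicate gene ids
#' are an error.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"gff3"` or `"tsv"`.
#' @return A [gene_annotation()] object.
#' @export
read_annotation <- function(path, format = c("auto", "gff3", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("annotation file not found: %s", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("gff", "gff3")) "gff3" else "tsv"
  }
  if (format == "gff3") read_annotation_gff3(path) else read_annotation_tsv(path)
}

read_annotation_tsv <- function(path) {
  lines <- readLines(path)
  len_lines <- grep("^##chrom_length\t", lines, value = TRUE)
  chrom_lengths <- NULL
  if (length(len_lines)) {
    parts <- strsplit(len_lines, "\t", fixed = TRUE)
    chrom_lengths <- vapply(parts, function(p) as.numeric(p[3]), numeric(1))
    names(chrom_lengths) <- vapply(parts, `[`, character(1), 2)
  }
  body <- lines[!grepl("^#", lines)]
  if (!length(body)) stopf("annotation TSV %s has no data rows", path)
  d <- utils::read.table(text = body, header = TRUE, sep = "\t",
                         quote = "", stringsAsFactors = FALSE,
                         check.names = FALSE)
  need <- c("gene_id", "chrom", "start", "end", "strand", "gc_fraction")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stopf("annotation TSV %s lacks column(s): %s", path,
          paste(miss, collapse = ", "))
  d$start <- as.numeric(d$start)
  d$end <- as.numeric(d$end)
  bad <- !is.finite(d$start) | !is.finite(d$end) | d$end < d$start
  if (any(bad)) {
    warnf("rejecting %d malformed annotation record(s) (end < start or non-numeric): %s",
          sum(bad), paste(utils::head(d$gene_id[bad], 5), collapse = ", "))
    d <- d[!bad, , drop = FALSE]
  }
  if (!nrow(d)) stopf("annotation TSV %s has no valid records", path)
  transcripts <- NULL
  if (all(c("exon_starts", "exon_ends") %in% names(d))) {
    transcripts <- parse_exon_columns(d)
  }
  gene_annotation(d[, need], transcripts = transcripts,
                  chrom_lengths = chrom_lengths)
}

# exon_starts/exon_ends: ';' separates transcripts, ',' separates exons
parse_exon_columns <- function(d) {
  tx <- list()
  for (i in seq_len(nrow(d))) {
    s_field <- d$exon_starts[i]
    e_field <- d$exon_ends[i]
    if (is.na(s_field) || !nzchar(s_field)) next
    s_tx <- strsplit(as.character(s_field), ";", fixed = TRUE)[[1]]
    e_tx <- strsplit(as.character(e_field), ";", fixed = TRUE)[[1]]
    if (length(s_tx) != length(e_tx))
      stopf("gene %s: exon_starts and exon_ends disagree on transcript count",
            d$gene_id[i])
    tx[[d$gene_id[i]]] <- unname(Map(function(ss, ee) {
      s <- as.numeric(strsplit(ss, ",", fixed = TRUE)[[1]])
      e <- as.numeric(strsplit(ee, ",", fixed = TRUE)[[1]])
      if (length(s) != length(e))
        stopf("gene %s: exon start/end count mismatch", d$gene_id[i])
      cbind(start = s, end = e)
    }, s_tx, e_tx))
  }
  tx
}

read_annotation_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(gr)),
                   start = GenomicRanges::start(gr),
                   end = GenomicRanges::end(gr),
                   strand = as.character(GenomicRanges::strand(gr)),
                   type = as.character(S4Vectors::mcols(gr)$type),
                   stringsAsFactors = FALSE)
  mc <- S4Vectors::mcols(gr)
  df$ID <- if ("ID" %in% names(mc)) as.character(mc$ID) else NA_character_
  parent <- if ("Parent" %in% names(mc)) {
    vapply(as.list(mc$Parent), function(p)
      if (length(p)) as.character(p[[1]]) else NA_character_, character(1))
  } else rep(NA_character_, nrow(df))
  df$Parent <- parent
  df$gc_fraction <- if ("gc_fraction" %in% names(mc))
    suppressWarnings(as.numeric(as.character(mc$gc_fraction)))
  else NA_real_

  is_gene <- df$type == "gene"
  if (!any(is_gene)) stopf("no `gene` features in %s", path)
  genes <- data.frame(gene_id = df$ID[is_gene], chrom = df$chrom[is_gene],
                      start = df$start[is_gene], end = df$end[is_gene],
                      strand = df$strand[is_gene],
                      gc_fraction = df$gc_fraction[is_gene],
                      stringsAsFactors = FALSE)
  if (anyNA(genes$gene_id)) stopf("gene feature without ID in %s", path)
  bad <- genes$end < genes$start
  if (any(bad)) {
    warnf("rejecting %d malformed gene record(s) in %s",
          sum(bad), path)
    genes <- genes[!bad, , drop = FALSE]
  }

  is_tx <- df$type %in% c("mRNA", "transcript")
  tx_parent <- df$Parent[is_tx]
  tx_id <- df$ID[is_tx]
  is_exon <- df$type == "exon"
  exon_by_tx <- split(data.frame(start = df$start[is_exon],
                                 end = df$end[is_exon]),
                      df$Parent[is_exon])
  transcripts <- list()
  for (j in seq_along(tx_id)) {
    gid <- tx_parent[j]
    if (is.na(gid) || !gid %in% genes$gene_id) next
    ex <- exon_by_tx[[tx_id[j]]]
    if (is.null(ex) || !nrow(ex)) next
    m <- cbind(start = ex$start, end = ex$end)
    transcripts[[gid]] <- c(transcripts[[gid]], list(m))
  }

  sl <- GenomeInfoDb::seqlengths(gr)
  sl <- sl[!is.na(sl)]
  if (!length(sl)) {
    # fall back to parsing ##sequence-region directives directly
    hdr <- grep("^##sequence-region", readLines(path, n = 500L), value = TRUE)
    if (length(hdr)) {
      parts <- strsplit(trimws(hdr), "\\s+")
      sl <- vapply(parts, function(p) as.numeric(p[4]), numeric(1))
      names(sl) <- vapply(parts, `[`, character(1), 2)
    }
  }
  gene_annotation(genes, transcripts = transcripts,
                  chrom_lengths = if (length(sl)) sl else NULL)
}

#' Write a gene annotation
#'
#' Writes the TSV dialect documented in [read_annotation()] (including
#' `##chrom_length` pragmas and exon columns), or GFF3 via rtracklayer with
#' gene/mRNA/exon features and a `gc_fraction` gene attribute.
#'
#' @param ann A `gene_annotation` object.
#' @param path Output file path.
#' @param format `"tsv"` or `"gff3"`.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(ann, path, format = c("tsv", "gff3")) {
  format <- match.arg(format)
  stopifnot(inherits(ann, "gene_annotation"))
  if (format == "tsv") {
    g <- ann$genes
    ex_s <- ex_e <- character(nrow(g))
    for (i in seq_len(nrow(g))) {
      txs <- ann$transcripts[[g$gene_id[i]]]
      ex_s[i] <- paste(vapply(txs, function(m)
        paste(fmt_num(m[, "start"]), collapse = ","), character(1)),
        collapse = ";")
      ex_e[i] <- paste(vapply(txs, function(m)
        paste(fmt_num(m[, "end"]), collapse = ","), character(1)),
        collapse = ";")
    }
    out <- data.frame(gene_id = g$gene_id, chrom = g$chrom,
                      start = fmt_num(g$start), end = fmt_num(g$end),
                      strand = g$strand, gc_fraction = fmt_num(g$gc_fraction),
                      exon_starts = ex_s, exon_ends = ex_e,
                      stringsAsFactors = FALSE)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("##chrom_length\t%s\t%s", names(ann$chrom_lengths),
                       fmt_num(ann$chrom_lengths)), con)
    utils::write.table(out, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
  } else {
    g <- ann$genes
    rows <- list()
    for (i in seq_len(nrow(g))) {
      gid <- g$gene_id[i]
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = g$chrom[i], start = g$start[i], end = g$end[i],
        strand = g$strand[i], type = "gene", ID = gid, Parent = NA_character_,
        gc_fraction = g$gc_fraction[i], stringsAsFactors = FALSE)
      txs <- ann$transcripts[[gid]]
      for (j in seq_along(txs)) {
        tid <- sprintf("%s.t%d", gid, j)
        m <- txs[[j]]
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = g$chrom[i], start = min(m[, 1]), end = max(m[, 2]),
          strand = g$strand[i], type = "mRNA", ID = tid, Parent = gid,
          gc_fraction = NA_real_, stringsAsFactors = FALSE)
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = g$chrom[i], start = m[, 1], end = m[, 2],
          strand = g$strand[i], type = "exon", ID = NA_character_,
          Parent = tid, gc_fraction = NA_real_, stringsAsFactors = FALSE)
      }
    }
    d <- do.call(rbind, rows)
    strand_ok <- ifelse(d$strand %in% c("+", "-"), d$strand, "*")
    gr <- GenomicRanges::GRanges(
      seqnames = d$chrom,
      ranges = IRanges::IRanges(start = d$start, end = d$end),
      strand = strand_ok)
    S4Vectors::mcols(gr)$type <- d$type
    S4Vectors::mcols(gr)$ID <- d$ID
    S4Vectors::mcols(gr)$Parent <- d$Parent
    S4Vectors::mcols(gr)$gc_fraction <- d$gc_fraction
    GenomeInfoDb::seqlengths(gr) <-
      ann$chrom_lengths[GenomeInfoDb::seqlevels(gr)]
    rtracklayer::export(gr, path, format = "gff3")
    # rtracklayer does not emit ##sequence-region pragmas; add them so
    # chromosome lengths survive the round trip
    lines <- readLines(path)
    pragmas <- sprintf("##sequence-region %s 1 %s", names(ann$chrom_lengths),
                       fmt_num(ann$chrom_lengths))
    writeLines(c(lines[1], pragmas, lines[-1]), path)
  }
  invisible(path)
}
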