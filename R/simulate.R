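#' Class-conditional feature profile for the genome simulator
#'
#' Parameterises how gene structure differs between planted RIDGEs, planted
#' anti-RIDGEs and the background, emulating the contrasts observed in real
#' expression domains: RIDGE genes are stochastically shorter, have fewer and
#' shorter introns and higher GC than anti-RIDGE genes.
#'
#' @param exon_count_lambda Poisson rate of extra exons per class (exon count
#'   is `1 + Poisson(lambda)`); named vector over
#'   `ridge`/`background`/`antiridge`.
#' @param exon_meanlog,exon_sdlog Log-normal parameters of exon length (bp),
#'   shared across classes.
#' @param intron_meanlog,intron_sdlog Log-normal intron length (bp) per class
#'   / shared sdlog.
#' @param gc_mean,gc_conc Beta mean per class and shared concentration for
#'   the GC fraction.
#' @param gap_meanlog,gap_sdlog Log-normal intergenic gap (bp).
#' @param second_transcript_prob Probability a gene carries a second,
#'   identical transcript.
#' @return A named list of class `sim_feature_profile`.
#' @export
sim_feature_profile <- function(
    exon_count_lambda = c(ridge = 5, background = 6, antiridge = 7),
    exon_meanlog = log(180), exon_sdlog = 0.4,
    intron_meanlog = c(ridge = log(1000), background = log(1500),
                       antiridge = log(2200)),
    intron_sdlog = 0.5,
    gc_mean = c(ridge = 0.55, background = 0.47, antiridge = 0.42),
    gc_conc = 60,
    gap_meanlog = log(18000), gap_sdlog = 0.5,
    second_transcript_prob = 0.3) {
  classes <- c("ridge", "background", "antiridge")
  for (nm in c("exon_count_lambda", "intron_meanlog", "gc_mean")) {
    v <- get(nm)
    if (!all(classes %in% names(v)))
      stopf("`%s` must be named over %s", nm, paste(classes, collapse = ", "))
  }
  structure(list(exon_count_lambda = exon_count_lambda,
                 exon_meanlog = exon_meanlog, exon_sdlog = exon_sdlog,
                 intron_meanlog = intron_meanlog, intron_sdlog = intron_sdlog,
                 gc_mean = gc_mean, gc_conc = gc_conc,
                 gap_meanlog = gap_meanlog, gap_sdlog = gap_sdlog,
                 second_transcript_prob = second_transcript_prob),
            class = "sim_feature_profile")
}

# expected bp consumed per gene (structure + following gap) for one class
expected_bp_per_gene <- function(profile, class) {
  lam <- profile$exon_count_lambda[[class]]
  e_exon <- exp(profile$exon_meanlog + profile$exon_sdlog^2 / 2)
  e_intron <- exp(profile$intron_meanlog[[class]] + profile$intron_sdlog^2 / 2)
  e_gap <- exp(profile$gap_meanlog + profile$gap_sdlog^2 / 2)
  (1 + lam) * e_exon + lam * e_intron + e_gap
}

# draw exon/intron structure and GC for one gene; returns list(length, exons, gc)
draw_gene_structure <- function(profile, class) {
  n_exon <- 1L + stats::rpois(1, profile$exon_count_lambda[[class]])
  exon_len <- pmax(30, round(stats::rlnorm(n_exon, profile$exon_meanlog,
                                           profile$exon_sdlog)))
  intron_len <- if (n_exon > 1)
    pmax(30, round(stats::rlnorm(n_exon - 1, profile$intron_meanlog[[class]],
                                 profile$intron_sdlog)))
  else numeric(0)
  starts <- ends <- numeric(n_exon)
  pos <- 1
  for (j in seq_len(n_exon)) {
    starts[j] <- pos
    ends[j] <- pos + exon_len[j] - 1
    pos <- ends[j] + (if (j < n_exon) intron_len[j] else 0) + 1
  }
  gm <- profile$gc_mean[[class]]
  gc <- stats::rbeta(1, gm * profile$gc_conc, (1 - gm) * profile$gc_conc)
  list(length = ends[n_exon], exon_start = starts, exon_end = ends, gc = gc)
}

#' Simulate a gene-annotated genome with planted expression domains
#'
#' Lays out `n_chrom` chromosomes of roughly `genes_per_chrom` genes each. On
#' every chromosome one RIDGE block and one anti-RIDGE block are planted (in
#' random order, separated by background segments), each budgeted to cover
#' `coverage_target` of the chromosome in bp. Gene structure is drawn from
#' the class-conditional [sim_feature_profile()], so planted-RIDGE genes are
#' stochastically shorter, with fewer/shorter introns and higher GC, than
#' planted-anti-RIDGE genes. Expression classes are assigned per gene:
#' housekeeping with probability `hk_prob_ridge` inside planted RIDGEs and
#' `hk_prob_background` elsewhere (reproducing HK over-representation on
#' RIDGEs), then tissue-specific / silent / intermediate.
#'
#' The generator is deterministic given `seed`: the same seed yields a
#' byte-identical annotation and truth.
#'
#' @param n_chrom Number of chromosomes, >= 1.
#' @param genes_per_chrom Approximate genes per chromosome (the bp budget is
#'   derived from it; the realised count varies by a few genes).
#' @param seed Integer seed.
#' @param coverage_target Planted bp coverage per region kind; both kinds
#'   together must stay below 0.8 of the genome or the planted domains could
#'   not be kept disjoint (error).
#' @param profile A [sim_feature_profile()].
#' @param hk_prob_ridge,hk_prob_background,hk_prob_antiridge Probability of
#'   the HK class inside planted RIDGEs / in the background / inside planted
#'   anti-RIDGEs (defaults 0.35 / 0.18 / 0.08: housekeeping genes cluster in
#'   domains of increased expression and are depleted from depressed
#'   domains).
#' @param ts_prob,silent_prob,silent_prob_antiridge Probabilities of the TS
#'   and silent classes (remaining genes are intermediate); silent genes are
#'   enriched inside planted anti-RIDGEs (default 0.20 vs 0.10), the mirror
#'   image of HK clustering on RIDGEs.
#' @param tissues Tissue panel used to attribute TS genes (study default five
#'   bovine tissues).
#' @return A list with `annotation` (a [gene_annotation()]) and `truth` (an
#'   object of class `simulation_truth`: planted `regions`, per-gene
#'   `classes` data.frame, realised `coverage` per kind, and the generator
#'   parameters).
#' @export
simulate_genome <- function(n_chrom = 5, genes_per_chrom = 500, seed = 1,
                            coverage_target = 0.10,
                            profile = sim_feature_profile(),
                            hk_prob_ridge = 0.35, hk_prob_background = 0.18,
                            hk_prob_antiridge = 0.08,
                            ts_prob = 0.10, silent_prob = 0.10,
                            silent_prob_antiridge = 0.20,
                            tissues = c("AP", "AM", "HC", "DH", "VH")) {
  if (n_chrom < 1) stopf("`n_chrom` must be >= 1")
  if (genes_per_chrom < 20) stopf("`genes_per_chrom` must be >= 20")
  if (!is_scalar_number(coverage_target) || coverage_target <= 0)
    stopf("`coverage_target` must be positive")
  if (2 * coverage_target > 0.8)
    stopf("planted domains would overlap: 2 * coverage_target must be <= 0.8")
  if (hk_prob_ridge + ts_prob + silent_prob > 1 ||
      hk_prob_background + ts_prob + silent_prob > 1 ||
      hk_prob_antiridge + ts_prob + silent_prob_antiridge > 1)
    stopf("class probabilities exceed 1")
  set.seed(as.integer(seed))

  e_bp <- c(ridge = expected_bp_per_gene(profile, "ridge"),
            background = expected_bp_per_gene(profile, "background"),
            antiridge = expected_bp_per_gene(profile, "antiridge"))
  mean_bp <- coverage_target * (e_bp[["ridge"]] + e_bp[["antiridge"]]) +
    (1 - 2 * coverage_target) * e_bp[["background"]]
  l_target <- genes_per_chrom * mean_bp

  genes <- list()
  transcripts <- list()
  truth_regions <- list()
  chrom_lengths <- numeric(0)
  region_of_gene <- character(0)

  for (ci in seq_len(n_chrom)) {
    chrom <- sprintf("chr%d", ci)
    kinds <- sample(c("RIDGE", "ANTIRIDGE"))
    bg_frac <- stats::runif(3, 0.5, 1.5)
    bg_frac <- bg_frac / sum(bg_frac)
    seg_class <- c("background", tolower(kinds[1]),
                   "background", tolower(kinds[2]), "background")
    budgets <- c(bg_frac[1] * (1 - 2 * coverage_target) * l_target,
                 coverage_target * l_target,
                 bg_frac[2] * (1 - 2 * coverage_target) * l_target,
                 coverage_target * l_target,
                 bg_frac[3] * (1 - 2 * coverage_target) * l_target)
    cur <- 0
    gi <- 0L
    for (si in seq_along(seg_class)) {
      seg_origin <- cur
      first_start <- NA_real_
      cls <- seg_class[si]
      struct_class <- if (cls %in% c("ridge", "antiridge")) cls else "background"
      while (cur - seg_origin < budgets[si]) {
        gap <- max(200, round(stats::rlnorm(1, profile$gap_meanlog,
                                            profile$gap_sdlog)))
        st <- draw_gene_structure(profile, struct_class)
        gi <- gi + 1L
        gstart <- cur + gap + 1
        gend <- gstart + st$length - 1
        gid <- sprintf("%s_g%04d", chrom, gi)
        exons <- cbind(start = gstart + st$exon_start - 1,
                       end = gstart + st$exon_end - 1)
        txs <- list(exons)
        if (stats::runif(1) < profile$second_transcript_prob)
          txs <- c(txs, list(exons))
        genes[[length(genes) + 1L]] <- data.frame(
          gene_id = gid, chrom = chrom, start = gstart, end = gend,
          strand = sample(c("+", "-"), 1), gc_fraction = st$gc,
          stringsAsFactors = FALSE)
        transcripts[[gid]] <- txs
        region_of_gene[gid] <- if (struct_class == "ridge") "RIDGE"
                               else if (struct_class == "antiridge") "ANTIRIDGE"
                               else "NONE"
        if (is.na(first_start)) first_start <- gstart
        cur <- gend
      }
      if (struct_class != "background") {
        truth_regions[[length(truth_regions) + 1L]] <- data.frame(
          chrom = chrom, start = first_start, end = cur,
          kind = if (struct_class == "ridge") "RIDGE" else "ANTIRIDGE",
          stringsAsFactors = FALSE)
      }
    }
    chrom_lengths[chrom] <- cur +
      max(200, round(stats::rlnorm(1, profile$gap_meanlog, profile$gap_sdlog)))
  }

  genes <- do.call(rbind, genes)
  truth_regions <- do.call(rbind, truth_regions)
  ann <- gene_annotation(genes, transcripts = transcripts,
                         chrom_lengths = chrom_lengths)

  # expression-class assignment: HK enriched inside planted RIDGEs,
  # silent enriched (and HK depleted) inside planted anti-RIDGEs
  reg <- unname(region_of_gene[genes$gene_id])
  p_hk <- ifelse(reg == "RIDGE", hk_prob_ridge,
                 ifelse(reg == "ANTIRIDGE", hk_prob_antiridge,
                        hk_prob_background))
  p_sil <- ifelse(reg == "ANTIRIDGE", silent_prob_antiridge, silent_prob)
  u <- stats::runif(nrow(genes))
  cls <- ifelse(u < p_hk, "HK",
                ifelse(u < p_hk + ts_prob, "TS",
                       ifelse(u < p_hk + ts_prob + p_sil,
                              "silent", "intermediate")))
  ts_tissue <- rep(NA_character_, nrow(genes))
  ts_tissue[cls == "TS"] <- sample(tissues, sum(cls == "TS"), replace = TRUE)
  classes <- data.frame(gene_id = genes$gene_id, class = cls,
                        ts_tissue = ts_tissue,
                        region = unname(region_of_gene[genes$gene_id]),
                        stringsAsFactors = FALSE)

  cov_by_kind <- vapply(c("RIDGE", "ANTIRIDGE"), function(k) {
    r <- truth_regions[truth_regions$kind == k, ]
    sum(r$end - r$start + 1) / sum(chrom_lengths)
  }, numeric(1))

  truth <- structure(list(regions = truth_regions, classes = classes,
                          coverage = cov_by_kind,
                          coverage_target = coverage_target,
                          tissues = tissues, seed = as.integer(seed),
                          profile = profile,
                          hk_prob_ridge = hk_prob_ridge,
                          hk_prob_background = hk_prob_background,
                          hk_prob_antiridge = hk_prob_antiridge,
                          ts_prob = ts_prob, silent_prob = silent_prob,
                          silent_prob_antiridge = silent_prob_antiridge),
                     class = "simulation_truth")
  list(annotation = ann, truth = truth)
}

#' @export
print.simulation_truth <- function(x, ...) {
  cat(sprintf("Simulation truth: %d planted region(s); coverage RIDGE %.3f, anti-RIDGE %.3f (target %.3f)\n",
              nrow(x$regions), x$coverage[["RIDGE"]],
              x$coverage[["ANTIRIDGE"]], x$coverage_target))
  print(table(x$classes$class))
  invisible(x)
}

#' Simulate an expression matrix over a simulated genome
#'
#' Per-gene, per-tissue log2-scale intensities:
#' `value = mu_bg + domain shift + class term + gene effect + noise`, where
#' the domain shift is `+delta` inside planted RIDGEs and `-delta` inside
#' planted anti-RIDGEs; the class term is `hk_shift` in every tissue for HK
#' genes, `ts_on` in the TS gene's tissue and `ts_off` elsewhere,
#' `silent_shift` everywhere for silent genes, and 0 for intermediate genes;
#' the shared per-gene effect (`Normal(0, sigma_gene)`) induces the high
#' correlation between tissue maps; the noise is
#' `Normal(0, sigma_bg)` per cell. Values are clipped to `clip`. Negative
#' controls are `Normal(nc_mean, nc_sd)`, clipped likewise. Deterministic
#' given `seed`.
#'
#' @param annotation The annotation from [simulate_genome()].
#' @param truth The matching `simulation_truth`.
#' @param seed Integer seed.
#' @param n_tissues Number of tissues (>= 1); defaults to the truth's tissue
#'   panel, truncated or recycled as needed.
#' @param mu_bg,sigma_bg Background mean and per-cell noise s.d. (log2
#'   units; the study's intensity scale runs roughly 9-14).
#' @param sigma_gene S.d. of the shared per-gene effect.
#' @param delta Domain shift in log2 units.
#' @param hk_shift,ts_on,ts_off,silent_shift Class terms in log2 units.
#' @param nc_mean,nc_sd,n_controls Negative-control distribution and pool
#'   size.
#' @param clip Length-2 numeric range values are clipped to.
#' @return An [expression_matrix()] including the negative-control pool.
#' @export
simulate_expression <- function(annotation, truth, seed = 1,
                                n_tissues = NULL,
                                mu_bg = 11, sigma_bg = 0.5, sigma_gene = 0.8,
                                delta = 1.5, hk_shift = 2.5, ts_on = 2.5,
                                ts_off = -1.2, silent_shift = -2.2,
                                nc_mean = 9.3, nc_sd = 0.5, n_controls = 500,
                                clip = c(8, 15)) {
  stopifnot(inherits(annotation, "gene_annotation"),
            inherits(truth, "simulation_truth"))
  cl <- truth$classes
  if (!identical(sort(cl$gene_id), sort(annotation$genes$gene_id)))
    stopf("`truth` does not match `annotation` (different gene sets)")
  tissue_names <- truth$tissues
  if (!is.null(n_tissues)) {
    n_tissues <- as.integer(n_tissues)
    if (is.na(n_tissues) || n_tissues < 1L) stopf("`n_tissues` must be >= 1")
    tissue_names <- if (n_tissues <= length(truth$tissues))
      truth$tissues[seq_len(n_tissues)]
    else sprintf("T%d", seq_len(n_tissues))
  }
  set.seed(as.integer(seed))
  ids <- annotation$genes$gene_id
  cl <- cl[match(ids, cl$gene_id), ]
  n <- length(ids)
  k <- length(tissue_names)
  shift <- ifelse(cl$region == "RIDGE", delta,
                  ifelse(cl$region == "ANTIRIDGE", -delta, 0))
  class_term <- matrix(0, n, k, dimnames = list(ids, tissue_names))
  class_term[cl$class == "HK", ] <- hk_shift
  class_term[cl$class == "silent", ] <- silent_shift
  is_ts <- which(cl$class == "TS")
  for (i in is_ts) {
    class_term[i, ] <- ts_off
    tt <- cl$ts_tissue[i]
    if (tt %in% tissue_names) class_term[i, tt] <- ts_on
    else class_term[i, sample(k, 1)] <- ts_on
  }
  gene_effect <- stats::rnorm(n, 0, sigma_gene)
  noise <- matrix(stats::rnorm(n * k, 0, sigma_bg), n, k)
  vals <- mu_bg + shift + gene_effect + class_term + noise
  vals <- pmin(pmax(vals, clip[1]), clip[2])
  dimnames(vals) <- list(ids, tissue_names)
  nc <- pmin(pmax(stats::rnorm(n_controls, nc_mean, nc_sd), clip[1]), clip[2])
  expression_matrix(vals, negative_controls = nc)
}

#' Write the simulation truth to JSON
#'
#' @param truth A `simulation_truth`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "simulation_truth"))
  out <- list(regions = truth$regions,
              classes = truth$classes,
              coverage = as.list(truth$coverage),
              coverage_target = truth$coverage_target,
              tissues = truth$tissues, seed = truth$seed)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", na = "null")
  invisible(path)
}
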