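#' Variant-selection configuration for the genome-wide burden analysis
#'
#' The genome-wide burden stage keeps variants that are rare in the reference
#' population (MAF <= `maf_threshold`, boundary inclusive), protein-changing,
#' observed at least once, and — as a cross-cohort batch correction —
#' sequenced in strictly more than `group_fraction_threshold` of each of the
#' three groups separately.
#'
#' @param maf_threshold Reference-population minor-allele-frequency cutoff
#'   (default 0.005, i.e. 0.5%; the filter is `ref_maf <= maf_threshold`).
#' @param group_fraction_threshold Per-group sequenced-fraction cutoff
#'   (default 0.80; the filter is strict: fraction `>` threshold).
#' @param protein_changing_classes Functional classes counted as
#'   protein-changing.
#' @return A list of class `selection_config`.
#' @export
selection_config <- function(maf_threshold = 0.005,
                             group_fraction_threshold = 0.80,
                             protein_changing_classes = PROTEIN_CHANGING) {
  stopifnot(maf_threshold > 0, maf_threshold <= 1,
            group_fraction_threshold > 0, group_fraction_threshold <= 1)
  bad <- setdiff(protein_changing_classes, FUNC_CLASSES)
  if (length(bad)) {
    abort(paste0("Unknown functional class(es): ", paste(bad, collapse = ", ")))
  }
  structure(list(maf_threshold = maf_threshold,
                 group_fraction_threshold = group_fraction_threshold,
                 protein_changing_classes = protein_changing_classes),
            class = "selection_config")
}

#' Is a variant protein-changing / rare?
#'
#' Vectorised membership tests against a [selection_config()].
#'
#' @param ann Annotation tibble (rows are variant records).
#' @param config A [selection_config()].
#' @return Logical vector, one element per annotation row.
#' @export
is_protein_changing <- function(ann, config = selection_config()) {
  ann$func_class %in% config$protein_changing_classes
}

#' @rdname is_protein_changing
#' @export
passes_rare_filter <- function(ann, config = selection_config()) {
  ann$ref_maf <= config$maf_threshold
}

#' Per-sample quality-control metrics and outlier flags
#'
#' Computes, per individual: overall call rate (non-missing genotypes /
#' variants), singleton count (variants whose single non-reference allele
#' across all samples is carried by that individual), and heterozygosity rate
#' (heterozygous calls / non-missing calls). An individual is flagged when any
#' metric deviates from the all-sample median by more than `k_mad`
#' median-absolute-deviations (MAD with the usual 1.4826 normal-consistency
#' scale), or when it has no non-missing calls at all.
#'
#' @param gm A [geno_matrix()].
#' @param k_mad Outlier cut in MAD units (default 4).
#' @return Tibble: `sample`, `group`, `call_rate`, `singleton_count`,
#'   `het_rate`, `outlier_flag`.
#' @export
individual_qc <- function(gm, k_mad = 4) {
  stopifnot(inherits(gm, "geno_matrix"), n_samples(gm) > 0, n_variants(gm) > 0)
  g <- gm$geno
  called <- !is.na(g)
  n_called <- rowSums(called)
  call_rate <- n_called / ncol(g)
  ac <- colSums(g, na.rm = TRUE)
  singleton_cols <- which(ac == 1L)
  singleton_count <- if (length(singleton_cols)) {
    rowSums(g[, singleton_cols, drop = FALSE] == 1L, na.rm = TRUE)
  } else {
    rep(0L, nrow(g))
  }
  het_rate <- ifelse(n_called > 0, rowSums(g == 1L, na.rm = TRUE) / n_called, 0)

  flag_metric <- function(x) {
    med <- median(x)
    m <- stats::mad(x)
    # discrete metrics (e.g. singleton counts) can put over half the cohort on
    # the median, collapsing the MAD; fall back to the SD then
    if (m == 0) m <- sd(x)
    if (is.na(m) || m == 0) return(rep(FALSE, length(x)))
    abs(x - med) > k_mad * m
  }
  outlier <- flag_metric(call_rate) | flag_metric(singleton_count) |
    flag_metric(het_rate) | (n_called == 0)
  tibble(sample = rownames(g), group = as.character(gm$group),
         call_rate = unname(call_rate),
         singleton_count = as.integer(unname(singleton_count)),
         het_rate = unname(het_rate), outlier_flag = unname(outlier))
}

#' Per-group sequenced fraction of a variant
#'
#' Fraction of a group's individuals with a non-missing genotype at the
#' variant. `sequenced_fractions()` returns the full variants x groups table.
#'
#' @param gm A [geno_matrix()] with group labels.
#' @param variant A variant key.
#' @param group One of `case`, `epilepsy_control`, `disease_control`.
#' @return A fraction in \[0, 1\].
#' @export
group_sequenced_fraction <- function(gm, variant, group) {
  stopifnot(inherits(gm, "geno_matrix"))
  if (!group %in% GROUPS) abort(paste0("Unknown group: ", group))
  rows <- which(gm$group == group)
  if (!length(rows)) abort(paste0("Group is empty: ", group))
  if (!variant %in% variant_keys(gm)) {
    abort(paste0("Unknown variant key: ", variant))
  }
  mean(!is.na(gm$geno[rows, variant]))
}

#' @rdname group_sequenced_fraction
#' @return For `sequenced_fractions()`, a numeric matrix (variants x 3
#'   groups).
#' @export
sequenced_fractions <- function(gm) {
  stopifnot(inherits(gm, "geno_matrix"))
  out <- vapply(GROUPS, function(g) {
    rows <- which(gm$group == g)
    if (!length(rows)) return(rep(NA_real_, n_variants(gm)))
    colMeans(!is.na(gm$geno[rows, , drop = FALSE]))
  }, numeric(n_variants(gm)))
  matrix(out, nrow = n_variants(gm),
         dimnames = list(variant_keys(gm), GROUPS))
}

#' Select variants for the genome-wide burden analysis
#'
#' Keeps variants that are (a) protein-changing, (b) rare in the reference
#' population, (c) carried by at least one individual, and (d) sequenced in
#' strictly more than the configured fraction of each of the three groups —
#' the batch correction that removes capture-kit coverage artefacts. Variants
#' present in the matrix but absent from the annotation table are excluded
#' with a warning naming their number.
#'
#' @param gm A [geno_matrix()] with group labels.
#' @param ann Annotation tibble.
#' @param config A [selection_config()].
#' @return Character vector of selected variant keys (matrix order).
#' @export
select_genomewide_variants <- function(gm, ann, config = selection_config()) {
  stopifnot(inherits(gm, "geno_matrix"))
  keys <- variant_keys(gm)
  unann <- setdiff(keys, ann$key)
  if (length(unann)) {
    warn(paste0(length(unann),
                " variant(s) without annotation excluded from selection."))
  }
  a <- ann[match(keys, ann$key), ]
  ok <- !is.na(a$key) &
    is_protein_changing(a, config) &
    passes_rare_filter(a, config)
  carried <- colSums(gm$geno, na.rm = TRUE) >= 1L
  sf <- sequenced_fractions(gm)
  covered <- rowSums(sf > config$group_fraction_threshold) == length(GROUPS)
  keys[ok & carried & covered]
}

#' Sweep the sequenced-fraction threshold
#'
#' Re-runs variant selection and per-individual burden scoring over a grid of
#' sequenced-fraction thresholds and reports, for each, the coefficient of
#' variation (sd / mean) of all per-individual burden scores. The threshold
#' minimising score variability is the recommended batch-correction setting;
#' a threshold leaving no selected variants (or an all-zero score vector) has
#' undefined variability, reported as `NA`.
#'
#' @param gm A [geno_matrix()] with group labels.
#' @param ann Annotation tibble.
#' @param thresholds Numeric grid (default `seq(0.5, 0.9, by = 0.1)`).
#' @param config Base [selection_config()]; its `group_fraction_threshold` is
#'   overridden by each grid point.
#' @param statistic `"cv"` (default) or `"var"` — variability measure.
#' @return Tibble: `threshold`, `n_variants`, `variability`, `is_argmin`
#'   (TRUE on the defined minimiser).
#' @export
sweep_group_fraction_threshold <- function(gm, ann,
                                           thresholds = seq(0.5, 0.9, by = 0.1),
                                           config = selection_config(),
                                           statistic = c("cv", "var")) {
  statistic <- match.arg(statistic)
  stopifnot(length(thresholds) >= 1, all(thresholds > 0), all(thresholds <= 1))
  res <- purrr::map(thresholds, function(th) {
    cfg <- config
    cfg$group_fraction_threshold <- th
    sel <- select_genomewide_variants(gm, ann, cfg)
    if (!length(sel)) {
      return(tibble(threshold = th, n_variants = 0L, variability = NA_real_))
    }
    prof <- compute_burden_profiles(gm, sel, ann)
    v <- if (statistic == "cv") {
      m <- mean(prof$burden_score)
      if (m == 0) NA_real_ else sd(prof$burden_score) / m
    } else {
      stats::var(prof$burden_score)
    }
    tibble(threshold = th, n_variants = length(sel), variability = v)
  })
  out <- bind_rows(res)
  out$is_argmin <- FALSE
  if (any(!is.na(out$variability))) {
    out$is_argmin[which.min(out$variability)] <- TRUE
  }
  out
}
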