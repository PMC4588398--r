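#' Per-individual deleteriousness burden profiles
#'
#' For each individual, sums the scaled deleteriousness (CADD) score of every
#' selected variant the individual carries, and counts those variants.
#' "Carried" means genotype code 1 or 2; by default each carried variant
#' contributes its score once per carrier regardless of zygosity
#' (presence-based), with an allele-dosage mode behind `dosage = TRUE`.
#' Missing genotypes contribute nothing.
#'
#' @param gm A [geno_matrix()].
#' @param selected Character vector of selected variant keys (a subset of the
#'   matrix's variants, each with an annotation row).
#' @param ann Annotation tibble supplying `cadd_scaled` per key.
#' @param dosage If `TRUE`, a homozygous carrier contributes the score twice.
#' @return Tibble: `sample`, `group`, `burden_score`, `variant_count`.
#' @export
compute_burden_profiles <- function(gm, selected, ann, dosage = FALSE) {
  stopifnot(inherits(gm, "geno_matrix"))
  if (!all(selected %in% variant_keys(gm))) {
    abort("Some selected variants are absent from the genotype matrix.")
  }
  scores <- ann$cadd_scaled[match(selected, ann$key)]
  if (anyNA(scores)) {
    abort(paste0("Selected variant(s) without annotation: ",
                 paste(head(selected[is.na(scores)], 3), collapse = ", ")))
  }
  g <- gm$geno[, selected, drop = FALSE]
  carrier <- !is.na(g) & g >= 1L
  weight <- if (dosage) ifelse(carrier, g, 0L) else carrier * 1L
  weight[is.na(weight)] <- 0L
  tibble(
    sample = sample_ids(gm),
    group = as.character(gm$group),
    burden_score = as.numeric(weight %*% scores),
    variant_count = as.integer(rowSums(carrier))
  )
}

#' Wilcoxon rank-sum test (Stata ranksum convention)
#'
#' Two-sample rank-sum test using mid-ranks for ties and the tie-corrected
#' normal approximation **without** continuity correction; when the pooled
#' sample size is at most 12, the two-sided p-value comes from exact
#' enumeration of all rank splits (tail defined by distance of the rank sum
#' from its null expectation, which handles tied data). When every value in
#' both groups is identical, z = 0 and p = 1.
#'
#' @param a,b Numeric vectors (each non-empty).
#' @param exact_max Pooled-size limit for the exact branch (default 12).
#' @return A list: `z` (tie-corrected normal statistic), `p` (two-sided),
#'   `method` (`"exact"` or `"normal"`).
#' @examples
#' wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))$p  # exact: 0.1
#' @export
wilcoxon_rank_sum <- function(a, b, exact_max = 12) {
  a <- as.numeric(a); b <- as.numeric(b)
  stopifnot(length(a) >= 1, length(b) >= 1)
  n_a <- length(a); n_b <- length(b); N <- n_a + n_b
  pooled <- c(a, b)
  r <- rank(pooled)                       # mid-ranks
  W <- sum(r[seq_len(n_a)])               # rank sum of group a
  E <- n_a * (N + 1) / 2
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties) / (N * (N - 1))
  V <- n_a * n_b / 12 * ((N + 1) - tie_term)
  if (V <= 0) return(list(z = 0, p = 1, method = "degenerate"))
  z <- (W - E) / sqrt(V)
  if (N <= exact_max) {
    splits <- combn(N, n_a)
    Wperm <- colSums(matrix(r[splits], nrow = n_a))
    p <- mean(abs(Wperm - E) >= abs(W - E) - 1e-9)
    return(list(z = z, p = p, method = "exact"))
  }
  list(z = z, p = min(1, 2 * pnorm(-abs(z))), method = "normal")
}

burden_pairs <- function() {
  tibble(
    group_a = c("case", "case", "epilepsy_control"),
    group_b = c("epilepsy_control", "disease_control", "disease_control")
  )
}

#' Pairwise group comparisons of burden profiles
#'
#' Runs the two-tailed Wilcoxon rank-sum test for each of the three group
#' pairs on both per-individual metrics (burden score and variant count): six
#' tests, Bonferroni-corrected at `alpha = 0.05 / n_tests`.
#'
#' @param profiles Profile tibble from [compute_burden_profiles()].
#' @param n_tests Number of tests in the Bonferroni family (default 6).
#' @param base_alpha Family-wise level (default 0.05).
#' @return Tibble: `metric`, `group_a`, `group_b`, `n_a`, `n_b`,
#'   `z_statistic`, `p_two_sided`, `bonferroni_alpha`, `significant`.
#' @export
compare_groups <- function(profiles, n_tests = 6, base_alpha = 0.05) {
  alpha <- base_alpha / n_tests
  pairs <- burden_pairs()
  purrr::map_dfr(c("burden_score", "variant_count"), function(metric) {
    purrr::pmap_dfr(pairs, function(group_a, group_b) {
      va <- profiles[[metric]][profiles$group == group_a]
      vb <- profiles[[metric]][profiles$group == group_b]
      if (!length(va) || !length(vb)) {
        abort(paste0("Empty group in comparison: ", group_a, " vs ", group_b))
      }
      w <- wilcoxon_rank_sum(va, vb)
      tibble(metric = metric, group_a = group_a, group_b = group_b,
             n_a = length(va), n_b = length(vb),
             z_statistic = w$z, p_two_sided = w$p,
             bonferroni_alpha = alpha, significant = w$p < alpha)
    })
  })
}

#' Group-level summary of burden profiles
#'
#' Mean, median and interquartile range of both per-individual metrics per
#' group — the layout of a burden-analysis summary table. Quartiles use the
#' default (type 7) sample quantile.
#'
#' @param profiles Profile tibble from [compute_burden_profiles()].
#' @return Tibble: `metric`, `group`, `n`, `mean`, `median`, `q1`, `q3`,
#'   `iqr`.
#' @export
burden_summary <- function(profiles) {
  long <- tidyr::pivot_longer(profiles, c("burden_score", "variant_count"),
                              names_to = "metric", values_to = "value")
  long |>
    group_by(.data$metric, .data$group) |>
    summarise(
      n = dplyr::n(),
      mean = mean(.data$value),
      median = median(.data$value),
      q1 = quantile(.data$value, 0.25),
      q3 = quantile(.data$value, 0.75),
      iqr = .data$q3 - .data$q1,
      .groups = "drop"
    )
}

#' Genome-wide burden analysis
#'
#' End-to-end driver: selects variants ([select_genomewide_variants()]),
#' computes per-individual burden profiles, and compares the three groups by
#' Wilcoxon rank-sum tests with Bonferroni control over six tests. Optionally
#' removes all of one gene's variants from the selected set first (post hoc
#' single-gene-exclusion re-analysis); excluding a gene with no variants in
#' the selected set is a warning-level no-op.
#'
#' @param gm A [geno_matrix()] with group labels.
#' @param ann Annotation tibble.
#' @param config A [selection_config()].
#' @param exclude_gene Optional gene symbol to drop from the selected set.
#' @param n_tests Bonferroni family size (default 6).
#' @param dosage Passed to [compute_burden_profiles()].
#' @return An object of class `burden_fit`: list with `selected`, `profiles`,
#'   `comparisons`, `summary`, `exclude_gene`.
#' @export
burden_analysis <- function(gm, ann, config = selection_config(),
                            exclude_gene = NULL, n_tests = 6,
                            dosage = FALSE) {
  selected <- select_genomewide_variants(gm, ann, config)
  if (!is.null(exclude_gene)) {
    selected <- exclude_gene_variants(selected, ann, exclude_gene)
  }
  profiles <- compute_burden_profiles(gm, selected, ann, dosage = dosage)
  structure(
    list(selected = selected,
         profiles = profiles,
         comparisons = compare_groups(profiles, n_tests = n_tests),
         summary = burden_summary(profiles),
         exclude_gene = exclude_gene),
    class = "burden_fit"
  )
}

#' Remove one gene's variants from a selected set
#'
#' @param selected Character vector of selected variant keys.
#' @param ann Annotation tibble.
#' @param gene Gene symbol.
#' @return The reduced key vector; warns (and returns the set unchanged) when
#'   the gene has no variants in the set.
#' @export
exclude_gene_variants <- function(selected, ann, gene) {
  gene_keys <- ann$key[ann$gene == gene]
  if (!any(selected %in% gene_keys)) {
    warn(paste0("Gene ", gene,
                " has no variants in the selected set; nothing excluded."))
    return(selected)
  }
  setdiff(selected, gene_keys)
}

#' @export
print.burden_fit <- function(x, ...) {
  cat("<burden_fit> ", length(x$selected), " selected variants, ",
      nrow(x$profiles), " individuals\n", sep = "")
  if (!is.null(x$exclude_gene)) {
    cat("  post hoc exclusion of gene: ", x$exclude_gene, "\n", sep = "")
  }
  print(x$comparisons)
  invisible(x)
}

#' @rdname burden_analysis
#' @param x A `burden_fit`.
#' @param ... Unused.
#' @method tidy burden_fit
#' @export
tidy.burden_fit <- function(x, ...) x$comparisons

#' @rdname burden_analysis
#' @method glance burden_fit
#' @export
glance.burden_fit <- function(x, ...) {
  tibble(
    n_selected = length(x$selected),
    n_samples = nrow(x$profiles),
    n_tests = nrow(x$comparisons),
    bonferroni_alpha = x$comparisons$bonferroni_alpha[1],
    n_significant = sum(x$comparisons$significant)
  )
}
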