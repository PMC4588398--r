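#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value by the probability-mass rule: the sum of hypergeometric
#' probabilities of all tables with the same margins whose probability does
#' not exceed the observed table's. A table with a zero margin carries no
#' information and returns p = 1.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @param alternative `"prob_mass"` (default) or `"double_tail"` (twice the
#'   smaller one-sided tail, capped at 1).
#' @return Two-sided p-value.
#' @examples
#' fisher_exact_2x2(matrix(c(13, 36, 5, 51), 2))  # ~0.021
#' @export
fisher_exact_2x2 <- function(table, alternative = c("prob_mass", "double_tail")) {
  alternative <- match.arg(alternative)
  table <- as.matrix(table)
  stopifnot(all(dim(table) == 2), all(table >= 0),
            all(table == round(table)))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) return(1)
  if (alternative == "prob_mass") {
    return(stats::fisher.test(table)$p.value)
  }
  m <- sum(table[1, ]); n <- sum(table[2, ]); k <- sum(table[, 1])
  x <- table[1, 1]
  lo <- max(0, k - n); hi <- min(k, m)
  lower <- sum(dhyper(lo:x, m, n, k))
  upper <- sum(dhyper(x:hi, m, n, k))
  min(1, 2 * min(lower, upper))
}

#' Pearson chi-squared test
#'
#' Classic Pearson statistic on an r x c contingency table, df =
#' (r-1)(c-1), upper-tail chi-squared p-value, no continuity correction.
#' All-zero rows or columns are dropped with a warning before testing.
#'
#' @param table r x c matrix of non-negative counts.
#' @return List: `chi2`, `df`, `p`.
#' @export
pearson_chi2 <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(table >= 0))
  zr <- rowSums(table) == 0; zc <- colSums(table) == 0
  if (any(zr) || any(zc)) {
    warn("Dropping all-zero row(s)/column(s) from contingency table.")
    table <- table[!zr, !zc, drop = FALSE]
  }
  if (nrow(table) < 2 || ncol(table) < 2) {
    return(list(chi2 = 0, df = 0L, p = 1))
  }
  ct <- suppressWarnings(chisq.test(table, correct = FALSE))
  list(chi2 = unname(ct$statistic), df = unname(ct$parameter),
       p = unname(ct$p.value))
}

#' Two-sample t-test on raw values
#'
#' Two-sided, pooled-variance by default (Welch via `welch = TRUE`). When
#' both groups are constant the test is degenerate: p = 1 if the means are
#' equal, p = 0 otherwise.
#'
#' @param a,b Numeric vectors, at least 2 values each.
#' @param welch Use the Welch (unequal-variance) form.
#' @return Two-sided p-value.
#' @export
ttest_from_samples <- function(a, b, welch = FALSE) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (sd(a) == 0 && sd(b) == 0) {
    return(if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0)
  }
  t.test(a, b, var.equal = !welch)$p.value
}

#' Expected event count from an incidence rate
#'
#' `incidence_per_1000py x person_years / 1000`, reported both exactly and
#' rounded to the nearest whole event. Used for the expected number of
#' case-phenotype deaths among controls given published incidence and the
#' cohort's summed years at risk.
#'
#' @param incidence_per_1000py Events per 1000 person-years (>= 0).
#' @param person_years Summed person-years at risk (>= 0).
#' @return List: `expected_real`, `expected_rounded`.
#' @examples
#' expected_event_count(5.9, 2563)  # 15.12 -> 15
#' @export
expected_event_count <- function(incidence_per_1000py, person_years) {
  stopifnot(incidence_per_1000py >= 0, person_years >= 0)
  e <- incidence_per_1000py * person_years / 1000
  list(expected_real = e, expected_rounded = as.integer(round(e)))
}

#' Bonferroni-corrected significance threshold
#'
#' @param n_tests Number of tests in the family.
#' @param base_alpha Family-wise level (default 0.05).
#' @return `base_alpha / n_tests`.
#' @export
bonferroni_alpha <- function(n_tests, base_alpha = 0.05) {
  stopifnot(n_tests >= 1)
  base_alpha / n_tests
}

#' Round to significant digits, halves away from zero
#'
#' Reporting helper matching the usual manuscript convention (0.00625 at two
#' significant digits prints as 0.0063, where round-half-even would give
#' 0.0062).
#'
#' @param x Numeric vector.
#' @param digits Significant digits to keep.
#' @return Rounded numeric vector.
#' @export
signif_half_up <- function(x, digits = 2) {
  out <- x
  nz <- !is.na(x) & x != 0
  m <- floor(log10(abs(x[nz])))
  f <- 10^(digits - 1 - m)
  out[nz] <- sign(x[nz]) * floor(abs(x[nz]) * f + 0.5) / f
  out
}

# yes/no tri-state column -> 2x2 table vs group, complete cases only
tri_state_table <- function(man, col) {
  v <- man[[col]]
  ok <- !is.na(v)
  if (!any(ok)) return(NULL)
  tab <- table(factor(v[ok], levels = c("yes", "no")),
               factor(man$group[ok], levels = c("case", "epilepsy_control")))
  matrix(tab, 2, 2, dimnames = dimnames(tab))
}

#' Clinical risk-factor comparison panel
#'
#' Compares cases against epilepsy controls on the cohort-description
#' variables, each with its conventional test: Fisher's exact for binary
#' factors (sex = male, living alone, convulsive and nocturnal seizures in the
#' prior 12 months), Pearson chi-squared for syndrome classification and
#' intellectual disability, Wilcoxon rank-sum for age at first seizure,
#' epilepsy duration and number of anti-epileptic drugs, and a t-test for age
#' at last follow-up. Unknown (`NA`) values are excluded per row
#' (complete-case denominators). The Bonferroni family covers the
#' `n_tests = 8` established risk factors; the age-at-follow-up row is
#' descriptive and reported against the same corrected level.
#'
#' @param manifest Manifest tibble (see [read_manifest()]); only `case` and
#'   `epilepsy_control` rows are used.
#' @param n_tests Bonferroni family size (default 8).
#' @param base_alpha Family-wise level (default 0.05).
#' @return Tibble: `variable`, `test`, `n_case`, `n_control`, `p`,
#'   `bonferroni_alpha`, `significant`, `tested` (FALSE when a row had no
#'   usable data).
#' @export
risk_factor_panel <- function(manifest, n_tests = 8, base_alpha = 0.05) {
  man <- manifest[manifest$group %in% c("case", "epilepsy_control"), ]
  if (!nrow(man)) abort("Manifest contains no case/epilepsy_control samples.")
  alpha <- bonferroni_alpha(n_tests, base_alpha)
  is_case <- man$group == "case"

  row_out <- function(variable, test, n_case, n_control, p) {
    tibble(variable = variable, test = test,
           n_case = n_case, n_control = n_control, p = p,
           bonferroni_alpha = alpha,
           significant = !is.na(p) & p < alpha,
           tested = !is.na(p))
  }
  cont_row <- function(variable, col, test_fn, test_name) {
    a <- man[[col]][is_case]; b <- man[[col]][!is_case]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    p <- if (length(a) >= 2 && length(b) >= 2) test_fn(a, b) else NA_real_
    row_out(variable, test_name, length(a), length(b), p)
  }
  fisher_row <- function(variable, tab) {
    p <- if (is.null(tab)) NA_real_ else fisher_exact_2x2(tab)
    n <- if (is.null(tab)) c(0L, 0L) else colSums(tab)
    row_out(variable, "fisher_exact", n[1], n[2], p)
  }

  sex_tab <- {
    ok <- !is.na(man$sex)
    tab <- table(factor(man$sex[ok] == "male", levels = c(TRUE, FALSE)),
                 factor(man$group[ok], levels = c("case", "epilepsy_control")))
    matrix(tab, 2, 2)
  }
  syn_ok <- !is.na(man$syndrome)
  syn_tab <- table(man$syndrome[syn_ok],
                   factor(man$group[syn_ok],
                          levels = c("case", "epilepsy_control")))
  id_tab <- tri_state_table(man, "intellectual_disability")

  bind_rows(
    cont_row("age_last_followup", "age_last_followup", ttest_from_samples,
             "t_test"),
    fisher_row("sex_male", sex_tab),
    row_out("syndrome", "pearson_chi2",
            sum(syn_ok & is_case), sum(syn_ok & !is_case),
            if (sum(syn_ok)) pearson_chi2(syn_tab)$p else NA_real_),
    cont_row("age_first_seizure", "age_first_seizure",
             function(a, b) wilcoxon_rank_sum(a, b)$p, "wilcoxon_rank_sum"),
    cont_row("epilepsy_duration", "epilepsy_duration",
             function(a, b) wilcoxon_rank_sum(a, b)$p, "wilcoxon_rank_sum"),
    row_out("intellectual_disability", "pearson_chi2",
            if (is.null(id_tab)) 0L else sum(id_tab[, 1]),
            if (is.null(id_tab)) 0L else sum(id_tab[, 2]),
            if (is.null(id_tab)) NA_real_ else pearson_chi2(id_tab)$p),
    cont_row("n_aeds", "n_aeds",
             function(a, b) wilcoxon_rank_sum(a, b)$p, "wilcoxon_rank_sum"),
    fisher_row("lives_alone", tri_state_table(man, "lives_alone")),
    fisher_row("convulsive_seizures_12m",
               tri_state_table(man, "convulsive_seizures_12m")),
    fisher_row("nocturnal_seizures_12m",
               tri_state_table(man, "nocturnal_seizures_12m"))
  )
}
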