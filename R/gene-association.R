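#' Adaptive permutation plan
#'
#' Controls the label-swapping permutation scheme used for gene-based
#' empirical p-values. Permutation for a gene stops early once both test
#' statistics have been met or exceeded `exceedance_stop` times (the gene is
#' then clearly not associated at any interesting level), or at `b_max`
#' permutations.
#'
#' @param b_max Maximum permutations per gene (default 1e6).
#' @param exceedance_stop Early-stop exceedance count r (default 100);
#'   a gene's p-value is then roughly r / permutations with ~10% relative
#'   Monte-Carlo error.
#' @param batch Permutations per batch between stop checks (default 1000).
#' @param seed Integer seed for the permutation stream.
#' @param i_threshold Power threshold on the I-value: genes with
#'   `i_value >= i_threshold` are underpowered and excluded from the
#'   multiple-testing family (default 1e-3).
#' @param base_alpha Family-wise level (default 0.05).
#' @param tests_per_gene Association tests per gene entering the Bonferroni
#'   family (default 2: burden and C-alpha).
#' @return A list of class `permutation_plan`.
#' @export
permutation_plan <- function(b_max = 1e6, exceedance_stop = 100, batch = 1000,
                             seed = 1L, i_threshold = 1e-3, base_alpha = 0.05,
                             tests_per_gene = 2) {
  stopifnot(b_max >= batch, batch >= 1, exceedance_stop >= 1,
            i_threshold > 0, base_alpha > 0, tests_per_gene >= 1)
  structure(list(b_max = as.integer(b_max),
                 exceedance_stop = as.integer(exceedance_stop),
                 batch = as.integer(batch), seed = as.integer(seed),
                 i_threshold = i_threshold, base_alpha = base_alpha,
                 tests_per_gene = as.integer(tests_per_gene)),
            class = "permutation_plan")
}

#' Build per-gene unique-variant sets
#'
#' Applies the gene-analysis variant refinement: protein-changing, rare
#' (reference MAF <= the selection config's threshold), scaled CADD >=
#' `cadd_min`, and observed at least once in any cohort. Variants with any
#' non-reference allele in the epilepsy-control cohort are flagged
#' (`excluded_epi`) and dropped from the tested set — the epilepsy-control
#' exclusion that enriches for risk specific to the case phenotype over
#' epilepsy itself. Allele counts are computed over genotyped individuals
#' only: a missing genotype is excluded from both numerator and denominator.
#'
#' @param gm A [geno_matrix()] with group labels.
#' @param ann Annotation tibble.
#' @param config A [selection_config()] (supplies the MAF threshold and
#'   protein-changing classes).
#' @param cadd_min Scaled-CADD cutoff (default 15; filter is `>=`).
#' @return Tibble, one row per refined variant: `gene`, `key`, `cadd_scaled`,
#'   allele counts `y_case`, `y_epi`, `y_ctrl`, genotyped counts
#'   `n_geno_case`, `n_geno_epi`, `n_geno_ctrl`, flags `excluded_epi`,
#'   `retained`, `case_exclusive`, `ctrl_exclusive`. Exclusivity is evaluated
#'   against the case and disease-control groups only; a variant seen in both
#'   belongs to neither exclusive set.
#' @export
build_gene_sets <- function(gm, ann, config = selection_config(),
                            cadd_min = 15) {
  stopifnot(inherits(gm, "geno_matrix"))
  keys <- variant_keys(gm)
  a <- ann[match(keys, ann$key), ]
  pass <- !is.na(a$key) &
    is_protein_changing(a, config) &
    passes_rare_filter(a, config) &
    a$cadd_scaled >= cadd_min
  g <- gm$geno
  grp <- as.character(gm$group)
  count_group <- function(lab) {
    rows <- grp == lab
    list(y = colSums(g[rows, , drop = FALSE], na.rm = TRUE),
         n = colSums(!is.na(g[rows, , drop = FALSE])))
  }
  cs <- count_group("case")
  ep <- count_group("epilepsy_control")
  ct <- count_group("disease_control")
  seen <- (cs$y + ep$y + ct$y) >= 1L
  keep <- pass & seen
  out <- tibble(
    gene = a$gene[keep], key = keys[keep], cadd_scaled = a$cadd_scaled[keep],
    y_case = as.integer(cs$y[keep]), y_epi = as.integer(ep$y[keep]),
    y_ctrl = as.integer(ct$y[keep]),
    n_geno_case = as.integer(cs$n[keep]), n_geno_epi = as.integer(ep$n[keep]),
    n_geno_ctrl = as.integer(ct$n[keep])
  )
  out |>
    mutate(
      excluded_epi = .data$y_epi > 0L,
      retained = !.data$excluded_epi & (.data$y_case + .data$y_ctrl) >= 1L,
      case_exclusive = .data$retained & .data$y_case > 0L & .data$y_ctrl == 0L,
      ctrl_exclusive = .data$retained & .data$y_ctrl > 0L & .data$y_case == 0L
    ) |>
    arrange(.data$gene, .data$key)
}

#' Cumulative minor allele frequency, percent
#'
#' The gene-level cumulative non-reference allele count expressed as a
#' percentage of genotyped chromosomes: `100 * count / (2 * n_genotyped)`,
#' rounded to two decimals for reporting.
#'
#' @param allele_count Cumulative non-reference allele count (>= 0).
#' @param n_genotyped Number of genotyped diploid individuals (>= 1).
#' @return Percentage, rounded to 2 decimal places.
#' @examples
#' cumulative_maf_pct(2, 18)  # 5.56
#' @export
cumulative_maf_pct <- function(allele_count, n_genotyped) {
  stopifnot(all(n_genotyped >= 1), all(allele_count >= 0))
  round(100 * allele_count / (2 * n_genotyped), 2)
}

#' Unique-variant burden statistic
#'
#' One-tailed statistic for an increased rare allele rate in cases: the sum of
#' case allele counts over the gene's case-exclusive variants (those with no
#' alternate allele in disease controls). Larger means more case-specific
#' burden; control-exclusive content does not change it.
#'
#' @param gene_set Per-variant tibble for one gene (rows of
#'   [build_gene_sets()] with `retained`, or anything with `y_case`,
#'   `y_ctrl`).
#' @return Integer statistic.
#' @export
burden_statistic <- function(gene_set) {
  gs <- if ("retained" %in% names(gene_set)) {
    gene_set[gene_set$retained, ]
  } else {
    gene_set
  }
  burden_stat_vec(gs$y_case, gs$y_ctrl)
}

burden_stat_vec <- function(y_case, y_ctrl) {
  as.integer(sum(y_case[y_ctrl == 0L]))
}

#' C-alpha overdispersion statistic
#'
#' For each variant i with `n_i >= 1` total alternate-allele copies among
#' genotyped cases and disease controls, compares the observed case share
#' `y_i` with its binomial expectation under the null,
#' `p0_i = n_geno_case_i / (n_geno_case_i + n_geno_ctrl_i)`:
#' \deqn{T = \sum_i (y_i - n_i p_{0i})^2 - n_i p_{0i} (1 - p_{0i}).}
#' Large T indicates departure from binomial sharing in either direction
#' (a mixture of risk and protective alleles inflates it), which is what
#' makes the test two-tailed; significance is assessed on the upper tail of
#' T's permutation distribution.
#'
#' @param gene_set Per-variant tibble for one gene (as for
#'   [burden_statistic()]; needs `y_case`, `y_ctrl` and, unless `p0` is
#'   given, `n_geno_case`, `n_geno_ctrl`).
#' @param p0 Optional per-variant null case share; computed from the
#'   genotyped counts when omitted.
#' @return The statistic, or `NA` when no variant has `n_i >= 1` (gene
#'   skipped).
#' @export
calpha_statistic <- function(gene_set, p0 = NULL) {
  gs <- if ("retained" %in% names(gene_set)) {
    gene_set[gene_set$retained, ]
  } else {
    gene_set
  }
  if (is.null(p0)) {
    p0 <- gs$n_geno_case / (gs$n_geno_case + gs$n_geno_ctrl)
  }
  calpha_stat_vec(gs$y_case, gs$y_case + gs$y_ctrl, p0)
}

calpha_stat_vec <- function(y, n, p0) {
  use <- n >= 1L
  if (!any(use)) return(NA_real_)
  y <- y[use]; n <- n[use]; p0 <- p0[use]
  sum((y - n * p0)^2 - n * p0 * (1 - p0))
}

# Per-gene permutation data: genotypes of case + disease-control individuals
# at the gene's retained variants. Epilepsy controls are excluded from this
# analysis entirely.
gene_perm_data <- function(gm, keys) {
  rows <- which(gm$group %in% c("case", "disease_control"))
  g <- gm$geno[rows, keys, drop = FALSE]
  C <- g
  C[is.na(C)] <- 0L
  list(
    C = C,                       # allele counts, missing as 0
    miss = is.na(g),             # missingness mask
    case_rows = which(as.character(gm$group)[rows] == "case"),
    n_total = length(rows)
  )
}

# both statistics from an assignment of case rows
gene_stats_for_labels <- function(pd, case_rows) {
  y_case <- colSums(pd$C[case_rows, , drop = FALSE])
  y_tot <- colSums(pd$C)
  y_ctrl <- y_tot - y_case
  n_case <- length(case_rows)
  n_geno_case <- n_case - colSums(pd$miss[case_rows, , drop = FALSE])
  n_geno_tot <- pd$n_total - colSums(pd$miss)
  p0 <- n_geno_case / n_geno_tot
  c(burden = burden_stat_vec(y_case, y_ctrl),
    calpha = calpha_stat_vec(y_case, y_tot, p0))
}

#' Adaptive permutation empirical p-value
#'
#' Estimates `Pr(statistic >= observed)` under uniform swapping of the
#' case/disease-control phenotype labels, recomputing the statistic — and
#' with it the case-exclusivity partition, which moves with the labels — in
#' every permutation. The empirical p-value is `(k + 1) / (B + 1)` with `k`
#' exceedances in `B` permutations; permutation stops early when `k` reaches
#' the plan's `exceedance_stop`, and a gene that exhausts `b_max` is flagged.
#' Deterministic given the plan seed.
#'
#' @param statistic_fn Function `(perm_data, case_rows) -> numeric`; the
#'   default computes the unique-variant burden statistic. Use
#'   `statistic = "calpha"` for the C-alpha statistic.
#' @param gm A [geno_matrix()] with group labels.
#' @param keys Retained variant keys of the gene.
#' @param plan A [permutation_plan()].
#' @param statistic Shortcut selecting a built-in statistic
#'   (`"burden"` or `"calpha"`) when `statistic_fn` is `NULL`.
#' @return List: `p`, `perms_used`, `exceedances`, `hit_b_max`, `observed`.
#' @export
adaptive_permutation <- function(gm, keys, plan = permutation_plan(),
                                 statistic = c("burden", "calpha"),
                                 statistic_fn = NULL) {
  statistic <- match.arg(statistic)
  pd <- gene_perm_data(gm, keys)
  if (is.null(statistic_fn)) {
    idx <- if (statistic == "burden") 1L else 2L
    statistic_fn <- function(pd, case_rows) {
      gene_stats_for_labels(pd, case_rows)[idx]
    }
  }
  withr::with_seed(plan$seed, {
    obs <- statistic_fn(pd, pd$case_rows)
    n_case <- length(pd$case_rows)
    k <- 0L; B <- 0L
    while (B < plan$b_max && k < plan$exceedance_stop) {
      nb <- min(plan$batch, plan$b_max - B)
      for (i in seq_len(nb)) {
        perm <- sample.int(pd$n_total, n_case)
        if (statistic_fn(pd, perm) >= obs - 1e-9) k <- k + 1L
      }
      B <- B + nb
      if (k >= plan$exceedance_stop) break
    }
    list(p = (k + 1) / (B + 1), perms_used = B, exceedances = k,
         hit_b_max = (B >= plan$b_max && k < plan$exceedance_stop),
         observed = unname(obs))
  })
}

# shared-permutation version: one label stream drives both statistics
permute_gene_pvalues <- function(pd, plan) {
  obs <- gene_stats_for_labels(pd, pd$case_rows)
  n_case <- length(pd$case_rows)
  k <- c(burden = 0L, calpha = 0L)
  B <- 0L
  while (B < plan$b_max &&
         (k[1] < plan$exceedance_stop || k[2] < plan$exceedance_stop)) {
    nb <- min(plan$batch, plan$b_max - B)
    for (i in seq_len(nb)) {
      perm <- sample.int(pd$n_total, n_case)
      s <- gene_stats_for_labels(pd, perm)
      k <- k + (s >= obs - 1e-9)
    }
    B <- B + nb
  }
  list(p = (k + 1) / (B + 1), perms_used = B, exceedances = k,
       hit_b_max = (B >= plan$b_max && any(k < plan$exceedance_stop)),
       observed = obs)
}

#' Smallest achievable empirical p-value (I-value)
#'
#' The probability, under uniform phenotype-label permutation over the case
#' and disease-control individuals, of the label assignment(s) attaining the
#' maximal statistic — i.e. all of the gene's carrier individuals labelled as
#' cases. For `c` distinct carriers, `n_case` cases among `N` individuals:
#' \deqn{I = \prod_{j=0}^{c-1} \frac{n_{case} - j}{N - j},}
#' evaluated through an exact hypergeometric count when `c <= 6` and through
#' the running product otherwise (the two coincide analytically; the split
#' guards against overflow in the binomial coefficients for large counts).
#' When `c > n_case` not all carriers can be cases and the formula becomes
#' the probability that every case is a carrier. A gene with no carriers has
#' I = 1. Genes with `I >=` the plan's threshold are underpowered: no
#' attainable empirical p-value could pass a meaningful corrected threshold.
#'
#' @param n_carriers Number of distinct carrier individuals c.
#' @param n_case Number of case-labelled individuals.
#' @param n_total Total individuals N in the permuted set.
#' @return The I-value in (0, 1].
#' @examples
#' i_value(2, 18, 1497)  # ~1.37e-4
#' @export
i_value <- function(n_carriers, n_case, n_total) {
  stopifnot(n_carriers >= 0, n_case >= 1, n_total >= n_case,
            n_carriers <= n_total)
  c <- n_carriers
  if (c == 0) return(1)
  if (c > n_case) {
    # max statistic: every case is a carrier
    return(exp(lchoose(c, n_case) - lchoose(n_total, n_case)))
  }
  if (c <= 6) {
    return(choose(n_total - c, n_case - c) / choose(n_total, n_case))
  }
  prod((n_case - seq_len(c) + 1) / (n_total - seq_len(c) + 1))
}

#' Adjusted Bonferroni correction over powered genes
#'
#' The multiple-testing family contains only genes powered to reach
#' significance: those with `i_value <` the plan's `i_threshold`. With `G`
#' such genes and `tests_per_gene` tests each, the corrected level is
#' `base_alpha / (tests_per_gene * G)`. With no powered genes, no tests are
#' declared and all flags are `FALSE`.
#'
#' @param results Gene-level tibble with columns `i_value`, `p_burden`,
#'   `p_calpha`.
#' @param plan A [permutation_plan()].
#' @return `results` with columns `tested`, `alpha_adjusted`,
#'   `significant_burden`, `significant_calpha`, `significant` added.
#' @export
adjusted_bonferroni <- function(results, plan = permutation_plan()) {
  tested <- results$i_value < plan$i_threshold
  m <- plan$tests_per_gene * sum(tested)
  alpha <- if (m == 0) NA_real_ else plan$base_alpha / m
  results |>
    mutate(
      tested = tested,
      alpha_adjusted = alpha,
      significant_burden = tested & !is.na(alpha) & .data$p_burden < alpha,
      significant_calpha = tested & !is.na(alpha) & .data$p_calpha < alpha,
      significant = .data$significant_burden | .data$significant_calpha
    )
}

#' Gene-based unique-variant association analysis
#'
#' End-to-end driver for the gene stage: refines variants
#' ([build_gene_sets()]), computes per-gene cumulative allele counts and
#' cumulative MAF percentages, the observed burden and C-alpha statistics,
#' adaptive-permutation empirical p-values (one label stream per gene driving
#' both tests), I-values, and the adjusted Bonferroni significance flags.
#' Epilepsy controls take no part in the tests: they act only through the
#' variant-exclusion filter.
#'
#' Gene-level cumulative-MAF denominators are the mean per-variant genotyped
#' count over the gene's contributing variants, rounded to the nearest
#' individual.
#'
#' @param gm A [geno_matrix()] with group labels.
#' @param ann Annotation tibble.
#' @param plan A [permutation_plan()].
#' @param config A [selection_config()].
#' @param cadd_min Scaled-CADD refinement cutoff (default 15).
#' @return Object of class `gene_assoc`: list with `genes` (one row per
#'   tested gene), `variants` (the refined per-variant table) and `plan`.
#' @export
gene_association <- function(gm, ann, plan = permutation_plan(),
                             config = selection_config(), cadd_min = 15) {
  variants <- build_gene_sets(gm, ann, config, cadd_min)
  ret <- variants[variants$retained, ]
  genes <- unique(ret$gene)
  n_case <- sum(gm$group == "case")
  n_total <- sum(gm$group %in% c("case", "disease_control"))

  rows <- withr::with_seed(plan$seed, purrr::map(genes, function(gn) {
    gs <- ret[ret$gene == gn, ]
    pd <- gene_perm_data(gm, gs$key)
    carriers <- sum(rowSums(pd$C) > 0L)
    iv <- i_value(carriers, n_case, n_total)
    pp <- permute_gene_pvalues(pd, plan)
    all_rows <- variants[variants$gene == gn, ]
    tibble(
      gene = gn,
      n_variants = nrow(gs),
      n_carriers = carriers,
      cum_case_alleles = sum(gs$y_case),
      cum_ctrl_alleles = sum(gs$y_ctrl),
      cum_epi_alleles = sum(all_rows$y_epi),
      cum_maf_case_pct = cumulative_maf_pct(sum(gs$y_case),
                                            max(1, round(mean(gs$n_geno_case)))),
      cum_maf_ctrl_pct = cumulative_maf_pct(sum(gs$y_ctrl),
                                            max(1, round(mean(gs$n_geno_ctrl)))),
      cum_maf_epi_pct = cumulative_maf_pct(sum(all_rows$y_epi),
                                           max(1, round(mean(all_rows$n_geno_epi)))),
      burden_stat = pp$observed[["burden"]],
      calpha_stat = pp$observed[["calpha"]],
      p_burden = pp$p[["burden"]],
      p_calpha = pp$p[["calpha"]],
      perms_used = pp$perms_used,
      hit_b_max = pp$hit_b_max,
      i_value = iv
    )
  }))
  genes_tbl <- bind_rows(rows)
  if (nrow(genes_tbl)) {
    genes_tbl <- adjusted_bonferroni(genes_tbl, plan) |>
      arrange(.data$p_calpha, .data$p_burden)
  }
  structure(list(genes = genes_tbl, variants = variants, plan = plan),
            class = "gene_assoc")
}

#' @export
print.gene_assoc <- function(x, ...) {
  cat("<gene_assoc> ", nrow(x$genes), " genes tested; ",
      sum(x$genes$tested %||% FALSE), " powered (I < ",
      format(x$plan$i_threshold), "); ",
      sum(x$genes$significant %||% FALSE), " significant\n", sep = "")
  print(x$genes)
  invisible(x)
}

#' @rdname gene_association
#' @param x A `gene_assoc`.
#' @param ... Unused.
#' @method tidy gene_assoc
#' @export
tidy.gene_assoc <- function(x, ...) x$genes

#' @rdname gene_association
#' @method glance gene_assoc
#' @export
glance.gene_assoc <- function(x, ...) {
  tibble(
    n_genes = nrow(x$genes),
    n_powered = sum(x$genes$tested),
    n_tests = x$plan$tests_per_gene * sum(x$genes$tested),
    alpha_adjusted = if (nrow(x$genes)) x$genes$alpha_adjusted[1] else NA_real_,
    n_significant = sum(x$genes$significant)
  )
}
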