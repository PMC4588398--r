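# small three-group matrix with hand-placed alleles for gene-set tests
gene_set_fixture <- function() {
  keys <- sprintf("1:%d:A:G", 1:5)
  n <- 6 + 4 + 10   # cases, epilepsy controls, disease controls
  g <- matrix(0L, n, 5, dimnames = list(sprintf("s%02d", 1:n), keys))
  g[1, 1] <- 1L               # v1: case-exclusive, CADD high
  g[2, 2] <- 1L               # v2: CADD 14.9 -> filtered out
  g[7, 3] <- 1L; g[1, 3] <- 2L  # v3: present in epilepsy controls -> excluded
  g[11, 4] <- 1L; g[12, 4] <- 1L  # v4: control-exclusive
  g[3, 5] <- 1L; g[13, 5] <- 1L   # v5: shared case+control -> neither exclusive
  g[14, 1] <- NA_integer_     # one control missing at v1
  gm <- geno_matrix(g, rep(c("case", "epilepsy_control", "disease_control"),
                           c(6, 4, 10)))
  ann <- make_ann(keys, gene = "GENE_X",
                  cadd_scaled = c(22, 14.9, 30, 17, 19))
  list(gm = gm, ann = ann)
}

test_that("gene sets apply CADD, epilepsy-exclusion and missing-aware counts", {
  fx <- gene_set_fixture()
  sets <- build_gene_sets(fx$gm, fx$ann)
  expect_false("1:2:A:G" %in% sets$key)          # cadd 14.9 < 15
  v3 <- sets[sets$key == "1:3:A:G", ]
  expect_true(v3$excluded_epi)                   # allele in epilepsy controls
  expect_false(v3$retained)                      # excluded entirely
  ret <- sets[sets$retained, ]
  expect_setequal(ret$key, c("1:1:A:G", "1:4:A:G", "1:5:A:G"))
  v1 <- ret[ret$key == "1:1:A:G", ]
  expect_true(v1$case_exclusive)
  expect_equal(v1$n_geno_ctrl, 9L)               # missing excluded from denom
  v5 <- ret[ret$key == "1:5:A:G", ]
  expect_false(v5$case_exclusive)                # shared: neither exclusive
  expect_false(v5$ctrl_exclusive)
})

test_that("cumulative MAF percentages follow the diploid-denominator formula", {
  expect_equal(cumulative_maf_pct(2, 18), 5.56)
  expect_equal(cumulative_maf_pct(0, 1479), 0)
  expect_equal(cumulative_maf_pct(4, 1250), 0.16)
})

test_that("burden statistic sums case alleles over case-exclusive variants", {
  gs <- tibble::tibble(y_case = c(2L, 0L, 1L), y_ctrl = c(0L, 3L, 1L))
  expect_equal(burden_statistic(gs), 2L)   # only the first is case-exclusive
  expect_equal(burden_statistic(tibble::tibble(y_case = integer(),
                                               y_ctrl = integer())), 0L)
  # invariant to control-exclusive content
  gs2 <- gs; gs2$y_ctrl[2] <- 30L
  expect_equal(burden_statistic(gs2), burden_statistic(gs))
})

test_that("C-alpha statistic matches plug-in arithmetic and a hand oracle", {
  one <- tibble::tibble(y_case = 1L, y_ctrl = 0L,
                        n_geno_case = 18L, n_geno_ctrl = 1482L)
  # p0 = 0.012; T = (1 - 0.012)^2 - 0.012 * 0.988
  expect_equal(calpha_statistic(one, p0 = 0.012), 0.964288, tolerance = 1e-9)

  # perfectly balanced sharing gives strictly negative T
  bal <- tibble::tibble(y_case = 2L, y_ctrl = 2L,
                        n_geno_case = 10L, n_geno_ctrl = 10L)
  expect_equal(calpha_statistic(bal), -4 * 0.5 * 0.5)

  # 4-variant toy gene against a spreadsheet-style recomputation
  toy <- tibble::tibble(y_case = c(1L, 0L, 2L, 1L), y_ctrl = c(0L, 2L, 1L, 1L),
                        n_geno_case = c(18L, 18L, 17L, 18L),
                        n_geno_ctrl = c(100L, 99L, 100L, 98L))
  p0 <- toy$n_geno_case / (toy$n_geno_case + toy$n_geno_ctrl)
  n <- toy$y_case + toy$y_ctrl
  by_hand <- sum((toy$y_case - n * p0)^2) - sum(n * p0 * (1 - p0))
  expect_equal(calpha_statistic(toy), by_hand, tolerance = 1e-12)

  # no observed copies -> statistic undefined
  expect_true(is.na(calpha_statistic(tibble::tibble(
    y_case = 0L, y_ctrl = 0L, n_geno_case = 5L, n_geno_ctrl = 5L))))
})

test_that("adaptive permutation is deterministic, bounded and sane", {
  fx <- gene_set_fixture()
  keys <- c("1:1:A:G", "1:4:A:G", "1:5:A:G")
  plan <- permutation_plan(b_max = 2000, batch = 500, seed = 77)
  r1 <- adaptive_permutation(fx$gm, keys, plan, statistic = "burden")
  r2 <- adaptive_permutation(fx$gm, keys, plan, statistic = "burden")
  expect_identical(r1, r2)
  expect_gte(r1$p, 1 / (plan$b_max + 1))
  expect_lte(r1$p, 1)

  # a constant statistic can never be exceeded less than always: p = 1
  const <- adaptive_permutation(fx$gm, keys, plan,
                                statistic_fn = function(pd, rows) 1)
  expect_equal(const$p, 1)
})

test_that("I-value follows the carrier product formula and its edge cases", {
  expect_equal(i_value(0, 18, 1497), 1)
  expect_equal(i_value(1, 18, 1497), 18 / 1497)
  expect_equal(i_value(2, 18, 1497), (18 * 17) / (1497 * 1496))
  # product branch (c > 6) equals the running product written out
  expect_equal(i_value(8, 18, 100),
               prod((18 - 0:7) / (100 - 0:7)), tolerance = 1e-12)
  # enumeration oracle on a small design: fraction of label assignments in
  # which every carrier is a case
  N <- 12; n_case <- 5; c <- 3
  splits <- utils::combn(N, n_case)
  all_in <- mean(apply(splits, 2, function(s) all(seq_len(c) %in% s)))
  expect_equal(i_value(c, n_case, N), all_in, tolerance = 1e-12)
  # more carriers than cases: probability every case is a carrier
  all_cases_carriers <- mean(apply(splits, 2, function(s) all(s <= 7)))
  expect_equal(i_value(7, n_case, N), all_cases_carriers, tolerance = 1e-12)
})

test_that("adjusted Bonferroni corrects only over powered genes", {
  mk <- function(i_values) tibble::tibble(
    i_value = i_values,
    p_burden = rep(1e-4, length(i_values)),
    p_calpha = rep(1, length(i_values))
  )
  plan <- permutation_plan(seed = 1)
  r16 <- adjusted_bonferroni(mk(rep(1e-4, 16)), plan)
  expect_equal(unique(r16$alpha_adjusted), 0.05 / 32)
  expect_equal(signif(unique(r16$alpha_adjusted), 3), 1.56e-3)
  expect_true(all(r16$significant_burden))
  expect_false(any(r16$significant_calpha))

  r1 <- adjusted_bonferroni(mk(c(1e-4, 0.5)), plan)
  expect_equal(unique(r1$alpha_adjusted), 0.025)
  expect_false(r1$tested[2])
  expect_false(r1$significant[2])   # underpowered genes never flagged

  r0 <- adjusted_bonferroni(mk(c(0.5, 0.9)), plan)
  expect_false(any(r0$significant))
  expect_true(all(is.na(r0$alpha_adjusted)))
})

test_that("a planted case-exclusive gene reaches a small empirical p", {
  sim <- simulate_cohort(sim_config(n_genes = 30, seed = 1234,
                                    kits = full_coverage_kits()))
  sim <- plant_exclusive_gene(sim, "GENE0001", 2, 4)
  plan <- permutation_plan(b_max = 50000, batch = 5000, seed = 9,
                           exceedance_stop = 20)
  res <- gene_association(sim$geno, sim$annotations, plan)
  g1 <- res$genes[res$genes$gene == "GENE0001", ]
  expect_equal(g1$cum_case_alleles, 2L)
  expect_equal(g1$cum_maf_case_pct, 5.56)
  expect_true(g1$tested)            # I-value ~1.4e-4 < 1e-3
  # two case-exclusive carriers among 18/1497: p of order 1e-4
  expect_lt(g1$p_burden, 5e-3)
  gl <- glance(res)
  expect_equal(gl$n_genes, nrow(res$genes))
  expect_s3_class(tidy(res), "tbl_df")
})

test_that("per-gene burden p is super-uniform under the null", {
  # label-independent genotypes: Pr(p <= alpha) <= alpha within simulation CI
  set.seed(55)
  plan <- permutation_plan(b_max = 400, batch = 200, seed = 3,
                           exceedance_stop = 40)
  ps <- vapply(1:120, function(i) {
    n <- 40
    g <- matrix(rbinom(n * 3, 1, 0.05), n, 3,
                dimnames = list(sprintf("s%02d", 1:n), sprintf("1:%d:A:G", 1:3)))
    gm <- geno_matrix(g, rep(c("case", "disease_control"), c(8, 32)))
    plan$seed <- 1000 + i
    adaptive_permutation(gm, variant_keys(gm), plan, statistic = "burden")$p
  }, numeric(1))
  for (alpha in c(0.1, 0.25)) {
    ci <- 1.96 * sqrt(alpha * (1 - alpha) / 120)
    expect_lte(mean(ps <= alpha), alpha + ci)
  }
})
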