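test_that("burden profiles sum carried scores with missing contributing nothing", {
  keys <- sprintf("1:%d:A:G", 1:4)
  #           v1  v2  v3  v4       scores: 12.3, 20.0, 5.0, 8.0
  g <- rbind(c(1L, 1L, 0L, 0L),    # carries v1+v2 -> 32.3, count 2
             c(2L, 0L, 0L, 0L),    # hom carrier of v1 -> 12.3 once, count 1
             c(NA, NA, NA, NA),    # all missing -> 0, 0
             c(0L, 0L, 0L, 0L),    # carries nothing -> 0, 0
             c(NA, 1L, 1L, 2L))    # v2+v3+v4 -> 33.0, count 3
  colnames(g) <- keys
  gm <- make_gm(g, rep("case", 5))
  ann <- make_ann(keys, cadd_scaled = c(12.3, 20.0, 5.0, 8.0))
  prof <- compute_burden_profiles(gm, keys, ann)
  expect_equal(prof$burden_score, c(32.3, 12.3, 0, 0, 33.0))
  expect_equal(prof$variant_count, c(2L, 1L, 0L, 0L, 3L))

  # dosage mode counts the homozygote twice
  prof_d <- compute_burden_profiles(gm, keys, ann, dosage = TRUE)
  expect_equal(prof_d$burden_score[2], 24.6)
  expect_equal(prof_d$variant_count[2], 1L)

  # burden is additive over disjoint selected sets
  p12 <- compute_burden_profiles(gm, keys[1:2], ann)
  p34 <- compute_burden_profiles(gm, keys[3:4], ann)
  expect_equal(p12$burden_score + p34$burden_score, prof$burden_score)
  expect_equal(p12$variant_count + p34$variant_count, prof$variant_count)
})

test_that("rank-sum test matches exact enumeration and is symmetric", {
  w <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(w$p, 0.1)
  expect_equal(w$method, "exact")

  same <- wilcoxon_rank_sum(c(2, 5, 5, 9), c(2, 5, 5, 9))
  expect_equal(same$z, 0)
  expect_equal(same$p, 1)

  set.seed(42)
  a <- rnorm(20); b <- rnorm(35, 0.4)
  expect_equal(wilcoxon_rank_sum(a, b)$p, wilcoxon_rank_sum(b, a)$p)

  # identical values in both groups -> degenerate p = 1
  expect_equal(wilcoxon_rank_sum(rep(3, 5), rep(3, 20))$p, 1)
})

test_that("normal branch reproduces the no-continuity-correction reference", {
  set.seed(7)
  for (i in 1:5) {
    a <- rnorm(15); b <- rnorm(25, 0.3)
    ours <- wilcoxon_rank_sum(a, b)
    ref <- stats::wilcox.test(a, b, exact = FALSE, correct = FALSE)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-10)
  }
  # with ties, the tie-corrected variance still matches
  set.seed(8)
  a <- sample(1:4, 30, replace = TRUE); b <- sample(1:4, 40, replace = TRUE)
  expect_equal(wilcoxon_rank_sum(a, b)$p,
               stats::wilcox.test(a, b, exact = FALSE, correct = FALSE)$p.value,
               tolerance = 1e-10)
})

test_that("exact and normal branches agree at n = 6 + 6", {
  # full enumeration of the tie-free null: without continuity correction the
  # branches differ by at most 0.07 anywhere, and by under 0.02 in the
  # decision-relevant tail (exact p <= 0.05)
  set.seed(9)
  for (i in 1:10) {
    a <- rnorm(6); b <- rnorm(6)
    pe <- wilcoxon_rank_sum(a, b)$p
    pn <- wilcoxon_rank_sum(a, b, exact_max = 0)$p
    expect_lt(abs(pe - pn), 0.07)
    if (pe <= 0.05) expect_lt(abs(pe - pn), 0.02)
  }
})

test_that("rank-sum test holds its level under the null", {
  set.seed(123)
  rej <- mean(vapply(1:1000, function(i) {
    wilcoxon_rank_sum(rnorm(25), rnorm(25))$p < 0.05
  }, logical(1)))
  ci_half <- 1.96 * sqrt(0.05 * 0.95 / 1000)
  expect_lt(abs(rej - 0.05), ci_half + 1e-9)
})

test_that("compare_groups runs six Bonferroni-corrected tests", {
  set.seed(5)
  prof <- tibble::tibble(
    sample = sprintf("s%03d", 1:125),
    group = rep(c("case", "epilepsy_control", "disease_control"),
                c(18, 87, 20)),
    burden_score = rnorm(125, 300, 40),
    variant_count = rpois(125, 100)
  )
  cmp <- compare_groups(prof)
  expect_equal(nrow(cmp), 6L)
  expect_equal(unique(cmp$bonferroni_alpha), 0.05 / 6)
  expect_equal(signif(unique(cmp$bonferroni_alpha), 2), 8.3e-3)
  expect_equal(cmp$significant, cmp$p_two_sided < 0.05 / 6)

  expect_error(compare_groups(prof[prof$group != "case", ]), "Empty group")
})

test_that("single-gene exclusion removes exactly that gene's contribution", {
  keys <- sprintf("1:%d:A:G", 1:6)
  ann <- make_ann(keys, gene = rep(c("GENE_A", "GENE_B", "GENE_C"), each = 2),
                  cadd_scaled = 16)
  g <- matrix(0L, 40, 6, dimnames = list(sprintf("s%02d", 1:40), keys))
  g[1:10, 1] <- 1L     # GENE_A carried by cases only
  g[11:40, 3] <- 1L    # GENE_B carried by controls
  gm <- geno_matrix(g, rep(c("case", "epilepsy_control", "disease_control"),
                           c(10, 10, 20)))
  fit_all <- burden_analysis(gm, ann)
  fit_wo_a <- burden_analysis(gm, ann, exclude_gene = "GENE_A")
  expect_true(all(fit_wo_a$profiles$burden_score[1:10] == 0))
  expect_equal(fit_wo_a$profiles$burden_score[11:40],
               fit_all$profiles$burden_score[11:40])

  # excluding a gene carried by nobody leaves profiles identical (it never
  # entered the selected set, so the exclusion warns and is a no-op)
  expect_warning(fit_wo_c <- burden_analysis(gm, ann, exclude_gene = "GENE_C"),
                 "nothing excluded")
  expect_equal(fit_wo_c$profiles, fit_all$profiles)

  # a gene absent from the selected set is a warning-level no-op
  expect_warning(
    fit_wo_x <- burden_analysis(gm, ann, exclude_gene = "GENE_NOPE"),
    "nothing excluded")
  expect_equal(fit_wo_x$profiles, fit_all$profiles)
})

test_that("summary, tidy, glance and autoplot expose the fit", {
  fx <- ten_variant_fixture()
  fit <- burden_analysis(fx$gm, fx$ann)
  s <- fit$summary
  expect_setequal(unique(s$metric), c("burden_score", "variant_count"))
  expect_equal(nrow(s), 6L)
  expect_named(tidy(fit), c("metric", "group_a", "group_b", "n_a", "n_b",
                            "z_statistic", "p_two_sided", "bonferroni_alpha",
                            "significant"))
  gl <- glance(fit)
  expect_equal(gl$n_tests, 6L)
  expect_equal(gl$n_selected, 6L)
  expect_s3_class(autoplot(fit), "ggplot")
})
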