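test_that("individual QC computes call rate, singletons and het rate", {
  g <- matrix(0L, 4, 5)
  g[2, ] <- NA_integer_                 # sample 2: nothing called
  g[3, 1:3] <- 1L                       # sample 3 uniquely carries 3 variants
  g[4, 4] <- 2L                         # hom alt: allele count 2, not singleton
  gm <- make_gm(g, rep("disease_control", 4))
  qc <- individual_qc(gm)
  expect_equal(qc$call_rate[2], 0)
  expect_true(qc$outlier_flag[2])
  expect_equal(qc$singleton_count, c(0L, 0L, 3L, 0L))
  expect_equal(qc$het_rate[3], 3 / 5)
})

test_that("outlier flagging is rare under a homogeneous simulated cohort", {
  sim <- simulate_cohort(sim_config(n_case = 50, n_epi_ctrl = 50,
                                    n_dis_ctrl = 200, n_genes = 400,
                                    variants_per_gene = 6, seed = 31))
  qc <- individual_qc(sim$geno, k_mad = 4)
  expect_lt(mean(qc$outlier_flag), 0.01)
})

test_that("protein-changing and rarity filters follow their boundary rules", {
  ann <- make_ann(sprintf("1:%d:A:G", 1:4),
                  func_class = c("synonymous", "missense", "missense", "noncoding"),
                  ref_maf = c(0.001, 0.005, 0.006, 0.001))
  expect_equal(is_protein_changing(ann), c(FALSE, TRUE, TRUE, FALSE))
  # MAF boundary is inclusive: 0.5% passes, 0.6% does not
  expect_equal(passes_rare_filter(ann), c(TRUE, TRUE, FALSE, TRUE))
})

test_that("group sequenced fraction counts non-missing over group size", {
  g <- matrix(0L, 18, 1)
  g[1:3, 1] <- NA_integer_              # 15 of 18 cases called
  gm <- make_gm(g, rep("case", 18))
  gm2 <- geno_matrix(rbind(gm$geno, matrix(0L, 2, 1,
                       dimnames = list(c("e1", "e2"), colnames(gm$geno)))),
                     c(rep("case", 18), rep("epilepsy_control", 2)))
  k <- variant_keys(gm2)
  expect_equal(group_sequenced_fraction(gm2, k, "case"), 15 / 18)
  expect_equal(group_sequenced_fraction(gm2, k, "epilepsy_control"), 1)
  expect_error(group_sequenced_fraction(gm2, k, "controls"), "Unknown group")
  gm3 <- subset_geno(gm2, samples = 1:18)
  gm3$geno[, 1] <- NA_integer_
  expect_equal(group_sequenced_fraction(geno_matrix(gm3$geno, rep("case", 18)),
                                        k, "case"), 0)
})

test_that("genome-wide selection keeps exactly the rule-respecting variants", {
  fx <- ten_variant_fixture()
  sel <- select_genomewide_variants(fx$gm, fx$ann)
  expect_setequal(sel, fx$surviving)

  # a variant sequenced in 14/18 cases but everywhere else fails the case rule
  g <- matrix(1L, 18 + 87 + 30, 1)
  g[1:4, 1] <- NA_integer_
  gm <- make_gm(g, rep(c("case", "epilepsy_control", "disease_control"),
                       c(18, 87, 30)))
  ann <- make_ann(variant_keys(gm))
  expect_length(select_genomewide_variants(gm, ann), 0)
  # called in 15/18 cases (0.833 > 0.80) it passes
  g2 <- g; g2[1:4, 1] <- 0L; g2[1:3, 1] <- NA_integer_
  gm2 <- make_gm(g2, as.character(gm$group))
  expect_length(select_genomewide_variants(gm2, ann), 1)
})

test_that("unannotated variants are excluded from selection with a warning", {
  fx <- ten_variant_fixture()
  ann <- fx$ann[-5, ]   # drop the annotation of a surviving variant
  expect_warning(sel <- select_genomewide_variants(fx$gm, ann),
                 "without annotation")
  expect_setequal(sel, setdiff(fx$surviving, fx$ann$key[5]))
})

test_that("selection is monotone in both thresholds and order-invariant", {
  withr::local_seed(8)
  for (rep in 1:3) {
    sim <- simulate_cohort(sim_config(n_case = 12, n_epi_ctrl = 15,
                                      n_dis_ctrl = 25, n_genes = 30,
                                      seed = 200 + rep))
    gm <- sim$geno; ann <- sim$annotations
    sel_base <- select_genomewide_variants(gm, ann, selection_config(0.005, 0.6))
    sel_tight_frac <- select_genomewide_variants(gm, ann, selection_config(0.005, 0.85))
    sel_tight_maf <- select_genomewide_variants(gm, ann, selection_config(0.001, 0.6))
    expect_true(all(sel_tight_frac %in% sel_base))
    expect_true(all(sel_tight_maf %in% sel_base))

    perm_s <- sample(n_samples(gm))
    perm_v <- sample(n_variants(gm))
    gm_perm <- subset_geno(gm, samples = perm_s, variants = perm_v)
    expect_setequal(
      select_genomewide_variants(gm_perm, ann, selection_config(0.005, 0.6)),
      sel_base)
  }
})

test_that("threshold sweep finds 0.8 under a constructed batch effect", {
  fx <- sweep_fixture()
  sw <- sweep_group_fraction_threshold(fx$gm, fx$ann)
  expect_equal(sw$threshold, seq(0.5, 0.9, by = 0.1))
  # permissive thresholds admit the badly covered high-score batch variants
  expect_gt(sw$variability[sw$threshold == 0.5],
            sw$variability[sw$threshold == 0.8])
  # 0.9 leaves no variants: variability undefined
  expect_equal(sw$n_variants[sw$threshold == 0.9], 0L)
  expect_true(is.na(sw$variability[sw$threshold == 0.9]))
  expect_equal(sw$threshold[sw$is_argmin], 0.8)
})

test_that("threshold sweep is flat with complete coverage", {
  sim <- simulate_cohort(sim_config(n_case = 10, n_epi_ctrl = 10,
                                    n_dis_ctrl = 20, n_genes = 20,
                                    kits = full_coverage_kits(), seed = 4))
  sw <- sweep_group_fraction_threshold(sim$geno, sim$annotations)
  expect_equal(length(unique(round(sw$variability, 12))), 1L)
})
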