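#' Simulation configuration for a three-cohort exome study
#'
#' Describes a synthetic jointly called case/control exome dataset: cohort
#' sizes (defaults are the post-QC sizes of the emulated study design:
#' 18 cases, 87 epilepsy controls, 1479 disease controls), a rare-variant
#' site-frequency spectrum, a scaled-deleteriousness score distribution,
#' capture-kit missingness masks, and optional planted case effects.
#'
#' The null configuration (`effect_count = 1`, `effect_score = 0`, no
#' `exclusive_genes`, and the default group-independent kit mixture) makes the
#' three groups exchangeable: genotypes, missingness and covariates are drawn
#' identically regardless of group label.
#'
#' @param n_case,n_epi_ctrl,n_dis_ctrl Cohort sizes.
#' @param n_genes Number of genes.
#' @param variants_per_gene Poisson mean of the per-gene variant count
#'   (minimum one variant per gene).
#' @param maf_shape1,maf_shape2,maf_max Site-frequency spectrum: minor allele
#'   frequencies are Beta(`maf_shape1`, `maf_shape2`) truncated to
#'   `(0, maf_max]`. The default Beta(0.2, 200) on (0, 0.005] gives a heavy
#'   rare tail with every simulated variant passing the MAF <= 0.5% filter.
#' @param cadd_high_weight Probability that a variant's scaled CADD is drawn
#'   from Uniform(15, 40) rather than Uniform(0, 15); exercises the
#'   scaled-CADD >= 15 gene-analysis filter from both sides.
#' @param kits List of capture-kit masks, each `list(coverage=, p_covered=,
#'   p_uncovered=)`: the kit covers a random `coverage` fraction of variants,
#'   where a covered variant is callable with probability `p_covered` and an
#'   uncovered one with `p_uncovered`. See [default_kits()],
#'   [full_coverage_kits()].
#' @param kit_mixture Numeric matrix, 3 rows (case, epilepsy_control,
#'   disease_control) x `length(kits)` columns of kit-assignment proportions
#'   per cohort; rows must sum to 1. `NULL` (default) assigns kits uniformly,
#'   independent of group.
#' @param effect_count Multiplier >= 1 on the per-variant alternate-allele
#'   frequency in cases (raises the expected carried-variant count).
#' @param effect_score Additive shift >= 0 applied to the scaled
#'   deleteriousness of every variant carried by at least one case (emulates
#'   over-representation of damaging alleles among case-carried variants).
#' @param exclusive_genes List of `list(gene=, n_case_carriers=,
#'   n_ctrl_carriers=)` specifications passed to [plant_exclusive_gene()].
#' @param seed Integer seed; all stochastic draws flow from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_case = 18, n_epi_ctrl = 87, n_dis_ctrl = 1479,
                       n_genes = 100, variants_per_gene = 4,
                       maf_shape1 = 0.2, maf_shape2 = 200, maf_max = 0.005,
                       cadd_high_weight = 0.3,
                       kits = default_kits(), kit_mixture = NULL,
                       effect_count = 1, effect_score = 0,
                       exclusive_genes = list(), seed = 1L) {
  stopifnot(n_case >= 1, n_epi_ctrl >= 1, n_dis_ctrl >= 1, n_genes >= 1,
            variants_per_gene > 0, maf_max > 0, maf_max <= 0.5,
            cadd_high_weight >= 0, cadd_high_weight <= 1,
            effect_count >= 1, effect_score >= 0, length(kits) >= 1)
  for (k in kits) {
    stopifnot(k$coverage >= 0, k$coverage <= 1,
              k$p_covered >= 0, k$p_covered <= 1,
              k$p_uncovered >= 0, k$p_uncovered <= 1)
  }
  if (is.null(kit_mixture)) {
    kit_mixture <- matrix(1 / length(kits), nrow = 3, ncol = length(kits),
                          dimnames = list(GROUPS, names(kits)))
  }
  if (!is.matrix(kit_mixture) || nrow(kit_mixture) != 3 ||
      ncol(kit_mixture) != length(kits) ||
      any(abs(rowSums(kit_mixture) - 1) > 1e-8)) {
    abort("kit_mixture must be a 3 x n_kits matrix with rows summing to 1.")
  }
  structure(
    list(n_case = n_case, n_epi_ctrl = n_epi_ctrl, n_dis_ctrl = n_dis_ctrl,
         n_genes = n_genes, variants_per_gene = variants_per_gene,
         maf_shape1 = maf_shape1, maf_shape2 = maf_shape2, maf_max = maf_max,
         cadd_high_weight = cadd_high_weight,
         kits = kits, kit_mixture = kit_mixture,
         effect_count = effect_count, effect_score = effect_score,
         exclusive_genes = exclusive_genes, seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Capture-kit mask presets
#'
#' `default_kits()` emulates three exome capture designs whose target regions
#' overlap but differ (as 38 Mb vs 50 Mb kits do): each covers 100% / 92% /
#' 85% of variants, with covered variants callable at 0.98 and uncovered at
#' 0.10 — so variants outside a widely used kit fail the per-group
#' sequenced-fraction filter. `full_coverage_kits()` is a single kit calling
#' everything (no missingness).
#'
#' @return A named list of kit masks for [sim_config()].
#' @export
default_kits <- function() {
  list(
    kit_wide   = list(coverage = 1.00, p_covered = 0.98, p_uncovered = 0.10),
    kit_medium = list(coverage = 0.92, p_covered = 0.98, p_uncovered = 0.10),
    kit_narrow = list(coverage = 0.85, p_covered = 0.98, p_uncovered = 0.10)
  )
}

#' @rdname default_kits
#' @export
full_coverage_kits <- function() {
  list(kit_full = list(coverage = 1, p_covered = 1, p_uncovered = 1))
}

rtrunc_beta <- function(n, shape1, shape2, upper) {
  # inverse-CDF sampling from Beta truncated to (0, upper]
  hi <- stats::pbeta(upper, shape1, shape2)
  u <- runif(n, min = 1e-12, max = hi)
  pmax(stats::qbeta(u, shape1, shape2), 1e-6)
}

#' Simulate a three-cohort exome dataset
#'
#' Draws variants (genes, positions, functional classes, reference MAFs,
#' deleteriousness scores), genotypes (binomial in the population MAF, with a
#' configurable case enrichment), capture-kit missingness, clinical
#' covariates, and any configured planted effects. Deterministic given the
#' config seed.
#'
#' @param config A [sim_config()].
#' @return A list of class `cohort_sim` with elements `geno` (a
#'   [geno_matrix()]), `annotations` (tibble), `manifest` (tibble) and
#'   `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, simulate_cohort_impl(config))
}

simulate_cohort_impl <- function(cfg) {
  n <- cfg$n_case + cfg$n_epi_ctrl + cfg$n_dis_ctrl
  group <- rep(GROUPS, times = c(cfg$n_case, cfg$n_epi_ctrl, cfg$n_dis_ctrl))
  sample_id <- sprintf("S%04d", seq_len(n))

  # ---- variants --------------------------------------------------------------
  nv_gene <- pmax(1L, rpois(cfg$n_genes, cfg$variants_per_gene))
  V <- sum(nv_gene)
  gene <- rep(sprintf("GENE%04d", seq_len(cfg$n_genes)), times = nv_gene)
  gidx <- rep(seq_len(cfg$n_genes), times = nv_gene)
  chrom <- as.character(((gidx - 1L) %% 22L) + 1L)
  # genes occupy disjoint 10 kb windows along their chromosome
  pos <- 1e5L + ((gidx - 1L) %/% 22L) * 10000L +
    as.integer(unlist(lapply(nv_gene, seq_len))) * 10L
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, V, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1))
  maf <- rtrunc_beta(V, cfg$maf_shape1, cfg$maf_shape2, cfg$maf_max)
  func_class <- sample(FUNC_CLASSES, V, replace = TRUE,
                       prob = c(0.55, 0.07, 0.06, 0.04, 0.05, 0.15, 0.08))
  high <- runif(V) < cfg$cadd_high_weight
  cadd_scaled <- ifelse(high, runif(V, 15, 40), runif(V, 0, 15))
  cadd_raw <- (cadd_scaled - 10) / 5 + rnorm(V, 0, 0.1)
  key <- variant_key(chrom, pos, ref, alt)

  # ---- genotypes -------------------------------------------------------------
  geno <- matrix(0L, n, V, dimnames = list(sample_id, key))
  is_case <- group == "case"
  n_case <- sum(is_case)
  p_case <- pmin(maf * cfg$effect_count, 0.5)
  geno[is_case, ] <- rbinom(n_case * V, 2L, rep(p_case, each = n_case))
  geno[!is_case, ] <- rbinom((n - n_case) * V, 2L, rep(maf, each = n - n_case))

  # ---- capture-kit missingness ----------------------------------------------
  n_kits <- length(cfg$kits)
  covered <- vapply(cfg$kits, function(k) runif(V) < k$coverage,
                    logical(V))
  covered <- matrix(covered, nrow = V)  # V x n_kits
  callable <- vapply(seq_len(n_kits), function(j) {
    k <- cfg$kits[[j]]
    ifelse(covered[, j], k$p_covered, k$p_uncovered)
  }, numeric(V))
  callable <- matrix(callable, nrow = V)
  kit_of <- integer(n)
  for (g in GROUPS) {
    idx <- which(group == g)
    kit_of[idx] <- sample.int(n_kits, length(idx), replace = TRUE,
                              prob = cfg$kit_mixture[g, ])
  }
  for (j in seq_len(n_kits)) {
    rows <- which(kit_of == j)
    if (!length(rows)) next
    q <- callable[, j]
    if (all(q >= 1)) next
    miss <- runif(length(rows) * V) >= rep(q, each = length(rows))
    geno[rows, ][miss] <- NA_integer_
  }

  # ---- planted annotation-level score effect ---------------------------------
  if (cfg$effect_score > 0) {
    case_carried <- colSums(geno[is_case, , drop = FALSE] >= 1L,
                            na.rm = TRUE) > 0
    cadd_scaled[case_carried] <- cadd_scaled[case_carried] + cfg$effect_score
  }

  annotations <- tibble(
    key = key, gene = gene, func_class = func_class, ref_maf = maf,
    cadd_raw = round(cadd_raw, 4), cadd_scaled = round(cadd_scaled, 3)
  )

  # ---- clinical covariates (group-independent: null-exchangeable) ------------
  age_first <- round(rgamma(n, shape = 1.2, scale = 5), 1)
  duration <- round(rgamma(n, shape = 3, scale = 9), 1)
  tri <- function(p_yes) {
    x <- sample(c("yes", "no"), n, replace = TRUE, prob = c(p_yes, 1 - p_yes))
    x[runif(n) < 0.05] <- NA_character_
    x
  }
  manifest <- tibble(
    sample = sample_id, group = group,
    sex = sample(c("male", "female"), n, replace = TRUE, prob = c(0.45, 0.55)),
    age_last_followup = round(age_first + duration, 1),
    age_first_seizure = age_first,
    epilepsy_duration = duration,
    syndrome = sample(c("DS", "FocalS", "FocalU", "GGE", "UE"), n,
                      replace = TRUE, prob = c(0.34, 0.28, 0.10, 0.15, 0.13)),
    intellectual_disability = tri(0.47),
    lives_alone = tri(0.08),
    convulsive_seizures_12m = tri(0.45),
    nocturnal_seizures_12m = tri(0.40),
    n_aeds = rpois(n, 8)
  )

  sim <- structure(
    list(geno = geno_matrix(geno, group), annotations = annotations,
         manifest = manifest, config = cfg),
    class = "cohort_sim"
  )
  for (xg in cfg$exclusive_genes) {
    sim <- plant_exclusive_gene(sim, xg$gene, xg$n_case_carriers,
                                xg$n_ctrl_carriers)
  }
  sim
}

#' @export
print.cohort_sim <- function(x, ...) {
  cat("<cohort_sim> ", n_samples(x$geno), " samples, ",
      n_variants(x$geno), " variants, ",
      length(unique(x$annotations$gene)), " genes (seed ",
      x$config$seed, ")\n", sep = "")
  invisible(x)
}

#' Plant group-exclusive alleles in a gene
#'
#' Adds fully genotyped heterozygous carriers of new variants in `gene`:
#' one variant whose alternate alleles occur only in cases
#' (`n_case_carriers` of them) and one occurring only in disease controls
#' (`n_ctrl_carriers`). Planted variants are rare, missense, and have scaled
#' CADD >= 15, so they pass every gene-analysis filter; their genotypes are
#' called in every sample, so they pass the sequenced-fraction filter.
#'
#' @param sim A `cohort_sim` (from [simulate_cohort()]).
#' @param gene Gene symbol already present in the simulated annotations.
#' @param n_case_carriers,n_ctrl_carriers Numbers of heterozygous carriers to
#'   plant in the case and disease-control cohorts (each must not exceed the
#'   cohort size).
#' @param cadd_scaled Scaled deleteriousness of the planted variants
#'   (default 25; must be >= 15).
#' @return The modified `cohort_sim`.
#' @export
plant_exclusive_gene <- function(sim, gene, n_case_carriers, n_ctrl_carriers,
                                 cadd_scaled = 25) {
  stopifnot(inherits(sim, "cohort_sim"), cadd_scaled >= 15,
            n_case_carriers >= 0, n_ctrl_carriers >= 0)
  ann <- sim$annotations
  grows <- which(ann$gene == gene)
  if (!length(grows)) abort(paste0("Gene not present in annotations: ", gene))
  gm <- sim$geno
  grp <- as.character(gm$group)
  case_ids <- which(grp == "case")
  ctrl_ids <- which(grp == "disease_control")
  if (n_case_carriers > length(case_ids)) {
    abort("n_case_carriers exceeds the case cohort size.")
  }
  if (n_ctrl_carriers > length(ctrl_ids)) {
    abort("n_ctrl_carriers exceeds the disease-control cohort size.")
  }
  vk <- parse_variant_key(ann$key[grows])
  chrom <- vk$chrom[1]
  next_pos <- max(vk$pos) + 1L

  add_variant <- function(carriers, pos) {
    col <- rep(0L, n_samples(gm))
    col[carriers] <- 1L
    k <- variant_key(chrom, pos, "A", "G")
    g2 <- cbind(gm$geno, col)
    colnames(g2)[ncol(g2)] <- k
    gm <<- geno_matrix(g2, grp)
    ann <<- bind_rows(ann, tibble(
      key = k, gene = gene, func_class = "missense", ref_maf = 1e-4,
      cadd_raw = (cadd_scaled - 10) / 5, cadd_scaled = cadd_scaled
    ))
  }
  if (n_case_carriers > 0) {
    add_variant(sample(case_ids, n_case_carriers), next_pos)
    next_pos <- next_pos + 1L
  }
  if (n_ctrl_carriers > 0) {
    add_variant(sample(ctrl_ids, n_ctrl_carriers), next_pos)
  }
  sim$geno <- gm
  sim$annotations <- ann
  sim
}

#' Write a simulated cohort to disk
#'
#' Emits exactly the formats the readers consume: `cohort.vcf` (plain-text
#' VCFv4.2), `annotations.tsv`, `manifest.tsv`.
#'
#' @param sim A `cohort_sim`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the three file paths, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  stopifnot(inherits(sim, "cohort_sim"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    vcf = file.path(dir, "cohort.vcf"),
    annotations = file.path(dir, "annotations.tsv"),
    manifest = file.path(dir, "manifest.tsv")
  )
  write_vcf(sim$geno, paths[["vcf"]])
  write_annotations(sim$annotations, paths[["annotations"]])
  write_manifest(sim$manifest, paths[["manifest"]])
  invisible(paths)
}
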