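---
title: "Rare-variant polygenic burden and unique-variant gene association"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rare-variant polygenic burden and unique-variant gene association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exomeburden)
```

## The analysis in brief

`exomeburden` implements a two-stage case–control analysis of rare,
protein-changing variants from jointly called whole-exome sequencing, designed
for a small case cohort (here, people who died of sudden unexpected death in
epilepsy, SUDEP) compared against two control cohorts: living epilepsy
controls and non-epilepsy disease controls.

**Stage 1 — genome-wide polygenic burden.** Each individual receives a burden
score
$$B_s = \sum_{v \in \mathcal{S}} w_v \, \mathbf{1}\{g_{sv} \ge 1\},$$
where $\mathcal{S}$ is the selected variant set, $w_v$ the variant's scaled
CADD deleteriousness score, and $g_{sv} \in \{0, 1, 2\}$ the allele count
(missing genotypes contribute nothing). The three cohorts are compared
pairwise on $B_s$ and on the carried-variant count by the two-tailed Wilcoxon
rank-sum test, Bonferroni-corrected over the six tests
($\alpha = 0.05/6 \approx 8.3 \times 10^{-3}$).

**Stage 2 — gene-based unique-variant association.** Within each gene,
variants are refined to scaled CADD ≥ 15 and purged of anything seen in
epilepsy controls; the tests then compare alleles exclusive to cases against
those exclusive to disease controls, using a one-tailed burden statistic and
the two-tailed C-alpha overdispersion statistic, with empirical p-values from
adaptive phenotype-label permutation. Multiple testing corrects only over
genes *powered* to reach significance, measured by the smallest achievable
empirical p-value (the I-value).

Because the individual-level data such a study rests on cannot be
redistributed, the package ships a synthetic-cohort generator that emulates
the study's structure end to end, so every stage is exercisable and testable
without external data.

## Data model

* A `geno_matrix` holds samples × variants allele counts with `NA` as an
  explicit missing code. The distinction between missing and homozygous
  reference is load-bearing: it is what joint calling provides and what the
  batch-correction filter consumes. Half-calls (`0/.`) are conservatively
  treated as missing.
* Variant annotations (gene, functional class, reference-population MAF, raw
  and scaled CADD) are a tibble keyed by the canonical `chrom:pos:ref:alt`
  string; multi-allelic VCF records are decomposed to one key per alternate
  allele, and shared allele padding is trimmed before keying so the
  annotation join is unambiguous. Full left-alignment against a reference
  genome is out of scope.
* The sample manifest carries the group label and the clinical covariates of
  the cohort-description stage, with `.` for unknown; unknowns are excluded
  per row from test denominators (complete-case analysis).

## Variant selection and the sequenced-fraction threshold

Stage-1 selection keeps variants that are

1. protein-changing (missense, nonsense, frameshift, in-frame indel,
   canonical splice);
2. rare: reference-population MAF ≤ 0.5%, **boundary inclusive**;
3. observed (≥ 1 alternate allele overall); and
4. sequenced in **strictly more than** 80% of each of the three groups
   separately.

The asymmetric boundary conventions (≤ for MAF, > for sequenced fraction)
follow the literal statements of the thresholds; the per-group (rather than
pooled) reading of rule 4 is a design choice — it is the reading under which
the filter actually removes capture-kit batch structure, since a variant
absent from one cohort's kit fails in that cohort alone. Rarity is judged on
the *reference-population* frequency in the annotations, not the in-cohort
frequency, because pathogenicity is tied to rarity in the general population.

The 80% figure is not arbitrary: `sweep_group_fraction_threshold()` re-runs
selection and scoring over a grid of thresholds and reports the variability
of all per-individual burden scores at each. "Variability" is realised as the
coefficient of variation (scale-free, so comparable across thresholds that
change the score's magnitude); a variance mode is available. A threshold that
leaves no variants has undefined variability and is reported `NA`. Under a
deliberately constructed batch effect (a high-score variant block missing in
a quarter of one cohort), permissive thresholds admit the block and inflate
the CV, while 0.8 excludes it — the test suite pins this behaviour.

Individual-level QC (`individual_qc()`) computes call rate, singleton count
and heterozygosity per sample and flags outliers beyond 4
median-absolute-deviations from the cohort median. The MAD uses the usual
1.4826 normal-consistency scale; for discrete metrics where more than half
the cohort sits on the median (MAD = 0) it falls back to the standard
deviation rather than flagging every non-median value. The 4-MAD rule itself
is a package choice of a conventional, conservative cut.

## Burden scores and group comparison

A carried variant contributes its scaled CADD score **once per carrier**
regardless of zygosity; the statements defining the score speak of variants
carried, not allele dosage, so presence-based is the default and dosage
weighting sits behind `dosage = TRUE`. The scaled (not raw) CADD score is
used: the gene-stage filter is defined on the scaled score, and scaled scores
are comparable across variants. Scores are reported at full precision and
rounded only in display tables.

`wilcoxon_rank_sum()` follows the Stata `ranksum` convention: mid-ranks for
ties, tie-corrected variance, normal approximation **without** continuity
correction. When the pooled sample size is at most 12 the two-sided p-value
comes instead from exact enumeration of all rank splits, with the tail
defined by distance of the rank sum from its null expectation (which remains
well-defined under ties). Degenerate comparisons (identical values
throughout) return p = 1. Full enumeration of the tie-free null at
$n_a = n_b = 6$ shows the two branches differ by at most 0.07 anywhere and by
less than 0.02 wherever the exact p is ≤ 0.05; the suite asserts those
verified bounds.

The post hoc robustness check of the burden result — removing every variant
of one gene (e.g. the syndrome gene *SCN1A* in the motivating study) and
re-running the comparison — is `burden_analysis(..., exclude_gene = ...)`.
Because the burden score is additive over disjoint variant sets, excluding
one gene subtracts exactly that gene's contribution, a property the tests
exploit to check *every* gene's exclusion cheaply after verifying the
equivalence against the package's own recomputation on sampled genes.

## Gene-based unique-variant association

Stage 2 refines to scaled CADD ≥ 15 (top ~3% most deleterious substitutions),
drops any variant with an alternate allele in the epilepsy-control cohort
(enriching for association with the case phenotype over epilepsy itself), and
computes, per variant, allele counts over **genotyped** individuals only.
Epilepsy controls then play no further part; the tests compare the 18 cases
with the 1479 disease controls.

* The **burden statistic** is the summed case allele count over
  case-exclusive variants (alternate alleles absent from disease controls);
  one-tailed, larger = more case-specific burden.
* The **C-alpha statistic** is
  $T = \sum_i \left[(y_i - n_i p_{0i})^2 - n_i p_{0i}(1 - p_{0i})\right]$
  over variants with $n_i \ge 1$ total copies, where $y_i$ is the case copy
  count and $p_{0i}$ the genotyped-case share. It detects overdispersion of
  allele sharing in either direction — that two-sidedness is intrinsic to
  $T$ — and significance is assessed on the upper tail of its permutation
  distribution (an $|T|$ mode would double-count the underdispersed side,
  which is not the alternative of interest; the upper-tail convention is
  standard C-alpha practice).

Empirical p-values come from uniform swapping of the case/disease-control
labels. Two points matter:

1. **The exclusivity partition is recomputed inside every permutation.**
   Which variants are "case-exclusive" depends on the labels; freezing the
   observed partition would make permuted statistics systematically smaller
   than the observed one and the p-values anti-conservative.
2. **Adaptive early stopping**: permutation for a gene stops once the
   observed statistic has been met or exceeded 100 times (the p-value is then
   estimated with roughly 10% relative Monte-Carlo error, ample to declare a
   gene unassociated), or at `b_max` (default $10^6$) permutations, whichever
   comes first. The exceedance count of 100 is a package choice for the
   qualitative rule of dropping clearly unassociated genes. p-values use the
   permutation estimator $(k+1)/(B+1)$, so $p \ge 1/(B+1)$ always.

The **I-value** is the probability, under label permutation, of the
configuration attaining the maximal statistic — all $c$ carrier individuals
labelled case: $\prod_{j=0}^{c-1}(n_{case}-j)/(N-j)$ (hypergeometric count
for $c \le 6$, running product above, identical analytically; if $c$ exceeds
the case count it becomes the probability that every case is a carrier). The
multiple-testing family contains only genes with I < 10⁻³, corrected as
$\alpha = 0.05/(2G)$ over $G$ powered genes and two tests each — with 16
powered genes, $\alpha = 1.56 \times 10^{-3}$.

Gene-level cumulative minor allele frequencies are reported as
$100 \cdot \text{count}/(2 n_{\text{genotyped}})$ with the gene's denominator
taken as the mean per-variant genotyped count (rounded); per-gene genotyped
counts, not full cohort sizes, are the denominators that make the reported
percentages coherent. The epilepsy-control column is reported over the gene's
refined variants *before* the epilepsy-exclusion step — after it, the column
would be identically zero.

## Clinical cohort description

`risk_factor_panel()` compares cases with epilepsy controls: Fisher's exact
test for binary factors, Pearson χ² (no continuity correction) for
multi-category ones, Wilcoxon rank-sum for skewed continuous covariates, and
a pooled-variance t-test (Welch optional) for age at follow-up. Fisher's
two-sided p uses the probability-mass rule (sum of all equally-or-less
probable tables with the same margins), with the doubled-one-tail convention
available behind a flag. The Bonferroni family covers the eight established
risk factors ($\alpha = 0.05/8 = 6.25 \times 10^{-3}$). Reported thresholds
round half-up at two significant digits (`signif_half_up()`), matching the
manuscript convention in which 0.00625 prints as 6.3 × 10⁻³.

`expected_event_count()` converts a published incidence (events per 1000
person-years) and the cohort's summed years at risk into an expected event
count — e.g. 5.9/1000 × 2563 years ⇒ 15.1, i.e. about 15 expected deaths
among 87 controls, the calculation behind describing a surviving control
cohort as enriched for lower risk.

## The synthetic cohort generator

`simulate_cohort()` draws, deterministically from one integer seed:

* **Cohort sizes** 18 / 87 / 1479 by default — the post-QC sizes of the
  emulated design.
* **Site-frequency spectrum**: MAFs from Beta(0.2, 200) truncated to
  (0, 0.005], a heavy rare tail under which every simulated variant passes
  the rarity filter unless configured otherwise; in-cohort allele counts are
  binomial in the MAF under Hardy–Weinberg.
* **Deleteriousness**: scaled CADD from a mixture of Uniform(0, 15) (weight
  0.7) and Uniform(15, 40), so the CADD ≥ 15 branch is exercised from both
  sides; functional classes are drawn with a realistic protein-changing
  majority plus synonymous/non-coding mass to exercise the class filter.
* **Capture kits**: three masks covering 100/92/85% of variants (callable
  probability 0.98 covered, 0.10 uncovered), emulating overlapping 38–50 Mb
  exome designs. Kit assignment is independent of cohort by default — a
  requirement, since the null configuration must make the three groups
  exchangeable — and per-cohort kit mixtures are opt-in for constructing
  batch effects.
* **Planted effects**: `effect_count` scales the case allele frequency
  (excess variant count); `effect_score` adds to the scaled deleteriousness
  of every variant carried by at least one case, emulating
  over-representation of damaging alleles among case-carried variants —
  with rare MAFs, sharing with controls is minimal, so the shift lands
  almost entirely on cases, and at zero it changes nothing, preserving the
  null. `plant_exclusive_gene()` adds fully genotyped heterozygous carriers
  of new CADD-25 missense variants, case- and control-exclusive, at stated
  counts — the configuration of the gene-stage reference rows (e.g. 2 case
  carriers vs 4 control carriers).
* **Clinical covariates** drawn group-independently with roughly the
  case-mix of a severe-epilepsy cohort (about a third Dravet-like syndrome,
  median ~8 lifetime anti-epileptic drugs, onset in early childhood), with
  5% unknowns in the tri-state fields.

What the generator deliberately does **not** model: linkage disequilibrium
(variants are independent, so burden-test type-I error under LD is not
probed), sequencing-level artefacts below the genotype (depth, genotype
quality), relatedness, and population stratification (an ancestry-analysis
hook is out of scope by design). Passing tests therefore demonstrate the
statistical machinery under the stated sampling model, not robustness to
those real-data complications.

## Validation problem sizes and numerical choices

The test suite validates operating characteristics at deliberately chosen
scales: family-wise error of the six-way burden comparison over 500 null
replicates of an 18/87/1479 cohort at ~200 variants; detection power over 40
replicates at ~8000 variants with a +10 per-variant score shift (and
robustness of that result to excluding any single gene when the effect spans
hundreds of genes); permutation p-values against exhaustive label enumeration
on ≤ 25-individual designs; and the I-value product formula against direct
enumeration. Variant counts are scaled down from the ~90,000 of a real
exome-wide analysis, which proportionally scales down per-individual carried
counts; the chosen sizes keep every distributional regime represented
(ties-heavy small counts in the null study, continuous-like scores in the
power study).

Numerical conventions collected in one place: exact Wilcoxon branch at pooled
n ≤ 12; permutation p-values as $(k+1)/(B+1)$; statistic exceedance compared
with a $10^{-9}$ slack to absorb floating-point noise; MAD with SD fallback
for degenerate spread; zero-margin contingency tables return p = 1; constant
two-sample comparisons return p = 1; genes with no observed copies are
skipped rather than scored 0; and all simulation randomness flows from a
single integer seed via isolated RNG scopes, so results are reproducible and
independent of ambient RNG state.

## Limitations

The burden comparison is rank-based and unadjusted — no covariate-adjusted
regression is offered, matching the design it implements. The gene stage
assumes the epilepsy-control exclusion enriches for case-specific signal; in
a small epilepsy-control cohort that filter is imperfect, and associated
genes may relate to epilepsy as well as to the case phenotype. Ancestry
handling is a placeholder: inputs are assumed ancestry-homogeneous post-QC.
CADD scores are consumed as annotations, never computed.
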