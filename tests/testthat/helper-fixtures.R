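# Small programmatic fixtures shared across test files.

# genotype matrix from a plain integer matrix (NA = missing)
make_gm <- function(mat, group) {
  if (is.null(rownames(mat))) rownames(mat) <- sprintf("s%02d", seq_len(nrow(mat)))
  if (is.null(colnames(mat))) colnames(mat) <- sprintf("1:%d:A:G", 100 + seq_len(ncol(mat)))
  geno_matrix(mat, group)
}

# annotation rows for given keys with overridable fields
make_ann <- function(keys, gene = "GENE1", func_class = "missense",
                     ref_maf = 0.001, cadd_scaled = 20, cadd_raw = 2) {
  tibble::tibble(
    key = keys,
    gene = rep_len(gene, length(keys)),
    func_class = rep_len(func_class, length(keys)),
    ref_maf = rep_len(ref_maf, length(keys)),
    cadd_raw = rep_len(cadd_raw, length(keys)),
    cadd_scaled = rep_len(cadd_scaled, length(keys))
  )
}

# --- 10-variant rule-violation fixture --------------------------------------
# Ten annotated variants over three small groups; exactly four violate exactly
# one selection criterion each (synonymous class; common MAF; zero carriers;
# sequenced fraction at/below 0.80 in one group). The other six survive.
ten_variant_fixture <- function() {
  n_case <- 10; n_epi <- 10; n_dis <- 20
  n <- n_case + n_epi + n_dis
  group <- rep(c("case", "epilepsy_control", "disease_control"),
               c(n_case, n_epi, n_dis))
  keys <- sprintf("1:%d:A:G", 1000 + 1:10)
  g <- matrix(0L, n, 10, dimnames = list(sprintf("s%02d", 1:n), keys))
  g[1, ] <- 1L                       # one carrier for every variant ...
  g[1, 3] <- 0L                      # ... except v3: zero carriers
  # v4: sequenced in exactly 8/10 cases (0.80, fails the strict > 0.80 rule)
  g[2:3, 4] <- NA_integer_
  ann <- make_ann(keys)
  ann$func_class[1] <- "synonymous"  # v1: not protein-changing
  ann$ref_maf[2] <- 0.006            # v2: too common
  surviving <- keys[c(5, 6, 7, 8, 9, 10)]
  list(gm = geno_matrix(g, group), ann = ann, surviving = surviving)
}

# --- threshold-sweep batch-effect fixture -----------------------------------
# Deterministic construction in which a capture batch effect inflates burden
# score spread at permissive thresholds:
#  * 4 "core" variants (score 10) sequenced in 22/25 epilepsy controls (0.88):
#    pass at 0.8, fail at 0.9 (so 0.9 keeps nothing -> variability NA);
#  * 2 "batch" variants (score 50) sequenced in 15/20 disease controls (0.75):
#    pass at <= 0.7 only, and their missing carriers crater five individuals'
#    scores, inflating the CV at permissive thresholds.
# Expected CV: ~0.222 at 0.5-0.7, ~0.110 at 0.8, NA at 0.9 -> argmin 0.8.
sweep_fixture <- function() {
  n_case <- 10; n_epi <- 25; n_dis <- 20
  n <- n_case + n_epi + n_dis
  group <- rep(c("case", "epilepsy_control", "disease_control"),
               c(n_case, n_epi, n_dis))
  keys <- sprintf("1:%d:A:G", 2000 + 1:6)
  g <- matrix(1L, n, 6, dimnames = list(sprintf("s%02d", 1:n), keys))
  epi_rows <- which(group == "epilepsy_control")
  # each core variant missing in 3 distinct epilepsy controls (12 in all)
  for (v in 1:4) g[epi_rows[(3 * v - 2):(3 * v)], v] <- NA_integer_
  dis_rows <- which(group == "disease_control")
  g[dis_rows[1:5], 5:6] <- NA_integer_   # batch variants: same 5 controls
  ann <- make_ann(keys, cadd_scaled = c(10, 10, 10, 10, 50, 50))
  list(gm = geno_matrix(g, group), ann = ann)
}

# independent oracles for the unique-variant statistics, written from the
# definitions (used to cross-check the permutation machinery)
oracle_burden <- function(g, case_rows) {
  ctrl_rows <- setdiff(seq_len(nrow(g)), case_rows)
  y_case <- colSums(g[case_rows, , drop = FALSE], na.rm = TRUE)
  y_ctrl <- colSums(g[ctrl_rows, , drop = FALSE], na.rm = TRUE)
  sum(y_case[y_ctrl == 0])
}

oracle_calpha <- function(g, case_rows) {
  ctrl_rows <- setdiff(seq_len(nrow(g)), case_rows)
  tot <- 0
  any_used <- FALSE
  for (v in seq_len(ncol(g))) {
    y <- sum(g[case_rows, v], na.rm = TRUE)
    n_i <- y + sum(g[ctrl_rows, v], na.rm = TRUE)
    if (n_i < 1) next
    n_gc <- sum(!is.na(g[case_rows, v]))
    n_gt <- n_gc + sum(!is.na(g[ctrl_rows, v]))
    p0 <- n_gc / n_gt
    tot <- tot + (y - n_i * p0)^2 - n_i * p0 * (1 - p0)
    any_used <- TRUE
  }
  if (any_used) tot else NA_real_
}
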