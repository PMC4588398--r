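#' Genotype matrix with explicit missingness
#'
#' A `geno_matrix` holds jointly called genotypes as a samples x variants
#' integer matrix of non-reference allele counts (0, 1, 2), with `NA` as the
#' missing-genotype code. Missing is a first-class state, never conflated with
#' homozygous reference: joint calling across all cohorts is what makes the
#' distinction meaningful, and every downstream count in the pipeline treats
#' `NA` as "not sequenced", not as "no alternate allele". Each sample carries a
#' group label (`case`, `epilepsy_control`, `disease_control`).
#'
#' @param geno Integer matrix, samples in rows (rownames = sample ids),
#'   variants in columns (colnames = canonical variant keys
#'   `"chrom:pos:ref:alt"`), entries in `{0, 1, 2, NA}`.
#' @param group Character or factor of group labels, one per sample, values in
#'   `c("case", "epilepsy_control", "disease_control")`. May be `NA` when
#'   genotypes are read before a manifest is attached.
#'
#' @return An object of class `geno_matrix`.
#' @examples
#' g <- matrix(c(0L, 1L, NA, 2L), 2, 2,
#'             dimnames = list(c("s1", "s2"), c("1:100:A:T", "1:200:G:C")))
#' gm <- geno_matrix(g, c("case", "disease_control"))
#' n_samples(gm)
#' @export
geno_matrix <- function(geno, group = NULL) {
  if (!is.matrix(geno)) abort("`geno` must be a matrix.")
  storage.mode(geno) <- "integer"
  if (is.null(rownames(geno)) || is.null(colnames(geno))) {
    abort("`geno` must have sample rownames and variant-key colnames.")
  }
  bad <- geno[!is.na(geno)]
  if (length(bad) && (any(bad < 0L) || any(bad > 2L))) {
    abort("Genotype codes must be 0, 1, 2 or NA (missing).")
  }
  if (anyDuplicated(colnames(geno))) abort("Duplicate variant keys in matrix.")
  if (anyDuplicated(rownames(geno))) abort("Duplicate sample ids in matrix.")
  if (is.null(group)) group <- rep(NA_character_, nrow(geno))
  group <- as.character(group)
  if (length(group) != nrow(geno)) {
    abort("`group` must have one label per sample.")
  }
  known <- is.na(group) | group %in% GROUPS
  if (!all(known)) {
    abort(paste0("Unknown group label(s): ",
                 paste(unique(group[!known]), collapse = ", ")))
  }
  structure(
    list(geno = geno, group = factor(group, levels = GROUPS)),
    class = "geno_matrix"
  )
}

#' @export
print.geno_matrix <- function(x, ...) {
  tab <- table(x$group, useNA = "ifany")
  cat("<geno_matrix> ", nrow(x$geno), " samples x ", ncol(x$geno),
      " variants\n", sep = "")
  cat("  groups: ", paste(names(tab), tab, sep = "=", collapse = ", "), "\n",
      sep = "")
  miss <- mean(is.na(x$geno))
  cat(sprintf("  missingness: %.1f%%\n", 100 * miss))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$geno)

#' @rdname geno_matrix
#' @param x A `geno_matrix`.
#' @export
n_samples <- function(x) nrow(x$geno)

#' @rdname geno_matrix
#' @export
n_variants <- function(x) ncol(x$geno)

#' @rdname geno_matrix
#' @export
sample_ids <- function(x) rownames(x$geno)

#' @rdname geno_matrix
#' @export
variant_keys <- function(x) colnames(x$geno)

#' Convert a genotype matrix to a long tibble
#'
#' One row per sample x variant call; `code` is `NA` for missing genotypes.
#'
#' @param x A `geno_matrix`.
#' @param ... Unused.
#' @return A tibble with columns `sample`, `group`, `key`, `code`.
#' @method as_tibble geno_matrix
#' @export
as_tibble.geno_matrix <- function(x, ...) {
  tibble(
    sample = rep(rownames(x$geno), times = ncol(x$geno)),
    group  = rep(as.character(x$group), times = ncol(x$geno)),
    key    = rep(colnames(x$geno), each = nrow(x$geno)),
    code   = as.integer(x$geno)
  )
}

#' Attach group labels from a sample manifest
#'
#' Reconciles the samples of a genotype matrix against a manifest and sets the
#' per-sample group labels. Every sample in the matrix must appear in the
#' manifest.
#'
#' @param gm A `geno_matrix`.
#' @param manifest Tibble with columns `sample` and `group` (see
#'   [read_manifest()]).
#' @return The `geno_matrix` with group labels set.
#' @export
attach_groups <- function(gm, manifest) {
  stopifnot(inherits(gm, "geno_matrix"))
  missing_ids <- setdiff(sample_ids(gm), manifest$sample)
  if (length(missing_ids)) {
    abort(paste0("Sample(s) in genotypes but not in manifest: ",
                 paste(head(missing_ids, 5), collapse = ", "),
                 if (length(missing_ids) > 5) ", ..."))
  }
  grp <- manifest$group[match(sample_ids(gm), manifest$sample)]
  geno_matrix(gm$geno, grp)
}

#' Subset a genotype matrix
#'
#' @param gm A `geno_matrix`.
#' @param samples,variants Optional character vectors (or logical/integer
#'   indices) selecting samples / variant keys to keep.
#' @return A `geno_matrix`.
#' @export
subset_geno <- function(gm, samples = NULL, variants = NULL) {
  stopifnot(inherits(gm, "geno_matrix"))
  g <- gm$geno
  grp <- as.character(gm$group)
  if (!is.null(samples)) {
    idx <- if (is.character(samples)) match(samples, rownames(g)) else samples
    g <- g[idx, , drop = FALSE]
    grp <- grp[idx]
  }
  if (!is.null(variants)) {
    g <- g[, variants, drop = FALSE]
  }
  geno_matrix(g, grp)
}

# ---- variant keys -----------------------------------------------------------

#' Canonical variant keys
#'
#' A variant key is `"chrom:pos:ref:alt"` after normalisation: shared trailing
#' then leading bases of ref/alt are trimmed (position advanced past trimmed
#' leading bases), so that equivalent right-padded representations of the same
#' indel key identically. Full left-alignment against a reference sequence is
#' out of scope; trimming alone makes keys from a decomposed VCF and from an
#' annotation table join unambiguously.
#'
#' @param chrom,pos,ref,alt Vectors describing biallelic variants (`pos`
#'   1-based; one `alt` allele per record).
#' @return Character vector of keys.
#' @examples
#' variant_key("2", 100, "AT", "AG")   # trims shared leading base
#' variant_key("2", 100, "CTT", "CT")  # trims shared trailing base
#' @export
variant_key <- function(chrom, pos, ref, alt) {
  n <- length(chrom)
  pos <- as.integer(pos)
  ref <- toupper(as.character(ref))
  alt <- toupper(as.character(alt))
  stopifnot(length(pos) == n, length(ref) == n, length(alt) == n)
  if (any(pos < 1L)) abort("Variant positions must be >= 1.")
  if (any(ref == alt)) abort("ref and alt alleles must differ.")
  for (i in seq_len(n)) {
    r <- ref[i]; a <- alt[i]
    # trim shared suffix
    while (nchar(r) > 1L && nchar(a) > 1L &&
           substr(r, nchar(r), nchar(r)) == substr(a, nchar(a), nchar(a))) {
      r <- substr(r, 1L, nchar(r) - 1L)
      a <- substr(a, 1L, nchar(a) - 1L)
    }
    # trim shared prefix, advancing pos
    while (nchar(r) > 1L && nchar(a) > 1L &&
           substr(r, 1L, 1L) == substr(a, 1L, 1L)) {
      r <- substr(r, 2L, nchar(r))
      a <- substr(a, 2L, nchar(a))
      pos[i] <- pos[i] + 1L
    }
    ref[i] <- r; alt[i] <- a
  }
  paste(chrom, pos, ref, alt, sep = ":")
}

#' @rdname variant_key
#' @param key Character vector of keys to split back into fields.
#' @return For `parse_variant_key()`, a tibble with columns `key`, `chrom`,
#'   `pos`, `ref`, `alt`.
#' @export
parse_variant_key <- function(key) {
  parts <- strsplit(key, ":", fixed = TRUE)
  bad <- lengths(parts) != 4L
  if (any(bad)) {
    abort(paste0("Malformed variant key(s): ",
                 paste(head(key[bad], 3), collapse = ", ")))
  }
  tibble(
    key = key,
    chrom = vapply(parts, `[[`, "", 1L),
    pos = as.integer(vapply(parts, `[[`, "", 2L)),
    ref = vapply(parts, `[[`, "", 3L),
    alt = vapply(parts, `[[`, "", 4L)
  )
}
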