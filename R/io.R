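#' Read a multi-sample VCF into a genotype matrix
#'
#' Parses the GT field of a VCF (v4.2), decomposing multi-allelic records into
#' one biallelic record per alternate allele. Genotype coding: number of copies
#' of the record's alternate allele (0, 1, 2). Any genotype containing a `.`
#' allele — fully missing `./.` or half-calls like `0/.` — is coded missing
#' (`NA`): half-calls are treated conservatively as unsequenced. Phase
#' separators (`|`) are ignored.
#'
#' Decomposition preserves the total non-reference allele count per sample per
#' site: a `1/2` genotype at a triallelic site contributes one copy to each of
#' the two derived biallelic records.
#'
#' @param path Path to a VCF file (plain text or bgzip/gzip).
#' @param manifest Optional manifest tibble (see [read_manifest()]); when
#'   given, samples are reconciled against it and group labels attached. A VCF
#'   sample absent from the manifest is an error.
#' @return A [geno_matrix()].
#' @export
read_vcf <- function(path, manifest = NULL) {
  if (!file.exists(path)) abort(paste0("No such VCF: ", path))
  vcf <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) abort(paste0("Failed to parse VCF '", path, "': ",
                                     conditionMessage(e)))
  )
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1, dimnames = list(NULL, names(gt)))
  samples <- colnames(gt)

  keys <- character(0)
  rows <- list()
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    gtv <- gt[i, ]
    alleles <- strsplit(gsub("|", "/", gtv, fixed = TRUE), "/", fixed = TRUE)
    has_dot <- vapply(alleles, function(a) length(a) == 0L || any(a == "."),
                      logical(1))
    has_dot <- has_dot | is.na(gtv)
    for (j in seq_along(alts)) {
      code <- vapply(alleles, function(a) sum(a == as.character(j)), 0L)
      code[has_dot] <- NA_integer_
      keys <- c(keys, variant_key(fix[i, "CHROM"], fix[i, "POS"],
                                  fix[i, "REF"], alts[j]))
      rows[[length(rows) + 1L]] <- code
    }
  }
  if (anyDuplicated(keys)) {
    abort(paste0("Duplicate variant key after decomposition: ",
                 keys[duplicated(keys)][1]))
  }
  geno <- do.call(rbind, rows)
  geno <- t(geno)  # samples x variants
  dimnames(geno) <- list(samples, keys)
  gm <- geno_matrix(geno)
  if (!is.null(manifest)) gm <- attach_groups(gm, manifest)
  gm
}

#' Write a genotype matrix as a plain-text VCF
#'
#' Emits a minimal VCFv4.2 with GT-only FORMAT. Coordinates and alleles are
#' recovered from the canonical variant keys; records are sorted by chromosome
#' and position. Codes map to `0/0`, `0/1`, `1/1`; `NA` to `./.`.
#'
#' @param gm A [geno_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  stopifnot(inherits(gm, "geno_matrix"))
  vk <- parse_variant_key(variant_keys(gm))
  ord <- order(suppressWarnings(as.integer(vk$chrom)), vk$chrom, vk$pos, vk$ref, vk$alt)
  vk <- vk[ord, ]
  g <- gm$geno[, ord, drop = FALSE]
  gt_map <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  lines <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste0("##contig=<ID=", unique(vk$chrom), ">"),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_ids(gm)), collapse = "\t")
  )
  body <- vapply(seq_len(nrow(vk)), function(i) {
    gt <- gt_map[as.character(g[, i])]
    gt[is.na(gt)] <- "./."
    paste(c(vk$chrom[i], vk$pos[i], ".", vk$ref[i], vk$alt[i], ".", ".", ".",
            "GT", gt), collapse = "\t")
  }, character(1))
  writeLines(c(lines, body), path)
  invisible(path)
}

# fixed column contracts for the TSV formats
ANNOTATION_COLS <- c("key", "gene", "func_class", "ref_maf", "cadd_raw",
                     "cadd_scaled")
MANIFEST_COLS <- c("sample", "group", "sex", "age_last_followup",
                   "age_first_seizure", "epilepsy_duration", "syndrome",
                   "intellectual_disability", "lives_alone",
                   "convulsive_seizures_12m", "nocturnal_seizures_12m",
                   "n_aeds")

#' Read a variant annotation table
#'
#' Tab-separated with header; one row per canonical variant key carrying the
#' gene symbol, functional class, reference-population minor allele frequency
#' and CADD raw/scaled deleteriousness scores. Duplicate keys are an error.
#'
#' @param path Path to the TSV.
#' @return A tibble with columns `key`, `gene`, `func_class`, `ref_maf`,
#'   `cadd_raw`, `cadd_scaled`.
#' @export
read_annotations <- function(path) {
  ann <- readr::read_tsv(path, col_types = readr::cols(
    key = readr::col_character(),
    gene = readr::col_character(),
    func_class = readr::col_character(),
    ref_maf = readr::col_double(),
    cadd_raw = readr::col_double(),
    cadd_scaled = readr::col_double()
  ))
  missing_cols <- setdiff(ANNOTATION_COLS, names(ann))
  if (length(missing_cols)) {
    abort(paste0("Annotation table missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  validate_annotations(ann)
}

#' Validate (and return) an annotation tibble
#'
#' Enforces the variant-record invariants: unique keys, known functional
#' classes, minor-allele frequencies in \[0, 0.5\], non-negative scaled CADD.
#'
#' @param ann Annotation tibble.
#' @return `ann`, invisibly usable.
#' @export
validate_annotations <- function(ann) {
  dup <- ann$key[duplicated(ann$key)]
  if (length(dup)) {
    abort(paste0("Duplicate annotation key(s): ",
                 paste(head(unique(dup), 3), collapse = ", ")))
  }
  bad_class <- setdiff(unique(ann$func_class), FUNC_CLASSES)
  if (length(bad_class)) {
    abort(paste0("Unknown functional class(es): ",
                 paste(bad_class, collapse = ", ")))
  }
  if (any(ann$ref_maf < 0 | ann$ref_maf > 0.5)) {
    abort("ref_maf must lie in [0, 0.5] (minor-allele convention).")
  }
  if (any(ann$cadd_scaled < 0)) abort("cadd_scaled must be >= 0.")
  ann
}

#' @rdname read_annotations
#' @param ann Annotation tibble.
#' @export
write_annotations <- function(ann, path) {
  readr::write_tsv(ann[ANNOTATION_COLS], path)
  invisible(path)
}

#' Read a sample manifest
#'
#' Tab-separated with header; one row per sample with group label, sex,
#' clinical covariates and tri-state risk factors. `.` encodes unknown and is
#' read as `NA`; unknowns are excluded from the denominators of clinical
#' tests. Unknown group labels are an error.
#'
#' @param path Path to the TSV.
#' @return A tibble with the manifest columns (see Details).
#' @export
read_manifest <- function(path) {
  man <- readr::read_tsv(path, na = c(".", "NA", ""), col_types = readr::cols(
    sample = readr::col_character(),
    group = readr::col_character(),
    sex = readr::col_character(),
    age_last_followup = readr::col_double(),
    age_first_seizure = readr::col_double(),
    epilepsy_duration = readr::col_double(),
    syndrome = readr::col_character(),
    intellectual_disability = readr::col_character(),
    lives_alone = readr::col_character(),
    convulsive_seizures_12m = readr::col_character(),
    nocturnal_seizures_12m = readr::col_character(),
    n_aeds = readr::col_integer()
  ))
  missing_cols <- setdiff(MANIFEST_COLS, names(man))
  if (length(missing_cols)) {
    abort(paste0("Manifest missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  bad <- setdiff(unique(man$group), GROUPS)
  if (length(bad)) {
    abort(paste0("Unknown group label(s): ", paste(bad, collapse = ", ")))
  }
  tri <- c("intellectual_disability", "lives_alone",
           "convulsive_seizures_12m", "nocturnal_seizures_12m")
  for (col in tri) {
    v <- man[[col]]
    bad <- setdiff(unique(v[!is.na(v)]), c("yes", "no"))
    if (length(bad)) {
      abort(paste0("Tri-state column ", col, " has value(s) ",
                   paste(bad, collapse = ", "), "; expected yes/no/."))
    }
  }
  man
}

#' @rdname read_manifest
#' @param man Manifest tibble.
#' @export
write_manifest <- function(man, path) {
  readr::write_tsv(man[MANIFEST_COLS], path, na = ".")
  invisible(path)
}

#' Write result tables to a directory
#'
#' Each element of `tables` (a named list of data frames) is written as
#' `<name>.tsv` under `dir`, with `.` for missing values — the same TSV
#' dialect the readers use.
#'
#' @param tables Named list of data frames.
#' @param dir Output directory (created if needed).
#' @return Character vector of file paths, invisibly.
#' @export
write_results <- function(tables, dir) {
  stopifnot(is.list(tables), !is.null(names(tables)), all(nzchar(names(tables))))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(names(tables), function(nm) {
    p <- file.path(dir, paste0(nm, ".tsv"))
    readr::write_tsv(as.data.frame(tables[[nm]]), p, na = ".")
    p
  }, character(1))
  invisible(paths)
}
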