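#' Read a SNP panel table
#'
#' A panel lists the birth-weight-associated variants used to build polygenic
#' scores: one row per variant with its effect (birth-weight-increasing)
#' allele, effect-allele frequency, effect class and per-allele weights on
#' birth weight acting through the maternal (`w_maternal`) and fetal
#' (`w_fetal`) genome. Effect classes follow the maternal/fetal partition of
#' birth-weight GWAS hits: `M_ONLY` (maternal-specific), `F_ONLY`
#' (fetal-specific), `SHARED_CONC` / `SHARED_OPP` (directionally concordant /
#' opposing maternal and fetal effects) and `UNCLASSIFIED`.
#'
#' Files are tab-separated UTF-8 with a header row; lines starting with `#`
#' are ignored.
#'
#' @param path Path to a TSV file.
#' @return A tibble with columns `variant_id`, `effect_allele`, `eaf`,
#'   `effect_class`, `w_maternal`, `w_fetal`, validated by
#'   [validate_panel()].
#' @export
#' @examples
#' p <- simulate_panel(5, seed = 1)
#' f <- tempfile(fileext = ".tsv")
#' write_panel(p, f)
#' read_panel(f)
read_panel <- function(path) {
  tbl <- read_tsv_strict(path)
  required <- c("variant_id", "effect_allele", "eaf", "effect_class",
                "w_maternal", "w_fetal")
  missing <- setdiff(required, names(tbl))
  if (length(missing) > 0) {
    abort(sprintf("Panel file is missing required column(s): %s.",
                  paste(missing, collapse = ", ")),
          class = "duomr_format_error")
  }
  panel <- tibble::as_tibble(tbl[required])
  panel$eaf <- as.numeric(panel$eaf)
  panel$w_maternal <- as.numeric(panel$w_maternal)
  panel$w_fetal <- as.numeric(panel$w_fetal)
  validate_panel(panel)
}

#' Validate a SNP panel
#'
#' Checks the panel invariants: unique variant ids, effect-allele frequencies
#' strictly inside (0, 1), recognised effect classes, and the class
#' constraints that maternal-specific variants carry no fetal weight and
#' fetal-specific variants no maternal weight.
#'
#' @param panel A data frame as returned by [read_panel()] or
#'   [simulate_panel()].
#' @return The validated panel, invisibly coerced to a tibble.
#' @export
validate_panel <- function(panel) {
  panel <- tibble::as_tibble(panel)
  if (nrow(panel) == 0) {
    abort("Panel has no variants.", class = "duomr_validation_error")
  }
  dup <- unique(panel$variant_id[duplicated(panel$variant_id)])
  if (length(dup) > 0) {
    abort(sprintf("Duplicated variant_id(s): %s.", paste(dup, collapse = ", ")),
          class = "duomr_validation_error")
  }
  if (any(!panel$effect_allele %in% c("A", "C", "G", "T"))) {
    abort("`effect_allele` must be one of A/C/G/T.",
          class = "duomr_validation_error")
  }
  if (any(!is.finite(panel$eaf)) || any(panel$eaf <= 0 | panel$eaf >= 1)) {
    abort("`eaf` must lie strictly in (0, 1) for every variant.",
          class = "duomr_validation_error")
  }
  bad_class <- setdiff(unique(panel$effect_class), PANEL_CLASSES)
  if (length(bad_class) > 0) {
    abort(sprintf("Unknown effect_class value(s): %s.",
                  paste(bad_class, collapse = ", ")),
          class = "duomr_validation_error")
  }
  if (any(panel$effect_class == "M_ONLY" & panel$w_fetal != 0)) {
    abort("M_ONLY variants must have w_fetal = 0.",
          class = "duomr_validation_error")
  }
  if (any(panel$effect_class == "F_ONLY" & panel$w_maternal != 0)) {
    abort("F_ONLY variants must have w_maternal = 0.",
          class = "duomr_validation_error")
  }
  panel
}

#' Write a SNP panel, dosage matrix or phenotype table to TSV
#'
#' Writers prepend a `# duomr-schema:` comment line recording the table kind
#' and schema version, then the tab-separated data with a header row.
#' Numeric values are written at full precision so a write/read round trip
#' reproduces them to better than 1e-12.
#'
#' @param x Table to write.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(x, path) write_duomr_tsv(validate_panel(x), path, "panel")

#' @rdname write_panel
#' @export
write_dosages <- function(x, path) write_duomr_tsv(x, path, "dosages")

#' @rdname write_panel
#' @export
write_phenotypes <- function(x, path) write_duomr_tsv(x, path, "phenotypes")

write_duomr_tsv <- function(x, path, kind) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# duomr-schema: %s v1", kind), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

read_tsv_strict <- function(path) {
  tbl <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  if (nrow(tbl) == 0) {
    abort(sprintf("No data rows in '%s'.", path),
          class = "duomr_validation_error")
  }
  tbl
}

#' Read a genotype dosage matrix
#'
#' Dosages are coded as the count of the panel's effect allele: 0/1/2 for
#' hard calls, fractional values in \[0, 2\] for imputed input. The TSV
#' layout is one row per individual (`individual_id` column) and one column
#' per variant. Panel variants absent from the file are dropped (with a
#' message reporting the count) or raise an error, depending on
#' `on_missing`; the mirroring of typical biobank scoring where some panel
#' SNPs are unavailable in the genotype data. Missing genotypes within a
#' retained variant are mean-imputed from the cohort (with a message) so
#' case-wise deletion cannot silently change the sample size.
#'
#' @param path TSV file path.
#' @param panel Optional panel; when given, the matrix is restricted to (and
#'   checked against) the panel's variants.
#' @param on_missing `"drop_variant"` (default) or `"fail"` for panel
#'   variants not present in the file.
#' @return A tibble: `individual_id` plus one numeric column per variant.
#' @export
read_dosages <- function(path, panel = NULL,
                         on_missing = c("drop_variant", "fail")) {
  on_missing <- match.arg(on_missing)
  tbl <- read_tsv_strict(path)
  if (!"individual_id" %in% names(tbl)) {
    abort("Dosage file must contain an `individual_id` column.",
          class = "duomr_format_error")
  }
  tbl$individual_id <- as.character(tbl$individual_id)
  if (!is.null(panel)) {
    panel <- validate_panel(panel)
    absent <- setdiff(panel$variant_id, names(tbl))
    if (length(absent) > 0) {
      if (on_missing == "fail") {
        abort(sprintf("Panel variant(s) absent from dosage file: %s.",
                      paste(absent, collapse = ", ")),
              class = "duomr_validation_error")
      }
      message(sprintf("Dropped %d of %d panel variant(s) absent from dosages.",
                      length(absent), nrow(panel)))
    }
    keep <- intersect(panel$variant_id, names(tbl))
    tbl <- tbl[c("individual_id", keep)]
  }
  validate_dosages(tbl)
}

#' @rdname read_dosages
#' @param dosages A dosage tibble to validate/impute in place.
#' @export
validate_dosages <- function(dosages) {
  dosages <- tibble::as_tibble(dosages)
  vars <- setdiff(names(dosages), "individual_id")
  if (length(vars) == 0) {
    abort("Dosage table has no variant columns.",
          class = "duomr_validation_error")
  }
  m <- as.matrix(dosages[vars])
  if (!is.numeric(m)) {
    abort("Dosage columns must be numeric.", class = "duomr_format_error")
  }
  n_na <- sum(is.na(m))
  if (n_na > 0) {
    message(sprintf("Mean-imputed %d missing genotype(s).", n_na))
    for (j in seq_along(vars)) {
      col <- m[, j]
      if (anyNA(col)) {
        mu <- mean(col, na.rm = TRUE)
        if (is.nan(mu)) {
          abort(sprintf("Variant %s has no observed genotypes.", vars[j]),
                class = "duomr_validation_error")
        }
        col[is.na(col)] <- mu
        m[, j] <- col
      }
    }
  }
  if (any(m < 0 | m > 2)) {
    abort("Dosages must lie in [0, 2] (count of effect allele).",
          class = "duomr_validation_error")
  }
  out <- tibble::as_tibble(as.data.frame(m))
  out <- dplyr::bind_cols(dosages["individual_id"], out)
  out
}

#' Read dosages from a VCF file
#'
#' Reads biallelic SNVs from a VCF 4.x file and converts them to effect-allele
#' dosages for the supplied panel. The `DS` FORMAT field is used when present;
#' otherwise hard `GT` calls are counted. Counting is oriented so the dosage
#' is the number of copies of the panel's effect allele (ALT counts are
#' flipped to `2 - d` when the effect allele is the REF allele). Panels are
#' assumed pre-harmonized: strand-ambiguous variants are taken at face value.
#'
#' @inheritParams read_dosages
#' @param field `"auto"` (DS when available, else GT), `"DS"` or `"GT"`.
#' @return A dosage tibble as in [read_dosages()].
#' @export
read_dosages_vcf <- function(path, panel, field = c("auto", "DS", "GT"),
                             on_missing = c("drop_variant", "fail")) {
  field <- match.arg(field)
  on_missing <- match.arg(on_missing)
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    abort("VCF input requires the 'vcfR' package.")
  }
  panel <- validate_panel(panel)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  biallelic <- !grepl(",", fix$ALT %||% "") &
    nchar(fix$REF) == 1 & nchar(fix$ALT) == 1
  ids <- fix$ID
  keep <- which(biallelic & ids %in% panel$variant_id)
  absent <- setdiff(panel$variant_id, ids[keep])
  if (length(absent) > 0) {
    if (on_missing == "fail") {
      abort(sprintf("Panel variant(s) absent from VCF: %s.",
                    paste(absent, collapse = ", ")),
            class = "duomr_validation_error")
    }
    message(sprintf("Dropped %d of %d panel variant(s) absent from VCF.",
                    length(absent), nrow(panel)))
  }
  if (length(keep) == 0) {
    abort("No usable panel variants in VCF.", class = "duomr_validation_error")
  }
  has_ds <- "DS" %in% vcfR::vcf_field_names(vcf, tag = "FORMAT")$ID
  use_ds <- switch(field, DS = TRUE, GT = FALSE, auto = has_ds)
  if (use_ds && !has_ds) {
    abort("VCF has no DS FORMAT field.", class = "duomr_format_error")
  }
  if (use_ds) {
    d <- vcfR::extract.gt(vcf, element = "DS", as.numeric = TRUE)
  } else {
    gt <- vcfR::extract.gt(vcf, element = "GT")
    d <- apply(gt, c(1, 2), function(g) {
      if (is.na(g)) return(NA_real_)
      sum(as.integer(strsplit(g, "[/|]")[[1]]))
    })
  }
  d <- d[keep, , drop = FALSE]
  rownames(d) <- ids[keep]
  # orient to the panel's effect allele
  alt <- fix$ALT[keep]
  eff <- panel$effect_allele[match(ids[keep], panel$variant_id)]
  flip <- eff != alt
  d[flip, ] <- 2 - d[flip, ]
  out <- tibble::as_tibble(t(d))
  out <- dplyr::bind_cols(tibble::tibble(individual_id = colnames(d)), out)
  validate_dosages(out)
}

#' Read a phenotype table
#'
#' Phenotype tables carry one row per individual: `individual_id`, optional
#' `birth_weight` in grams, binary endpoint columns (0/1), and covariates
#' such as `age` and `sex`.
#'
#' @param path TSV file path.
#' @return A tibble.
#' @export
read_phenotypes <- function(path) {
  tbl <- read_tsv_strict(path)
  if (!"individual_id" %in% names(tbl)) {
    abort("Phenotype file must contain an `individual_id` column.",
          class = "duomr_format_error")
  }
  tbl$individual_id <- as.character(tbl$individual_id)
  tibble::as_tibble(tbl)
}
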