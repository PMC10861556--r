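#' Unweighted polygenic score
#'
#' The raw unweighted score is the number of effect (birth-weight-increasing)
#' alleles summed over the panel subset -- integer-valued for hard genotype
#' calls. This is the lead-SNP scoring used for maternal-specific instruments,
#' preferred over weighted scores when per-variant effects on intrauterine
#' growth are unknown.
#'
#' @param dosages Dosage tibble (`individual_id` + variant columns).
#' @param panel Panel (or panel subset) whose variants are summed; variants
#'   absent from `dosages` raise an error (subset the panel first, or use
#'   [read_dosages()] with `on_missing = "drop_variant"`).
#' @param score_name Label stored in the output.
#' @return A long tibble `individual_id`, `score`, `value` (raw scale) with
#'   attribute `n_variants_used`.
#' @export
#' @examples
#' panel <- simulate_panel(4, seed = 1)
#' coh <- simulate_families(panel, 10, seed = 2)
#' unweighted_score(coh$dosages, panel)
unweighted_score <- function(dosages, panel, score_name = "unweighted") {
  panel <- validate_panel(panel)
  G <- score_dosage_matrix(dosages, panel)
  raw_score_tbl(dosages$individual_id, unname(rowSums(G)), score_name,
                ncol(G))
}

#' Weighted polygenic score
#'
#' Raw score `sum(w * dosage)` using the panel's maternal or fetal
#' per-allele weights. Variants whose chosen weight is zero still enter the
#' sum (contributing nothing); an all-zero weight column is an error.
#'
#' @inheritParams unweighted_score
#' @param which `"maternal"` or `"fetal"` weight column.
#' @return A long tibble as in [unweighted_score()].
#' @export
weighted_score <- function(dosages, panel, which = c("maternal", "fetal"),
                           score_name = NULL) {
  which <- match.arg(which)
  panel <- validate_panel(panel)
  w <- if (which == "maternal") panel$w_maternal else panel$w_fetal
  if (all(w == 0)) {
    abort(sprintf("All %s weights are zero; cannot form a weighted score.",
                  which))
  }
  G <- score_dosage_matrix(dosages, panel)
  raw_score_tbl(dosages$individual_id, as.numeric(G %*% w),
                score_name %||% paste0("weighted-", which), ncol(G))
}

score_dosage_matrix <- function(dosages, panel) {
  if (nrow(panel) == 0) abort("Empty panel subset.")
  missing <- setdiff(panel$variant_id, names(dosages))
  if (length(missing) > 0) {
    abort(sprintf("Variant(s) not present in dosages: %s.",
                  paste(missing, collapse = ", ")))
  }
  dosage_matrix(dosages)[, panel$variant_id, drop = FALSE]
}

raw_score_tbl <- function(ids, values, score_name, n_used) {
  out <- tibble::tibble(individual_id = ids, score = score_name,
                        value = values)
  attr(out, "n_variants_used") <- n_used
  out
}

#' Standardize polygenic scores to z-scores
#'
#' Scores are reported per SD unit: each score is centred and scaled within
#' the chosen reference group. The default pools the whole cohort (mothers,
#' fathers and children together); `"within_role"` standardizes separately
#' per role, which requires a `role` column (join one from the cohort's
#' `members` first, or pass `members`).
#'
#' @param scores Long score tibble (`individual_id`, `score`, `value`).
#' @param reference `"whole_cohort"` or `"within_role"`.
#' @param members Optional member table supplying `individual_id` -> `role`.
#' @return The tibble with `value` replaced by z-scores.
#' @export
standardize_scores <- function(scores,
                               reference = c("whole_cohort", "within_role"),
                               members = NULL) {
  reference <- match.arg(reference)
  scores <- tibble::as_tibble(scores)
  if (reference == "within_role" && !"role" %in% names(scores)) {
    if (is.null(members)) {
      abort("within_role standardization needs a `role` column or `members`.")
    }
    scores <- dplyr::left_join(scores,
                               members[c("individual_id", "role")],
                               by = "individual_id")
  }
  grp <- if (reference == "whole_cohort") "score" else c("score", "role")
  out <- scores %>%
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) %>%
    dplyr::mutate(.s = sd(.data$value)) %>%
    dplyr::ungroup()
  if (any(out$.s == 0 | is.na(out$.s))) {
    bad <- unique(out$score[out$.s == 0 | is.na(out$.s)])
    abort(sprintf("Zero-variance score(s): %s.", paste(bad, collapse = ", ")),
          class = "duomr_validation_error")
  }
  out <- out %>%
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) %>%
    dplyr::mutate(value = (.data$value - mean(.data$value)) / .data$.s) %>%
    dplyr::ungroup() %>%
    dplyr::select(-".s")
  attr(out, "n_variants_used") <- attr(scores, "n_variants_used")
  out
}

#' Catalog of standard score definitions for a panel
#'
#' Emits the lead-SNP score subsets used throughout the package:
#' * `M-SPECIFIC` -- maternal-specific variants (`M_ONLY`);
#' * `F-SPECIFIC` -- fetal-specific variants (`F_ONLY`);
#' * `M-ALL` -- all variants with a maternal effect
#'   (`M_ONLY + SHARED_CONC + SHARED_OPP`);
#' * `MF-ALL` -- `M-ALL` plus `F_ONLY` and `UNCLASSIFIED` (the full panel
#'   when every class is present);
#' * `weighted-maternal`, `weighted-fetal` -- weighted analogues over the
#'   whole panel.
#'
#' Sizes are reported from the supplied panel as given. Empty subsets are
#' flagged rather than dropped.
#'
#' @param panel A validated panel.
#' @return A tibble: `score`, `type` (unweighted/weighted), `classes`
#'   (list-column), `which` (weight column for weighted scores),
#'   `n_variants`, `empty`.
#' @export
score_catalog <- function(panel) {
  panel <- validate_panel(panel)
  defs <- tibble::tibble(
    score = c("M-SPECIFIC", "F-SPECIFIC", "M-ALL", "MF-ALL",
              "weighted-maternal", "weighted-fetal"),
    type = c(rep("unweighted", 4), rep("weighted", 2)),
    classes = list("M_ONLY", "F_ONLY",
                   c("M_ONLY", "SHARED_CONC", "SHARED_OPP"),
                   c("M_ONLY", "SHARED_CONC", "SHARED_OPP", "F_ONLY",
                     "UNCLASSIFIED"),
                   PANEL_CLASSES, PANEL_CLASSES),
    which = c(NA, NA, NA, NA, "maternal", "fetal")
  )
  defs$n_variants <- purrr::map_int(defs$classes,
                                    ~ sum(panel$effect_class %in% .x))
  defs$empty <- defs$n_variants == 0L
  defs
}

#' Compute a set of standard scores for a cohort
#'
#' Convenience wrapper: computes any subset of the [score_catalog()] scores
#' from a cohort's dosages and standardizes them. Variants missing from the
#' dosage table are dropped before scoring (their count is recorded in the
#' `n_used` column); remaining variants are not re-weighted. For unweighted
#' scores a validation pass errors if any defining per-allele weight is
#' negative, since effect alleles are assumed pre-oriented to increase birth
#' weight.
#'
#' @param cohort A `family_cohort`, or a dosage tibble.
#' @param panel Panel; defaults to the cohort's own.
#' @param scores Character vector of catalog score names.
#' @param standardize Passed to [standardize_scores()]; `"none"` skips
#'   standardization.
#' @return Long tibble `individual_id`, `score`, `value`, `n_used`.
#' @export
compute_scores <- function(cohort, panel = NULL,
                           scores = c("M-SPECIFIC", "F-SPECIFIC"),
                           standardize = c("whole_cohort", "within_role",
                                           "none")) {
  standardize <- match.arg(standardize)
  if (inherits(cohort, "family_cohort")) {
    dosages <- cohort$dosages
    members <- cohort$members
    panel <- panel %||% cohort$panel
  } else {
    dosages <- cohort
    members <- NULL
  }
  panel <- validate_panel(panel)
  catalog <- score_catalog(panel)
  unknown <- setdiff(scores, catalog$score)
  if (length(unknown) > 0) {
    abort(sprintf("Unknown score(s): %s.", paste(unknown, collapse = ", ")))
  }
  present <- intersect(panel$variant_id, names(dosages))
  res <- purrr::map(scores, function(sc) {
    def <- catalog[catalog$score == sc, ]
    sub <- panel[panel$effect_class %in% def$classes[[1]], ]
    n_panel <- nrow(sub)
    sub <- sub[sub$variant_id %in% present, ]
    if (nrow(sub) == 0) {
      abort(sprintf("Score %s has no scorable variants in this panel/dosages.",
                    sc))
    }
    if (def$type == "unweighted") {
      wcol <- if (sc == "F-SPECIFIC") sub$w_fetal else sub$w_maternal
      if (sc == "MF-ALL") {
        wcol <- ifelse(sub$effect_class == "F_ONLY", sub$w_fetal,
                       pmax(sub$w_maternal, sub$w_fetal))
      }
      if (any(wcol < 0)) {
        abort(sprintf(
          "Score %s: negative defining weight(s); effect alleles must be pre-oriented to increase birth weight.",
          sc), class = "duomr_validation_error")
      }
      out <- unweighted_score(dosages, sub, score_name = sc)
    } else {
      out <- weighted_score(dosages, panel[panel$variant_id %in% present, ],
                            which = def$which, score_name = sc)
    }
    if (nrow(sub) < n_panel && def$type == "unweighted") {
      message(sprintf("Score %s: using %d of %d panel variants.",
                      sc, nrow(sub), n_panel))
    }
    out$n_used <- attr(out, "n_variants_used")
    out
  })
  res <- dplyr::bind_rows(res)
  if (standardize != "none") {
    res <- standardize_scores(res, reference = standardize, members = members)
  }
  res
}
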