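#' Select disease-discordant same-sex full-sibling pairs
#'
#' For each family with at least two genotyped children, enumerates the
#' same-sex sibling duos discordant for the outcome (exactly one case) and
#' keeps one duo per family, chosen uniformly at random under `seed` when
#' several are eligible -- this preserves independence across pairs.
#' Families with no eligible duo are dropped. Because full siblings share
#' their mother's genotype, any PGS-disease association surviving the
#' within-pair comparison must act through the child's own genome.
#'
#' @param cohort A `family_cohort` simulated with `n_children = 2` (or any
#'   member table with sibling links).
#' @param phenotypes Child phenotype tibble holding the outcome.
#' @param outcome Name of the 0/1 outcome column.
#' @param scores Optional long standardized score tibble; when given, the
#'   chosen `score` is attached as `pgs_case` / `pgs_control`.
#' @param score Score name to attach.
#' @param seed Seed for the per-family random choice.
#' @return A tibble: `pair_id`, `family_id`, `case_id`, `control_id`, `sex`
#'   and, with `scores`, `pgs_case`, `pgs_control`.
#' @export
select_discordant_pairs <- function(cohort, phenotypes, outcome = "case",
                                    scores = NULL, score = "M-SPECIFIC",
                                    seed = NULL) {
  members <- if (inherits(cohort, "family_cohort")) cohort$members else cohort
  children <- dplyr::filter(members, .data$role == "CHILD")
  y <- setNames(phenotypes[[outcome]], phenotypes$individual_id)
  children$outcome <- unname(y[children$individual_id])
  children <- dplyr::filter(children, !is.na(.data$outcome))
  set_seed_if(seed)

  pairs <- children %>%
    dplyr::group_by(.data$family_id) %>%
    dplyr::group_map(function(kids, key) {
      if (nrow(kids) < 2) return(NULL)
      combos <- utils::combn(nrow(kids), 2)
      eligible <- apply(combos, 2, function(ij) {
        kids$sex[ij[1]] == kids$sex[ij[2]] &&
          sum(kids$outcome[ij]) == 1L
      })
      if (!any(eligible)) return(NULL)
      pick <- which(eligible)
      if (length(pick) > 1) pick <- sample(pick, 1) else pick <- pick[1]
      ij <- combos[, pick]
      case <- ij[which(kids$outcome[ij] == 1L)]
      ctrl <- ij[which(kids$outcome[ij] == 0L)]
      tibble::tibble(family_id = key$family_id,
                     case_id = kids$individual_id[case],
                     control_id = kids$individual_id[ctrl],
                     sex = kids$sex[case])
    }) %>%
    dplyr::bind_rows()
  if (nrow(pairs) == 0) {
    abort("No discordant same-sex sibling pairs available.",
          class = "duomr_validation_error")
  }
  pairs <- dplyr::mutate(pairs, pair_id = dplyr::row_number(),
                         .before = 1)
  if (!is.null(scores)) {
    sc <- dplyr::filter(scores, .data$score == .env$score)
    val <- setNames(sc$value, sc$individual_id)
    pairs$pgs_case <- unname(val[pairs$case_id])
    pairs$pgs_control <- unname(val[pairs$control_id])
  }
  pairs
}

#' Conditional logistic regression on 1:1 matched sibling pairs
#'
#' Estimates the within-family PGS effect by maximizing the matched
#' conditional likelihood
#' `prod( exp(b * x_case) / (exp(b * x_case) + exp(b * x_control)) )`,
#' equivalent to an intercept-free logistic regression of 1 on the
#' within-pair score difference. Matching absorbs everything shared within
#' the pair -- family, sex and in particular the mother's genotype -- so the
#' estimate isolates the child's own (fetal) genetic effect. Fitting uses
#' [survival::clogit()]. Pairs with equal scores contribute likelihood 1/2
#' for every `b` and are retained. No covariates enter by default;
#' `use_age_diff` adds the within-pair age difference.
#'
#' @param pairs Tibble from [select_discordant_pairs()] with `pgs_case` and
#'   `pgs_control` (and `age_case` / `age_control` if `use_age_diff`).
#' @param use_age_diff Add the case-control age difference as a covariate.
#' @return An object of class `sib_fit` (also `mr_fit`), with `tidy()` /
#'   `glance()` methods; the estimate is the logOR per SD of PGS.
#' @export
conditional_logit <- function(pairs, use_age_diff = FALSE) {
  pairs <- tibble::as_tibble(pairs)
  need <- c("pair_id", "pgs_case", "pgs_control")
  if (!all(need %in% names(pairs))) {
    abort("`pairs` must carry pair_id, pgs_case and pgs_control.")
  }
  diffs <- pairs$pgs_case - pairs$pgs_control
  if (all(diffs == 0)) {
    abort("All within-pair PGS differences are zero; effect unidentifiable.",
          class = "duomr_validation_error")
  }
  long <- tibble::tibble(
    pair_id = rep(pairs$pair_id, 2),
    status = rep(c(1L, 0L), each = nrow(pairs)),
    pgs = c(pairs$pgs_case, pairs$pgs_control),
    one = 1
  )
  # clogit() is coxph() on a constant-time Surv with the exact partial
  # likelihood; called directly so survival need not be attached
  form <- survival::Surv(one, status) ~ pgs + survival::strata(pair_id)
  if (use_age_diff) {
    if (!all(c("age_case", "age_control") %in% names(pairs))) {
      abort("`use_age_diff` needs age_case and age_control columns.")
    }
    long$age <- c(pairs$age_case, pairs$age_control)
    form <- survival::Surv(one, status) ~ pgs + age +
      survival::strata(pair_id)
  }
  fit <- withCallingHandlers(
    survival::coxph(form, data = long, method = "exact"),
    warning = function(w) {
      if (grepl("infinite|converge", conditionMessage(w))) {
        abort(paste("Conditional likelihood maximized at infinity:",
                    "separation across pairs."),
              class = "duomr_separation_error")
      }
      invokeRestart("muffleWarning")
    }
  )
  est <- stats::coef(fit)
  vc <- stats::vcov(fit)
  if (any(!is.finite(est)) || any(abs(est) > 15)) {
    abort("Diverging conditional-logit estimate: separation detected.",
          class = "duomr_separation_error")
  }
  structure(list(coefficients = est, vcov = vc, n = nrow(pairs),
                 n_cases = nrow(pairs), n_informative = sum(diffs != 0),
                 iterations = fit$iter %||% NA_integer_,
                 score_norm = NA_real_, firth = FALSE,
                 formula = form, model = "CONDITIONAL_LOGIT"),
            class = c("sib_fit", "mr_fit"))
}

#' @export
print.sib_fit <- function(x, ...) {
  cat(sprintf("<sib_fit> conditional logistic on %d discordant pairs (%d informative)\n",
              x$n, x$n_informative))
  print(tidy(x))
  invisible(x)
}

# Exact 1:1 matched conditional log-likelihood; exposed internally for the
# grid-search oracle used in validation.
conditional_loglik <- function(beta, pgs_case, pgs_control) {
  d <- beta * (pgs_case - pgs_control)
  sum(d - log1p(exp(d)))
}
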