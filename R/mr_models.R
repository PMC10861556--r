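# Logistic-regression engine: Newton / iteratively reweighted least squares
# with explicit rank and separation diagnostics. Convergence is declared on
# the score (gradient) norm, not the deviance. The optional Firth penalty
# adds the Jeffreys-prior score correction h * (1/2 - mu).
logistic_irls <- function(X, y, tol = 1e-8, maxit = 100, firth = FALSE,
                          separation_bound = 15) {
  p <- ncol(X)
  qr_x <- qr(X)
  if (qr_x$rank < p) {
    bad <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):p]]
    abort(sprintf("Design matrix is rank deficient; collinear column(s): %s.",
                  paste(bad, collapse = ", ")),
          class = "duomr_rank_error")
  }
  beta <- rep(0, p)
  converged <- FALSE
  score_norm <- Inf
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    w <- mu * (1 - mu)
    info <- crossprod(X * w, X)
    ch <- tryCatch(chol(info), error = function(e) NULL)
    if (is.null(ch)) {
      abort("Information matrix is singular (likely separation or extreme weights).",
            class = "duomr_separation_error")
    }
    resid <- y - mu
    if (firth) {
      # hat diagonal of W^(1/2) X (X'WX)^-1 X' W^(1/2)
      xu <- backsolve(ch, forwardsolve(t(ch), t(X)))
      h <- w * colSums(xu * t(X))
      resid <- resid + h * (0.5 - mu)
    }
    score <- drop(crossprod(X, resid))
    score_norm <- max(abs(score))
    if (score_norm < tol) {
      converged <- TRUE
      break
    }
    beta <- beta + drop(backsolve(ch, forwardsolve(t(ch), score)))
    if (!firth && max(abs(beta)) > separation_bound) {
      abort(paste("Diverging coefficients: complete or quasi-complete",
                  "separation detected. Consider `firth = TRUE`."),
            class = "duomr_separation_error")
    }
  }
  if (!converged) {
    abort(sprintf("IRLS did not converge in %d iterations (score norm %.3g).",
                  maxit, score_norm),
          class = "duomr_convergence_error")
  }
  vcov <- chol2inv(chol(crossprod(X * (plogis(drop(X %*% beta)) *
                                         (1 - plogis(drop(X %*% beta)))), X)))
  dimnames(vcov) <- list(colnames(X), colnames(X))
  list(coefficients = setNames(beta, colnames(X)), vcov = vcov,
       iterations = it, score_norm = score_norm)
}

#' Fit a logistic regression with Wald inference
#'
#' Maximum-likelihood logistic regression via Newton / iteratively
#' reweighted least squares, converged on a score-norm tolerance of `tol`.
#' Standard errors come from the inverse observed information. Unlike
#' [stats::glm()], degenerate inputs fail loudly: a one-class outcome, a
#' rank-deficient design (error names the collinear columns) and complete or
#' quasi-complete separation (diverging coefficients) are explicit errors.
#' `firth = TRUE` applies Firth's Jeffreys-prior penalty, which keeps
#' estimates finite under separation -- off by default so the estimand is
#' never changed silently.
#'
#' @param data Data frame holding the outcome and covariates.
#' @param formula Model formula; the response must be 0/1.
#' @param firth Apply Firth penalization.
#' @param tol Score-norm convergence tolerance.
#' @param maxit Maximum Newton iterations.
#' @return An object of class `mr_fit`; see [tidy.mr_fit()] /
#'   [glance.mr_fit()].
#' @export
#' @examples
#' d <- data.frame(y = rep(c(1, 0, 1, 0), c(30, 70, 10, 90)),
#'                 x = rep(c(1, 1, 0, 0), c(30, 70, 10, 90)))
#' tidy(fit_logistic(d, y ~ x))  # logOR = log(30*90/(70*10))
fit_logistic <- function(data, formula, firth = FALSE, tol = 1e-8,
                         maxit = 100) {
  mf <- stats::model.frame(formula, data = data, na.action = stats::na.fail)
  y <- stats::model.response(mf)
  if (!all(y %in% c(0, 1))) {
    abort("Outcome must be coded 0/1.", class = "duomr_validation_error")
  }
  if (length(unique(y)) < 2) {
    abort("Outcome has a single class; logistic model is undefined.",
          class = "duomr_validation_error")
  }
  X <- stats::model.matrix(formula, mf)
  fit <- logistic_irls(X, y, tol = tol, maxit = maxit, firth = firth)
  structure(list(coefficients = fit$coefficients, vcov = fit$vcov,
                 n = length(y), n_cases = sum(y),
                 iterations = fit$iterations, score_norm = fit$score_norm,
                 firth = firth, formula = formula, model = "LOGISTIC"),
            class = "mr_fit")
}

#' @export
print.mr_fit <- function(x, ...) {
  cat(sprintf("<mr_fit> %s, n = %d (%d cases)\n", x$model, x$n, x$n_cases))
  print(tidy(x))
  invisible(x)
}

mr_fit_tidy_tbl <- function(x) {
  est <- x$coefficients
  se <- sqrt(diag(x$vcov))
  z <- est / se
  tibble::tibble(
    term = names(est),
    estimate = unname(est),
    std.error = unname(se),
    statistic = unname(z),
    p.value = unname(2 * pnorm(-abs(z))),
    or = exp(unname(est)),
    or_ci_low = exp(unname(est - 1.96 * se)),
    or_ci_high = exp(unname(est + 1.96 * se))
  )
}

#' Tidy and summarize fitted association models
#'
#' `tidy()` returns one row per model term with the log odds ratio
#' (`estimate`), Wald standard error, z statistic, two-sided p-value and the
#' odds-ratio scale estimate with its 95% Wald interval
#' (`exp(estimate +/- 1.96 * std.error)`). `glance()` returns one row of
#' model-level summaries.
#'
#' @param x An `mr_fit`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy mr_fit
#' @export
tidy.mr_fit <- function(x, ...) mr_fit_tidy_tbl(x)

#' @rdname tidy.mr_fit
#' @method glance mr_fit
#' @export
glance.mr_fit <- function(x, ...) {
  tibble::tibble(n = x$n, n_cases = x$n_cases, iterations = x$iterations,
                 score_norm = x$score_norm, firth = x$firth)
}

#' Build parent-child analysis pairs from a cohort
#'
#' One row per (parent, child) duo with ids, the child's sex and age, and
#' the parent's age -- the unit of analysis for the mother-child and
#' father-child association models.
#'
#' @param cohort A `family_cohort`.
#' @param parent `"mother"` or `"father"`.
#' @return A tibble: `family_id`, `parent_id`, `child_id`, `child_sex`,
#'   `child_age`, `parent_age`.
#' @export
family_pairs <- function(cohort, parent = c("mother", "father")) {
  parent <- match.arg(parent)
  stopifnot(inherits(cohort, "family_cohort"))
  children <- dplyr::filter(cohort$members, .data$role == "CHILD")
  pid <- if (parent == "mother") children$mother_id else children$father_id
  parents <- cohort$members[match(pid, cohort$members$individual_id), ]
  tibble::tibble(
    family_id = children$family_id,
    parent_id = pid,
    child_id = children$individual_id,
    child_sex = children$sex,
    child_age = children$age,
    parent_age = parents$age
  )
}

#' Assemble a pair-level modelling table
#'
#' Joins standardized scores and child phenotypes onto parent-child pairs,
#' producing the one-row-per-pair table consumed by [mr_triplet()]:
#' `pgs_parent` is the parent's score, `pgs_child` the child's score for the
#' same score definition, plus every phenotype column of the child.
#'
#' @param cohort A `family_cohort`.
#' @param scores Long standardized score tibble from [compute_scores()].
#' @param phenotypes Child phenotype tibble (e.g. from [assign_disease()]).
#' @param score Score name to use.
#' @param parent `"mother"` or `"father"`.
#' @return A pair-level tibble.
#' @export
pair_data <- function(cohort, scores, phenotypes = NULL,
                      score = "M-SPECIFIC",
                      parent = c("mother", "father")) {
  pairs <- family_pairs(cohort, parent)
  sc <- dplyr::filter(scores, .data$score == .env$score)
  if (nrow(sc) == 0) abort(sprintf("Score %s not found in `scores`.", score))
  val <- setNames(sc$value, sc$individual_id)
  pairs$pgs_parent <- unname(val[pairs$parent_id])
  pairs$pgs_child <- unname(val[pairs$child_id])
  if (!is.null(phenotypes)) {
    pheno <- dplyr::select(phenotypes, -dplyr::any_of(
      c("family_id", "mother_id", "father_id", "sex", "age",
        "pgs_mother", "pgs_child", "pgs_parent")))
    pairs <- dplyr::left_join(pairs, pheno,
                              by = c(child_id = "individual_id"))
  }
  pairs
}

#' Fit the within-family MR model triplet
#'
#' Fits three logistic regressions of the child's binary outcome on
#' identical rows: parent's PGS only (`PARENT_ONLY`), child's PGS only
#' (`CHILD_ONLY`), and both jointly (`JOINT`). Conditioning on the child's
#' score in the joint model blocks the transmission path that otherwise
#' violates the MR exclusion restriction: under a purely fetal
#' (pleiotropic) effect the parent-only estimate reflects roughly half the
#' child effect (the parent-child score correlation), while the joint
#' parent estimate goes to zero; under a true maternal (intrauterine)
#' effect the parent estimate is unchanged by the adjustment. The
#' attenuation report quantifies this contrast.
#'
#' @param data One row per pair, with the outcome, `pgs_parent`,
#'   `pgs_child` and any covariates.
#' @param outcome Name of the 0/1 outcome column.
#' @param pgs_parent,pgs_child Names of the standardized score columns.
#' @param covariates Character vector of covariate column names included in
#'   all three models (e.g. child age, principal components, batch).
#' @param boot_reps Pair-resampling bootstrap draws for the attenuation
#'   ratio's percentile CI; 0 (default) skips the bootstrap.
#' @param firth Passed to [fit_logistic()].
#' @param seed Seed for the bootstrap.
#' @return An object of class `mr_triplet`: `tidy()` gives the term-level
#'   association table across the three models, `glance()` the attenuation
#'   report (`parent_logOR_unadjusted`, `parent_logOR_joint`,
#'   `child_logOR_joint`, `attenuation_ratio` and bootstrap CI when
#'   requested).
#' @export
mr_triplet <- function(data, outcome, pgs_parent = "pgs_parent",
                       pgs_child = "pgs_child", covariates = NULL,
                       boot_reps = 0, firth = FALSE, seed = NULL) {
  data <- tibble::as_tibble(data)
  need <- c(outcome, pgs_parent, pgs_child, covariates)
  missing <- setdiff(need, names(data))
  if (length(missing) > 0) {
    abort(sprintf("Column(s) not in data: %s.", paste(missing, collapse = ", ")))
  }
  data <- data[complete.cases(data[need]), ]
  cov_rhs <- if (length(covariates)) paste(c("", sprintf("`%s`", covariates)),
                                           collapse = " + ") else ""
  form <- function(terms) {
    stats::as.formula(sprintf("`%s` ~ %s%s", outcome,
                              paste(sprintf("`%s`", terms), collapse = " + "),
                              cov_rhs))
  }
  fits <- list(
    PARENT_ONLY = fit_logistic(data, form(pgs_parent), firth = firth),
    CHILD_ONLY = fit_logistic(data, form(pgs_child), firth = firth),
    JOINT = fit_logistic(data, form(c(pgs_parent, pgs_child)), firth = firth)
  )
  label_term <- function(term) {
    term <- gsub("`", "", term)
    dplyr::case_when(term == pgs_parent ~ "PARENT_PGS",
                     term == pgs_child ~ "CHILD_PGS",
                     TRUE ~ term)
  }
  results <- purrr::imap(fits, function(f, nm) {
    dplyr::mutate(tidy(f), model = nm, term = label_term(.data$term),
                  n = f$n, n_cases = f$n_cases)
  }) %>% dplyr::bind_rows()

  get_est <- function(model, term) {
    results$estimate[results$model == model & results$term == term]
  }
  att <- list(
    parent_logOR_unadjusted = get_est("PARENT_ONLY", "PARENT_PGS"),
    parent_logOR_joint = get_est("JOINT", "PARENT_PGS"),
    child_logOR_joint = get_est("JOINT", "CHILD_PGS")
  )
  att$attenuation_ratio <-
    if (att$parent_logOR_unadjusted != 0) {
      att$parent_logOR_joint / att$parent_logOR_unadjusted
    } else {
      NA_real_
    }
  if (boot_reps > 0) {
    set_seed_if(seed)
    ratios <- purrr::map_dbl(seq_len(boot_reps), function(i) {
      idx <- sample.int(nrow(data), replace = TRUE)
      d <- data[idx, ]
      f1 <- tryCatch(fit_logistic(d, form(pgs_parent), firth = firth),
                     error = function(e) NULL)
      f2 <- tryCatch(fit_logistic(d, form(c(pgs_parent, pgs_child)),
                                  firth = firth), error = function(e) NULL)
      if (is.null(f1) || is.null(f2)) return(NA_real_)
      # parent term sits right after the intercept in both designs
      unname(f2$coefficients[2] / f1$coefficients[2])
    })
    qs <- quantile(ratios, c(0.025, 0.975), na.rm = TRUE)
    att$attenuation_ci_low <- unname(qs[1])
    att$attenuation_ci_high <- unname(qs[2])
    att$boot_reps <- boot_reps
  }
  structure(list(results = results, attenuation = att, fits = fits,
                 outcome = outcome, n = fits$JOINT$n,
                 n_cases = fits$JOINT$n_cases),
            class = "mr_triplet")
}

#' @export
print.mr_triplet <- function(x, ...) {
  cat(sprintf("<mr_triplet> outcome `%s`, n = %d (%d cases)\n",
              x$outcome, x$n, x$n_cases))
  print(dplyr::filter(tidy(x), .data$term %in% c("PARENT_PGS", "CHILD_PGS")))
  cat(sprintf("attenuation ratio (joint/unadjusted parent logOR): %.3f\n",
              x$attenuation$attenuation_ratio))
  invisible(x)
}

#' @rdname mr_triplet
#' @param x An `mr_triplet`.
#' @param ... Unused.
#' @method tidy mr_triplet
#' @export
tidy.mr_triplet <- function(x, ...) x$results

#' @rdname mr_triplet
#' @method glance mr_triplet
#' @export
glance.mr_triplet <- function(x, ...) {
  tibble::as_tibble(x$attenuation[!purrr::map_lgl(x$attenuation, is.null)])
}

#' Filter parent-child pairs to independent sets
#'
#' `one_child_per_mother` keeps the oldest child of each parent.
#' `max_4th_degree` additionally enforces that no two retained individuals
#' are related closer than 4th degree; in simulated cohorts relatedness only
#' arises within a family, so this keeps a single pair per family -- the
#' oldest parent's oldest child. Both filters are deterministic given ages
#' (ties broken by id).
#'
#' @param pairs Pair tibble from [family_pairs()] or [pair_data()].
#' @param mode Filtering rule.
#' @return The filtered pair tibble.
#' @export
select_independent_pairs <- function(pairs,
                                     mode = c("one_child_per_mother",
                                              "max_4th_degree")) {
  mode <- match.arg(mode)
  pairs <- tibble::as_tibble(pairs)
  key <- if (mode == "one_child_per_mother") "parent_id" else "family_id"
  pairs %>%
    dplyr::arrange(dplyr::desc(.data$child_age), .data$child_id) %>%
    dplyr::distinct(dplyr::across(dplyr::all_of(key)), .keep_all = TRUE) %>%
    dplyr::arrange(.data$family_id, .data$child_id)
}

#' Append an extra polygenic score as a covariate
#'
#' Adds one standardized score (e.g. a gestational-length PGS) as a covariate
#' column, joined by individual id, for use in the `covariates` argument of
#' [mr_triplet()].
#'
#' @param data Pair-level tibble.
#' @param scores Long score tibble.
#' @param score Which score to append.
#' @param by Column of `data` holding the individual id to join on.
#' @param name Column name to create; defaults to the score name.
#' @return `data` with the new column.
#' @export
add_covariate_score <- function(data, scores, score, by = "child_id",
                                name = score) {
  if (name %in% names(data)) {
    abort(sprintf("Column `%s` already exists.", name),
          class = "duomr_validation_error")
  }
  sc <- dplyr::filter(scores, .data$score == .env$score)
  if (nrow(sc) == 0) abort(sprintf("Score %s not found.", score))
  val <- setNames(sc$value, sc$individual_id)
  data[[name]] <- unname(val[data[[by]]])
  data
}

#' Structural stand-in covariates for simulated analyses
#'
#' Adds the covariate structure used alongside real-data association models:
#' `n_pcs` standard-normal noise columns (principal-component surrogates --
#' the generator produces no population structure) and a categorical
#' genotyping `batch` with uniformly random levels.
#'
#' @param data Tibble to extend.
#' @param n_pcs Number of noise PC columns.
#' @param n_batches Number of batch levels.
#' @param seed Optional integer seed.
#' @return `data` with columns `PC1..PCk` and `batch`.
#' @export
add_noise_covariates <- function(data, n_pcs = 10, n_batches = 5,
                                 seed = NULL) {
  set_seed_if(seed)
  n <- nrow(data)
  for (j in seq_len(n_pcs)) data[[paste0("PC", j)]] <- rnorm(n)
  data$batch <- factor(sample(paste0("b", seq_len(n_batches)), n,
                              replace = TRUE))
  data
}
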