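#' Simulate one mother-child pair scenario dataset
#'
#' Draws `n_pairs` standardized mother/child PGS pairs from the bivariate
#' normal (means 0, variances 1, correlation `rho`), computes each child's
#' disease risk from the logistic risk function with the intercept
#' calibrated so the expected risk equals `prevalence`, and samples case
#' status Bernoulli(risk). This is the data-generating step shared by the
#' power simulations and the large-sample model-property checks.
#'
#' @param n_pairs Number of mother-child pairs.
#' @param beta_mother,beta_child True log odds ratios per SD of the
#'   mother's / child's PGS.
#' @param prevalence Target case fraction in (0, 1).
#' @param rho Mother-child PGS correlation.
#' @param seed Optional integer seed.
#' @return A tibble: `pgs_mother`, `pgs_child`, `risk`, `case`.
#' @export
simulate_pair_scenario <- function(n_pairs, beta_mother = 0, beta_child = 0,
                                   prevalence, rho = 0.5, seed = NULL) {
  set_seed_if(seed)
  d <- sample_pgs_pairs(n_pairs, rho = rho)
  scn <- disease_scenario(beta_mother, beta_child, prevalence,
                          mediation = "direct_pgs", rho = rho)
  assign_disease(d, scn)
}

#' One power-simulation replicate
#'
#' Executes the four-step procedure once: (1) sample `n_pairs`
#' bivariate-normal PGS pairs (means 0, variances 1, correlation `rho`);
#' (2) build the logistic risk with the intercept calibrated to the target
#' prevalence; (3) draw Bernoulli case status; (4) regress status jointly on
#' the mother's and child's PGSs and record the Wald p-values of both
#' terms.
#'
#' @inheritParams simulate_pair_scenario
#' @param on_degenerate What to do when the sampled outcome has a single
#'   class (vanishingly rare at realistic prevalences): `"error"` (default)
#'   or `"resample"` with fresh draws.
#' @return A one-row tibble: estimates, standard errors and p-values for
#'   both PGS terms, plus the realized case count.
#' @export
simulate_once <- function(n_pairs, beta_mother = 0, beta_child = 0,
                          prevalence, rho = 0.5, seed = NULL,
                          on_degenerate = c("error", "resample")) {
  on_degenerate <- match.arg(on_degenerate)
  n_pairs <- assert_count(n_pairs, "n_pairs", min = 100)
  assert_scalar_prob(prevalence, "prevalence")
  set_seed_if(seed)
  alpha <- calibrate_intercept(beta_mother, beta_child, prevalence, rho)
  repeat {
    z <- mvtnorm::rmvnorm(n_pairs, sigma = matrix(c(1, rho, rho, 1), 2))
    risk <- plogis(alpha + beta_mother * z[, 1] + beta_child * z[, 2])
    y <- rbinom(n_pairs, 1L, risk)
    s <- sum(y)
    if (s > 0 && s < n_pairs) break
    if (on_degenerate == "error") {
      abort("Sampled outcome is degenerate (all cases or all controls).",
            class = "duomr_validation_error")
    }
  }
  X <- cbind(`(Intercept)` = 1, pgs_mother = z[, 1], pgs_child = z[, 2])
  fit <- logistic_irls(X, y)
  se <- sqrt(diag(fit$vcov))
  zst <- fit$coefficients / se
  p <- 2 * pnorm(-abs(zst))
  tibble::tibble(
    est_mother = fit$coefficients[["pgs_mother"]],
    est_child = fit$coefficients[["pgs_child"]],
    se_mother = se[["pgs_mother"]], se_child = se[["pgs_child"]],
    p_mother = p[["pgs_mother"]], p_child = p[["pgs_child"]],
    n_cases = s
  )
}

#' Estimate power of the joint mother+child model by simulation
#'
#' Runs `reps` independent replicates of [simulate_once()] and reports, for
#' each PGS term, the fraction of replicates with Wald p below `alpha` --
#' the simulated power -- together with its binomial Monte-Carlo standard
#' error `sqrt(power * (1 - power) / reps)`. Per-replicate seeds are derived
#' from `seed` by a counter scheme, so the result does not depend on
#' evaluation order.
#'
#' @inheritParams simulate_once
#' @param reps Number of simulation replicates (>= 100).
#' @param alpha Two-sided test level.
#' @return A one-row `power_grid` tibble: scenario parameters, `power_mother`,
#'   `power_child` and their `mc_se_*`.
#' @export
estimate_power <- function(n_pairs, beta_mother = 0, beta_child = 0,
                           prevalence, reps = 1000, alpha = 0.05,
                           rho = 0.5, seed = NULL,
                           on_degenerate = c("error", "resample")) {
  reps <- assert_count(reps, "reps", min = 100)
  assert_scalar_prob(alpha, "alpha")
  on_degenerate <- match.arg(on_degenerate)
  base <- seed %||% sample.int(.Machine$integer.max, 1)
  ps <- purrr::map(seq_len(reps), function(r) {
    simulate_once(n_pairs, beta_mother, beta_child, prevalence, rho,
                  seed = derive_seed(base, "power_rep", r),
                  on_degenerate = on_degenerate)
  }) %>% dplyr::bind_rows()
  pm <- mean(ps$p_mother < alpha)
  pc <- mean(ps$p_child < alpha)
  out <- tibble::tibble(
    beta_mother = beta_mother, beta_child = beta_child,
    or_mother = exp(beta_mother), or_child = exp(beta_child),
    prevalence = prevalence, n_pairs = n_pairs, reps = reps, alpha = alpha,
    power_mother = pm, mc_se_mother = sqrt(pm * (1 - pm) / reps),
    power_child = pc, mc_se_child = sqrt(pc * (1 - pc) / reps)
  )
  class(out) <- c("power_grid", class(out))
  out
}

#' Power over a grid of maternal/child effects
#'
#' Convenience sweep of [estimate_power()] over every combination of the
#' supplied maternal and child odds ratios.
#'
#' @inheritParams estimate_power
#' @param or_mother,or_child Odds-ratio grids (per SD of PGS).
#' @return A `power_grid` tibble, one row per combination.
#' @export
power_grid <- function(n_pairs, or_mother = 1, or_child = 1, prevalence,
                       reps = 1000, alpha = 0.05, rho = 0.5, seed = NULL) {
  combos <- tidyr::expand_grid(or_mother = or_mother, or_child = or_child)
  base <- seed %||% sample.int(.Machine$integer.max, 1)
  out <- purrr::pmap(combos, function(or_mother, or_child) {
    estimate_power(n_pairs, log(or_mother), log(or_child), prevalence,
                   reps = reps, alpha = alpha, rho = rho,
                   seed = derive_seed(base, "grid",
                                      round(or_mother * 1e6 + or_child * 1e3)))
  }) %>% dplyr::bind_rows()
  class(out) <- c("power_grid", class(out))
  out
}

#' Minimum detectable maternal odds ratio
#'
#' Finds the smallest odds ratio on the grid `1 + k * grid_step` at which
#' the joint model's simulated power for the maternal term reaches
#' `target_power`. Power is monotone non-decreasing in the odds ratio, so
#' the grid is searched by bisection; each evaluated point is returned with
#' its Monte-Carlo standard error, and the reported boundary should be read
#' with the MC uncertainty of the bracketing points in mind.
#'
#' @inheritParams estimate_power
#' @param beta_child Fixed true child effect (logOR per SD); 0 by default.
#' @param target_power Power to reach, in (0, 1).
#' @param grid_step Grid resolution on the OR scale.
#' @param or_max Largest OR considered.
#' @return A list of class `mdor`: `or` (the boundary), `power` at the
#'   boundary, and `evaluations`, a `power_grid` tibble of every grid point
#'   assessed.
#' @export
min_detectable_or <- function(n_pairs, prevalence, beta_child = 0,
                              target_power = 0.8, grid_step = 0.01,
                              reps = 1000, alpha = 0.05, rho = 0.5,
                              or_max = 1.5, seed = NULL) {
  if (grid_step <= 0) abort("`grid_step` must be > 0.")
  assert_scalar_prob(target_power, "target_power")
  base <- seed %||% sample.int(.Machine$integer.max, 1)
  k_max <- ceiling((or_max - 1) / grid_step)
  evals <- list()
  power_at <- function(k) {
    key <- as.character(k)
    if (!is.null(evals[[key]])) return(evals[[key]])
    or <- 1 + k * grid_step
    row <- estimate_power(n_pairs, beta_mother = log(or),
                          beta_child = beta_child, prevalence = prevalence,
                          reps = reps, alpha = alpha, rho = rho,
                          seed = derive_seed(base, "mdor", k))
    evals[[key]] <<- row
    row
  }
  hi <- power_at(k_max)
  if (hi$power_mother < target_power) {
    abort(sprintf(
      "Power %.3f at OR %.2f (grid maximum) is below target %.2f; raise `or_max`.",
      hi$power_mother, 1 + k_max * grid_step, target_power),
      class = "duomr_validation_error")
  }
  lo_k <- 1L
  lo <- power_at(lo_k)
  if (lo$power_mother >= target_power) {
    hit_k <- lo_k
  } else {
    # bisection on the grid index; power is monotone in the OR
    lo_b <- lo_k
    hi_b <- k_max
    while (hi_b - lo_b > 1L) {
      mid <- as.integer(floor((lo_b + hi_b) / 2))
      if (power_at(mid)$power_mother >= target_power) hi_b <- mid else lo_b <- mid
    }
    hit_k <- hi_b
  }
  ev <- dplyr::bind_rows(evals[order(as.integer(names(evals)))])
  class(ev) <- c("power_grid", class(ev))
  structure(list(or = 1 + hit_k * grid_step,
                 power = power_at(hit_k)$power_mother,
                 target_power = target_power, grid_step = grid_step,
                 reps = reps, n_pairs = n_pairs, prevalence = prevalence,
                 beta_child = beta_child, evaluations = ev),
            class = "mdor")
}

#' @export
print.mdor <- function(x, ...) {
  cat(sprintf(
    "<mdor> minimum detectable maternal OR = %.2f (power %.3f >= %.2f)\n",
    x$or, x$power, x$target_power))
  cat(sprintf("  n = %d pairs, prevalence %.4f, %d reps, grid step %.2f\n",
              x$n_pairs, x$prevalence, x$reps, x$grid_step))
  invisible(x)
}

#' @rdname min_detectable_or
#' @param x An `mdor` object.
#' @param ... Unused.
#' @method tidy mdor
#' @export
tidy.mdor <- function(x, ...) x$evaluations

#' @rdname min_detectable_or
#' @method glance mdor
#' @export
glance.mdor <- function(x, ...) {
  tibble::tibble(or = x$or, power = x$power, target_power = x$target_power,
                 grid_step = x$grid_step, reps = x$reps, n_pairs = x$n_pairs,
                 prevalence = x$prevalence, beta_child = x$beta_child)
}
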