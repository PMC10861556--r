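# Independent reference implementations used as oracles. These deliberately
# avoid the package's code paths.

# Brute-force Newton-Raphson for logistic regression with explicit
# gradient/Hessian assembly and solve() updates.
newton_logistic <- function(X, y, maxit = 200, tol = 1e-12) {
  beta <- rep(0, ncol(X))
  for (i in seq_len(maxit)) {
    eta <- as.numeric(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    g <- as.numeric(t(X) %*% (y - mu))
    if (max(abs(g)) < tol) break
    H <- t(X) %*% (X * (mu * (1 - mu)))
    beta <- beta + as.numeric(solve(H, g))
  }
  beta
}

# Exact 1:1 matched conditional log-likelihood, maximised by golden-section
# search via optimize().
clogit_grid_oracle <- function(pgs_case, pgs_control, lower = -5, upper = 5) {
  d <- pgs_case - pgs_control
  ll <- function(b) sum(b * d - log1p(exp(b * d)))
  stats::optimize(ll, c(lower, upper), maximum = TRUE, tol = 1e-10)$maximum
}

# Pair-level scenario table and standardized M-SPECIFIC scores for a cohort;
# shared by several tests.
build_scored_cohort <- function(n_families, n_snps = 100, n_children = 1,
                                seed = 1) {
  panel <- simulate_panel(n_snps, seed = seed)
  cohort <- simulate_families(panel, n_families, n_children = n_children,
                              seed = seed + 1)
  scores <- suppressMessages(
    compute_scores(cohort, scores = c("M-SPECIFIC", "F-SPECIFIC")))
  list(panel = panel, cohort = cohort, scores = scores)
}
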