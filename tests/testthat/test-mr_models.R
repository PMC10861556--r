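test_that("logistic fit recovers the closed-form 2x2 odds ratio", {
  d <- data.frame(y = rep(c(1, 0, 1, 0), c(30, 70, 10, 90)),
                  x = rep(c(1, 1, 0, 0), c(30, 70, 10, 90)))
  fit <- fit_logistic(d, y ~ x)
  expect_equal(unname(fit$coefficients["x"]), log(30 * 90 / (70 * 10)),
               tolerance = 1e-8)
  # Wald CI invariant: or_ci95 = exp(logOR +/- 1.96 se)
  td <- tidy(fit)
  expect_equal(td$or_ci_low, exp(td$estimate - 1.96 * td$std.error))
  expect_equal(td$or_ci_high, exp(td$estimate + 1.96 * td$std.error))
})

test_that("fitter matches Newton oracle and glm on random small datasets", {
  set.seed(404)
  for (i in 1:10) {
    n <- sample(60:200, 1)
    X <- cbind(1, matrix(rnorm(n * 3), n, 3))
    colnames(X) <- c("(Intercept)", "a", "b", "c")
    beta <- c(-0.5, runif(3, -0.8, 0.8))
    y <- rbinom(n, 1, plogis(X %*% beta))
    if (sum(y) < 5 || sum(y) > n - 5) next
    d <- data.frame(y = y, a = X[, 2], b = X[, 3], c = X[, 4])
    fit <- fit_logistic(d, y ~ a + b + c)
    expect_equal(unname(fit$coefficients), newton_logistic(X, y),
                 tolerance = 1e-6)
    ref <- stats::glm(y ~ a + b + c, data = d, family = binomial(),
                      control = list(epsilon = 1e-12))
    expect_equal(unname(fit$coefficients), unname(coef(ref)),
                 tolerance = 1e-6)
    expect_equal(unname(sqrt(diag(fit$vcov))),
                 unname(sqrt(diag(vcov(ref)))), tolerance = 1e-5)
  }
})

test_that("degenerate designs raise explicit errors", {
  # single-class outcome
  d <- data.frame(y = rep(1, 50), x = rnorm(50))
  expect_error(fit_logistic(d, y ~ x), "single class",
               class = "duomr_validation_error")
  # complete separation
  d2 <- data.frame(y = rep(c(0, 1), each = 25), x = c(rnorm(25), rnorm(25) + 30))
  expect_error(fit_logistic(d2, y ~ x), "separation",
               class = "duomr_separation_error")
  # Firth penalization keeps the separated fit finite
  ff <- fit_logistic(d2, y ~ x, firth = TRUE)
  expect_true(is.finite(ff$coefficients["x"]))
  # rank deficiency names the collinear column
  d3 <- data.frame(y = rbinom(100, 1, 0.4), x = rnorm(100))
  d3$x2 <- d3$x
  expect_error(fit_logistic(d3, y ~ x + x2), "x2",
               class = "duomr_rank_error")
})

test_that("null association gives near-zero slope at large n", {
  set.seed(77)
  d <- data.frame(y = rbinom(20000, 1, 0.2), x = rnorm(20000))
  fit <- tidy(fit_logistic(d, y ~ x))
  expect_lt(abs(fit$estimate[2]), 3 * fit$std.error[2])
})

test_that("triplet shows attenuation under a pure fetal effect", {
  d <- simulate_pair_scenario(150000, beta_mother = 0,
                              beta_child = log(0.87),
                              prevalence = 0.0275, seed = 501)
  tri <- mr_triplet(d, outcome = "case", pgs_parent = "pgs_mother",
                    pgs_child = "pgs_child")
  td <- tidy(tri)
  po <- td[td$model == "PARENT_ONLY" & td$term == "PARENT_PGS", ]
  jp <- td[td$model == "JOINT" & td$term == "PARENT_PGS", ]
  jc <- td[td$model == "JOINT" & td$term == "CHILD_PGS", ]
  expect_lt(abs(po$estimate - 0.5 * log(0.87)), 3 * po$std.error)
  expect_lt(abs(jp$estimate), 3 * jp$std.error)
  expect_lt(abs(jc$estimate - log(0.87)), 3 * jc$std.error)
  g <- glance(tri)
  expect_equal(g$attenuation_ratio,
               g$parent_logOR_joint / g$parent_logOR_unadjusted)
})

test_that("pure maternal effects are invariant to child-score adjustment", {
  d <- simulate_pair_scenario(150000, beta_mother = log(1.2),
                              beta_child = 0, prevalence = 0.1, seed = 502)
  tri <- mr_triplet(d, outcome = "case", pgs_parent = "pgs_mother",
                    pgs_child = "pgs_child")
  td <- tidy(tri)
  po <- td[td$model == "PARENT_ONLY" & td$term == "PARENT_PGS", ]
  jp <- td[td$model == "JOINT" & td$term == "PARENT_PGS", ]
  expect_lt(abs(jp$estimate - po$estimate),
            3 * sqrt(po$std.error^2 + jp$std.error^2))
})

test_that("covariates and extra scores behave under the joint model", {
  d <- simulate_pair_scenario(20000, beta_mother = 0, beta_child = log(0.8),
                              prevalence = 0.1, seed = 503)
  d <- add_noise_covariates(d, n_pcs = 3, n_batches = 3, seed = 504)
  tri0 <- mr_triplet(d, outcome = "case", pgs_parent = "pgs_mother",
                     pgs_child = "pgs_child")
  tri1 <- mr_triplet(d, outcome = "case", pgs_parent = "pgs_mother",
                     pgs_child = "pgs_child",
                     covariates = c("PC1", "PC2", "PC3", "batch"))
  e0 <- tidy(tri0)
  e1 <- tidy(tri1)
  jc0 <- e0[e0$model == "JOINT" & e0$term == "CHILD_PGS", ]
  jc1 <- e1[e1$model == "JOINT" & e1$term == "CHILD_PGS", ]
  expect_lt(abs(jc0$estimate - jc1$estimate), 2 * jc0$std.error)
  # duplicating the maternal score is a rank error
  d$dup <- d$pgs_mother
  expect_error(mr_triplet(d, outcome = "case", pgs_parent = "pgs_mother",
                          pgs_child = "pgs_child", covariates = "dup"),
               class = "duomr_rank_error")
})

test_that("bootstrap attenuation CI brackets the point estimate", {
  d <- simulate_pair_scenario(4000, beta_mother = 0, beta_child = log(0.6),
                              prevalence = 0.2, seed = 505)
  tri <- mr_triplet(d, outcome = "case", pgs_parent = "pgs_mother",
                    pgs_child = "pgs_child", boot_reps = 50, seed = 506)
  g <- glance(tri)
  expect_true(g$attenuation_ci_low <= g$attenuation_ci_high)
  expect_equal(g$boot_reps, 50)
})

test_that("independent-pair filters keep the oldest child deterministically", {
  members <- tibble::tibble(
    family_id = c("f1", "f1", "f1", "f1", "f1", "f2", "f2", "f2"),
    individual_id = c("f1_M", "f1_F", "k1", "k2", "k3", "f2_M", "f2_F", "k4"),
    role = c("MOTHER", "FATHER", "CHILD", "CHILD", "CHILD",
             "MOTHER", "FATHER", "CHILD"),
    sex = c("F", "M", "F", "M", "M", "F", "M", "F"),
    age = c(70, 72, 40, 45, 38, 66, 67, 30),
    mother_id = c(NA, NA, "f1_M", "f1_M", "f1_M", NA, NA, "f2_M"),
    father_id = c(NA, NA, "f1_F", "f1_F", "f1_F", NA, NA, "f2_F"))
  cohort <- structure(list(members = members), class = "family_cohort")
  pairs <- family_pairs(cohort, "mother")
  kept <- select_independent_pairs(pairs, "one_child_per_mother")
  expect_equal(nrow(kept), 2)
  expect_setequal(kept$child_id, c("k2", "k4"))  # oldest per mother
  expect_identical(kept, select_independent_pairs(pairs,
                                                  "one_child_per_mother"))
  # singleton families unchanged under the stricter filter
  kept2 <- select_independent_pairs(pairs, "max_4th_degree")
  expect_setequal(kept2$child_id, c("k2", "k4"))
})

test_that("add_covariate_score joins by id and rejects duplicates", {
  sc <- tibble::tibble(individual_id = c("k1", "k2"), score = "gest",
                       value = c(0.3, -0.2))
  d <- tibble::tibble(child_id = c("k1", "k2"), case = c(0, 1))
  out <- add_covariate_score(d, sc, "gest")
  expect_equal(out$gest, c(0.3, -0.2))
  expect_error(add_covariate_score(out, sc, "gest"), "already exists",
               class = "duomr_validation_error")
})

test_that("father-child pairs mirror mother-child pairs under a fetal effect", {
  sc <- build_scored_cohort(8000, n_snps = 60, seed = 808)
  ph <- assign_birthweight(sc$cohort, seed = 809)
  msp <- sc$scores[sc$scores$score == "M-SPECIFIC", ]
  val <- setNames(msp$value, msp$individual_id)
  ph$pgs_mother <- unname(val[ph$mother_id])
  ph$pgs_child <- unname(val[ph$individual_id])
  b <- log(0.8)
  ph <- assign_disease(ph, disease_scenario(0, b, prevalence = 0.15),
                       seed = 810)
  tri <- purrr::map(c("mother", "father"), function(par) {
    pairs <- pair_data(sc$cohort, sc$scores, ph, score = "M-SPECIFIC",
                       parent = par)
    tidy(mr_triplet(pairs, outcome = "case"))
  })
  jm <- lapply(tri, function(td) td[td$model == "JOINT", ])
  father_term <- jm[[2]][jm[[2]]$term == "PARENT_PGS", ]
  expect_lt(abs(father_term$estimate), 3 * father_term$std.error)
  cm <- jm[[1]][jm[[1]]$term == "CHILD_PGS", ]
  cf <- jm[[2]][jm[[2]]$term == "CHILD_PGS", ]
  expect_lt(abs(cm$estimate - cf$estimate),
            3 * sqrt(cm$std.error^2 + cf$std.error^2))
  expect_lt(abs(cf$estimate - b), 3 * cf$std.error)
})
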