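test_that("simulate_panel honours class constraints and determinism", {
  p <- simulate_panel(29, class_mix = c(M_ONLY = 1), seed = 5)
  expect_equal(nrow(p), 29)
  expect_true(all(p$effect_class == "M_ONLY"))
  expect_true(all(p$w_fetal == 0))
  expect_true(all(p$w_maternal >= 0))

  p0 <- simulate_panel(10, effect_scale = 0, seed = 5)
  expect_true(all(p0$w_maternal == 0) && all(p0$w_fetal == 0))

  expect_identical(simulate_panel(50, seed = 9), simulate_panel(50, seed = 9))
  expect_error(simulate_panel(0), "n_snps")

  # opposing-effect variants carry opposite-sign weights
  p2 <- simulate_panel(200, seed = 6)
  opp <- p2[p2$effect_class == "SHARED_OPP", ]
  expect_true(all(opp$w_maternal > 0) && all(opp$w_fetal < 0))
})

test_that("Mendelian transmission law holds locus by locus", {
  p <- simulate_panel(20, seed = 21)
  coh <- simulate_families(p, 800, seed = 22)
  G <- as.matrix(coh$dosages[-1])
  rownames(G) <- coh$dosages$individual_id
  kids <- dplyr::filter(coh$members, role == "CHILD")
  gm <- G[kids$mother_id, , drop = FALSE]
  gf <- G[kids$father_id, , drop = FALSE]
  gc <- G[kids$individual_id, , drop = FALSE]
  # attainability: child dosage bounded by forced transmissions
  lower <- (gm == 2) + (gf == 2)
  upper <- 2 - ((gm == 0) + (gf == 0))
  expect_true(all(gc >= lower & gc <= upper))
  # both parents homozygous reference -> child 0; mother homozygous effect
  # with father reference -> child exactly 1
  expect_true(all(gc[gm == 0 & gf == 0] == 0))
  expect_true(all(gc[gm == 2 & gf == 0] == 1))
  # heterozygous mother with reference father: transmitted allele is the
  # child's dosage, Bernoulli(1/2)
  sel <- gm == 1 & gf == 0
  phat <- mean(gc[sel])
  expect_lt(abs(phat - 0.5), 3 * sqrt(0.25 / sum(sel)))
})

test_that("relative correlations of scores match kinship expectations", {
  sc <- build_scored_cohort(4000, n_snps = 100, n_children = 2, seed = 31)
  msp <- sc$scores[sc$scores$score == "M-SPECIFIC", ]
  val <- setNames(msp$value, msp$individual_id)
  fam <- unique(sc$cohort$members$family_id)
  m <- val[paste0(fam, "_M")]
  f <- val[paste0(fam, "_F")]
  c1 <- val[paste0(fam, "_C1")]
  c2 <- val[paste0(fam, "_C2")]
  expect_lt(abs(cor(m, c1) - 0.5), 0.05)
  expect_lt(abs(cor(f, c1) - 0.5), 0.05)
  expect_lt(abs(cor(c1, c2) - 0.5), 0.05)
  expect_lt(abs(cor(m, f)), 0.05)  # random mating
})

test_that("assortative-mating knob induces parental score correlation", {
  p <- simulate_panel(100, seed = 41)
  coh <- simulate_families(p, 3000, parent_pgs_cor = 0.4, seed = 42)
  sc <- suppressMessages(compute_scores(coh, scores = "weighted-maternal"))
  val <- setNames(sc$value, sc$individual_id)
  fam <- unique(coh$members$family_id)
  r <- cor(val[paste0(fam, "_M")], val[paste0(fam, "_F")])
  expect_lt(abs(r - 0.4), 0.1)
})

test_that("birth weight variance partition matches the target fractions", {
  # equal-weight maternal-specific panel: slope of BW on the mother's
  # standardized score has closed form sd_g * sqrt(h2_maternal)
  panel <- tibble::tibble(
    variant_id = sprintf("v%03d", 1:50),
    effect_allele = "A",
    eaf = runif(50, 0.1, 0.5),
    effect_class = "M_ONLY",
    w_maternal = 1, w_fetal = 0)
  coh <- simulate_families(panel, 20000, seed = 51)
  ph <- assign_birthweight(coh, panel, h2_maternal = 0.05, h2_fetal = 0,
                           mean_g = 3500, sd_g = 500, seed = 52)
  sc <- suppressMessages(compute_scores(coh, panel, scores = "M-SPECIFIC"))
  val <- setNames(sc$value, sc$individual_id)
  mother_score <- val[ph$mother_id]
  fit <- stats::lm(ph$birth_weight ~ mother_score)
  slope <- unname(coef(fit)[2])
  expected <- 500 * sqrt(0.05)  # 111.8 g per SD
  expect_lt(abs(slope - expected), 3 * summary(fit)$coefficients[2, 2])

  # no genetic effect: pure noise, slope compatible with zero
  ph0 <- assign_birthweight(coh, panel, h2_maternal = 0, h2_fetal = 0,
                            seed = 53)
  fit0 <- stats::lm(ph0$birth_weight ~ mother_score)
  expect_lt(abs(coef(fit0)[2]), 3 * summary(fit0)$coefficients[2, 2])

  expect_error(assign_birthweight(coh, panel, h2_maternal = -0.1), "negative")
  expect_error(assign_birthweight(coh, panel, h2_maternal = 0.6,
                                  h2_fetal = 0.5), "< 1")
})

test_that("birth weight assignment is reproducible under a seed", {
  p <- simulate_panel(10, seed = 61)
  coh <- simulate_families(p, 100, seed = 62)
  a <- assign_birthweight(coh, seed = 63)
  b <- assign_birthweight(coh, seed = 63)
  expect_identical(a, b)
})

test_that("intercept calibration matches numerical integration", {
  # null scenario: closed form alpha = logit(prevalence)
  expect_equal(calibrate_intercept(0, 0, prevalence = 0.167),
               qlogis(0.167), tolerance = 1e-12)
  # oracle: adaptive quadrature over the standard normal
  for (prm in list(c(0.3, 0.0275), c(0.5, 0.167), c(0.1, 0.02))) {
    b <- prm[1]; prev <- prm[2]
    a <- calibrate_intercept(beta_mother = 0, beta_child = b,
                             prevalence = prev, rho = 0.5)
    mean_risk <- stats::integrate(function(z) plogis(a + b * z) * dnorm(z),
                                  -Inf, Inf, rel.tol = 1e-10)$value
    expect_lt(abs(mean_risk - prev), 1e-3)
    expect_lt(abs(mean_risk - prev), 1e-8)  # quadrature agreement is tight
  }
})

test_that("disease assignment hits the target prevalence and odds ratios", {
  n <- 30000
  d <- sample_pgs_pairs(n, rho = 0.5, seed = 71)
  scn <- disease_scenario(beta_mother = 0, beta_child = 0, prevalence = 0.167)
  out <- assign_disease(d, scn, seed = 72)
  expect_lt(abs(mean(out$case) - 0.167), 3 * sqrt(0.167 * 0.833 / n))
  # null betas give constant risk at the prevalence
  expect_equal(unique(round(out$risk, 12)), 0.167)

  # logOR definition: +1 SD of child PGS multiplies the odds by exp(beta)
  scn2 <- disease_scenario(0, log(2), prevalence = 0.1)
  out2 <- assign_disease(d, scn2, seed = 73)
  odds <- function(p) p / (1 - p)
  r1 <- plogis(qlogis(out2$risk[1]) - scn2$beta_child * out2$pgs_child[1])
  r2 <- plogis(qlogis(out2$risk[2]) - scn2$beta_child * out2$pgs_child[2])
  expect_equal(r1, r2, tolerance = 1e-12)  # residual risk identical
  expect_equal(odds(out2$risk[1]) / odds(r1), 2^out2$pgs_child[1],
               tolerance = 1e-10)
})

test_that("realized prevalence stays within 3 binomial SE across seeds", {
  n <- 5000
  prev <- 0.1
  d <- sample_pgs_pairs(n, rho = 0.5, seed = 81)
  scn <- disease_scenario(log(1.3), log(0.8), prevalence = prev)
  hits <- vapply(1:40, function(s) {
    out <- assign_disease(d, scn, seed = 1000 + s)
    abs(mean(out$case) - prev) < 3 * sqrt(prev * (1 - prev) / n)
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("bivariate PGS pair sampling has the stated moments", {
  d <- sample_pgs_pairs(36211, rho = 0.5, seed = 91)
  expect_lt(abs(cor(d$pgs_mother, d$pgs_child) - 0.5), 0.01)
  expect_lt(abs(mean(d$pgs_mother)), 0.02)
  expect_lt(abs(sd(d$pgs_child) - 1), 0.02)
  d0 <- sample_pgs_pairs(20000, rho = 0, seed = 92)
  expect_lt(abs(cor(d0$pgs_mother, d0$pgs_child)), 0.02)
  expect_identical(sample_pgs_pairs(50, seed = 3),
                   sample_pgs_pairs(50, seed = 3))
  expect_error(sample_pgs_pairs(10, rho = 1), "rho")
})

test_that("near-collinear scores inflate joint standard errors as 1/(1-rho^2)", {
  n <- 100000
  d <- sample_pgs_pairs(n, rho = 0.99, seed = 101)
  scn <- disease_scenario(0, 0, prevalence = 0.2, rho = 0.99)
  out <- assign_disease(d, scn, seed = 102)
  joint <- fit_logistic(out, case ~ pgs_mother + pgs_child)
  single <- fit_logistic(out, case ~ pgs_mother)
  vif <- (tidy(joint)$std.error[2] / tidy(single)$std.error[2])^2
  expect_equal(vif, 1 / (1 - 0.99^2), tolerance = 0.1 * 1 / (1 - 0.99^2))
})
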