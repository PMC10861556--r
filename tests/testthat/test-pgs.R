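tiny_panel <- function(n = 3, class = "M_ONLY", wm = 1, wf = 0) {
  tibble::tibble(variant_id = paste0("v", seq_len(n)),
                 effect_allele = "A", eaf = seq(0.2, 0.4, length.out = n),
                 effect_class = class, w_maternal = wm, w_fetal = wf)
}

test_that("unweighted score is the effect-allele count", {
  p <- tiny_panel(3)
  d <- tibble::tibble(individual_id = c("a", "b"),
                      v1 = c(2, 2), v2 = c(1, 2), v3 = c(0, 2))
  s <- unweighted_score(d, p)
  expect_equal(s$value[s$individual_id == "a"], 3)
  expect_equal(s$value[s$individual_id == "b"], 2 * 3)  # 2k for k SNPs
  expect_equal(attr(s, "n_variants_used"), 3)
  expect_error(unweighted_score(d, p[0, ]), "no variants|Empty")
})

test_that("weighted score reduces to unweighted and is linear in weights", {
  p <- tiny_panel(3, class = "SHARED_CONC", wm = 1, wf = 1)
  d <- tibble::tibble(individual_id = c("a", "b"),
                      v1 = c(2, 0), v2 = c(1, 1), v3 = c(0, 2))
  expect_equal(weighted_score(d, p, "maternal")$value,
               unweighted_score(d, p)$value)
  p2 <- p
  p2$w_maternal <- -p2$w_maternal
  expect_equal(weighted_score(d, p2, "maternal")$value,
               -weighted_score(d, p, "maternal")$value)
  p1 <- tiny_panel(1, wm = 0.5)
  d1 <- tibble::tibble(individual_id = "a", v1 = 2)
  expect_equal(weighted_score(d1, p1, "maternal")$value, 1.0)
  p0 <- tiny_panel(2, wm = 0)
  expect_error(weighted_score(tibble::tibble(individual_id = "a",
                                             v1 = 1, v2 = 1),
                              p0, "maternal"), "zero")
})

test_that("raw score mean over an HWE cohort approaches 2 * sum(eaf)", {
  p <- simulate_panel(50, class_mix = c(M_ONLY = 1), seed = 7)
  coh <- simulate_families(p, 3000, seed = 8)
  s <- unweighted_score(coh$dosages, p)
  expected <- 2 * sum(p$eaf)
  v <- sum(2 * p$eaf * (1 - p$eaf))
  expect_lt(abs(mean(s$value) - expected), 3 * sqrt(v / nrow(s)))
})

test_that("standardization yields z-scores and flags degenerate input", {
  raw <- tibble::tibble(individual_id = as.character(1:100), score = "s",
                        value = rnorm(100, 10, 3))
  z <- standardize_scores(raw)
  expect_lt(abs(mean(z$value)), 1e-8)
  expect_lt(abs(sd(z$value) - 1), 1e-8)
  # location shifts do not change z-scores
  shifted <- dplyr::mutate(raw, value = value + 5)
  expect_equal(standardize_scores(shifted)$value, z$value, tolerance = 1e-12)
  const <- dplyr::mutate(raw, value = 1)
  expect_error(standardize_scores(const), "Zero-variance score\\(s\\): s",
               class = "duomr_validation_error")
})

test_that("score catalog reports subset sizes from the panel as given", {
  counts <- c(M_ONLY = 32, F_ONLY = 68, SHARED_CONC = 27, SHARED_OPP = 15,
              UNCLASSIFIED = 71)
  p <- simulate_panel(sum(counts), class_mix = counts, seed = 13)
  cat <- score_catalog(p)
  sizes <- setNames(cat$n_variants, cat$score)
  expect_equal(sizes[["M-SPECIFIC"]], 32L)
  expect_equal(sizes[["F-SPECIFIC"]], 68L)
  expect_equal(sizes[["M-ALL"]], 32L + 27L + 15L)
  expect_equal(sizes[["MF-ALL"]], sum(counts))
  expect_false(any(cat$empty))
  # all-maternal panel: fetal subset is empty and flagged
  pm <- simulate_panel(10, class_mix = c(M_ONLY = 1), seed = 14)
  catm <- score_catalog(pm)
  expect_true(catm$empty[catm$score == "F-SPECIFIC"])
})

test_that("scores are invariant to variant order in the panel", {
  sc <- build_scored_cohort(200, n_snps = 30, seed = 17)
  shuffled <- sc$panel[sample(nrow(sc$panel)), ]
  s1 <- unweighted_score(sc$cohort$dosages, sc$panel)
  s2 <- unweighted_score(sc$cohort$dosages, shuffled)
  expect_equal(s1$value, s2$value)
  w1 <- weighted_score(sc$cohort$dosages, sc$panel, "fetal")
  w2 <- weighted_score(sc$cohort$dosages, shuffled, "fetal")
  expect_equal(w1$value, w2$value, tolerance = 1e-12)
})

test_that("child score regression on the mother's recovers transmission 1/2", {
  sc <- build_scored_cohort(4000, n_snps = 80, seed = 19)
  raw <- unweighted_score(sc$cohort$dosages, sc$panel)
  val <- setNames(raw$value, raw$individual_id)
  kids <- dplyr::filter(sc$cohort$members, role == "CHILD")
  slope <- cov(val[kids$individual_id], val[kids$mother_id]) /
    var(val[kids$mother_id])
  expect_lt(abs(slope - 0.5), 0.05)
})

test_that("within-role standardization uses role-specific references", {
  sc <- build_scored_cohort(300, n_snps = 20, seed = 23)
  z <- suppressMessages(
    compute_scores(sc$cohort, scores = "M-SPECIFIC",
                   standardize = "within_role"))
  expect_true("role" %in% names(z))
  by_role <- dplyr::summarise(dplyr::group_by(z, role),
                              m = mean(value), s = sd(value))
  expect_true(all(abs(by_role$m) < 1e-8))
  expect_true(all(abs(by_role$s - 1) < 1e-8))
})
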