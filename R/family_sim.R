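#' Simulate a synthetic SNP panel
#'
#' Generates a stand-in panel of independent birth-weight variants with
#' effect-allele frequencies uniform on `[maf_low, maf_high]` and per-allele
#' weights drawn half-normal within each effect class. Class constraints are
#' enforced: maternal-specific variants get `w_fetal = 0`, fetal-specific
#' variants `w_maternal = 0`, directionally opposing variants get a negative
#' fetal weight (the effect allele is oriented to increase birth weight
#' through the maternal genome). Weights are rescaled so the theoretical
#' Hardy-Weinberg variance of each weighted genetic component (maternal and
#' fetal) equals `effect_scale^2`; the absolute variance fractions on birth
#' weight are set later by [assign_birthweight()].
#'
#' The default class mix follows the composition of lead-SNP birth-weight
#' panels partitioned into maternal/fetal effect classes
#' (32 : 68 : 27 : 15 : 71 for
#' M_ONLY : F_ONLY : SHARED_CONC : SHARED_OPP : UNCLASSIFIED).
#'
#' @param n_snps Number of variants (>= 1).
#' @param maf_low,maf_high Bounds for the effect-allele frequency,
#'   `0 < maf_low <= maf_high < 1`.
#' @param class_mix Named non-negative weights over the five effect classes;
#'   normalised to proportions internally.
#' @param effect_scale Standard deviation of each weighted genetic component
#'   under HWE; `0` gives an all-zero-weight (null) panel.
#' @param seed Optional integer seed.
#' @return A validated panel tibble (see [read_panel()]).
#' @export
simulate_panel <- function(n_snps,
                           maf_low = 0.05, maf_high = 0.5,
                           class_mix = c(M_ONLY = 32, F_ONLY = 68,
                                         SHARED_CONC = 27, SHARED_OPP = 15,
                                         UNCLASSIFIED = 71),
                           effect_scale = 1,
                           seed = NULL) {
  n_snps <- assert_count(n_snps, "n_snps")
  if (!(maf_low > 0 && maf_high < 1 && maf_low <= maf_high)) {
    abort("Require 0 < maf_low <= maf_high < 1.")
  }
  if (effect_scale < 0) abort("`effect_scale` must be >= 0.")
  mix <- setNames(rep(0, length(PANEL_CLASSES)), PANEL_CLASSES)
  bad <- setdiff(names(class_mix), PANEL_CLASSES)
  if (length(bad) > 0) {
    abort(sprintf("Unknown class_mix name(s): %s.", paste(bad, collapse = ", ")))
  }
  mix[names(class_mix)] <- class_mix
  if (any(mix < 0) || sum(mix) <= 0) {
    abort("`class_mix` must be non-negative with a positive sum.")
  }
  mix <- mix / sum(mix)
  set_seed_if(seed)

  # largest-remainder apportionment of classes
  raw <- mix * n_snps
  counts <- floor(raw)
  rem <- n_snps - sum(counts)
  if (rem > 0) {
    top <- order(raw - counts, decreasing = TRUE)[seq_len(rem)]
    counts[top] <- counts[top] + 1
  }
  classes <- rep(PANEL_CLASSES, times = counts)

  eaf <- runif(n_snps, maf_low, maf_high)
  wm <- abs(rnorm(n_snps))
  wf <- abs(rnorm(n_snps))
  wm[classes == "F_ONLY"] <- 0
  wf[classes == "M_ONLY"] <- 0
  wf[classes == "SHARED_OPP"] <- -wf[classes == "SHARED_OPP"]

  # scale each component to the requested HWE standard deviation
  v_locus <- 2 * eaf * (1 - eaf)
  for (w in c("wm", "wf")) {
    ww <- get(w)
    tot <- sum(ww^2 * v_locus)
    scl <- if (tot > 0) effect_scale / sqrt(tot) else 0
    assign(w, ww * scl)
  }
  if (effect_scale == 0) {
    wm[] <- 0
    wf[] <- 0
  }

  panel <- tibble::tibble(
    variant_id = sprintf("snp%04d", seq_len(n_snps)),
    effect_allele = sample(c("A", "C", "G", "T"), n_snps, replace = TRUE),
    eaf = eaf,
    effect_class = classes,
    w_maternal = wm,
    w_fetal = wf
  )
  validate_panel(panel)
}

#' Simulate genotyped nuclear families
#'
#' Parental genotypes are drawn per locus as Binomial(2, eaf) (Hardy-Weinberg
#' equilibrium, random mating) and each child allele is drawn uniformly from
#' the corresponding parent's two alleles, independently across loci --
#' Mendelian transmission, so a child shares 50% of variants with each
#' parent in expectation. Loci are independent (no linkage disequilibrium).
#'
#' With `n_children = 2` each family carries a full-sibling pair for the
#' discordant-sibling analyses. The optional `parent_pgs_cor` knob re-pairs
#' fathers to mothers by Gaussian-copula rank coupling on their weighted
#' maternal scores, emulating assortative mating; the achieved parental
#' score correlation is approximate.
#'
#' @param panel A validated SNP panel.
#' @param n_families Number of families (>= 1).
#' @param n_children Children per family (1 or 2).
#' @param parent_pgs_cor Target correlation between the parents' weighted
#'   maternal scores (0 = random mating, the default).
#' @param child_age_mean,child_age_sd Normal age distribution for children,
#'   truncated at 18 years; used only as a covariate downstream.
#' @param seed Optional integer seed.
#' @return A `family_cohort`: list with `members` (tibble of `family_id`,
#'   `individual_id`, `role`, `sex`, `age`, `mother_id`, `father_id`) and
#'   `dosages` (tibble, one column per panel variant).
#' @export
#' @examples
#' coh <- simulate_families(simulate_panel(10, seed = 1), 50, seed = 2)
#' coh
simulate_families <- function(panel, n_families, n_children = 1,
                              parent_pgs_cor = 0,
                              child_age_mean = 46.3, child_age_sd = 14.2,
                              seed = NULL) {
  panel <- validate_panel(panel)
  n_families <- assert_count(n_families, "n_families")
  n_children <- assert_count(n_children, "n_children")
  if (n_children > 2) abort("`n_children` must be 1 or 2.")
  if (abs(parent_pgs_cor) >= 1) abort("`parent_pgs_cor` must be in (-1, 1).")
  set_seed_if(seed)

  m <- nrow(panel)
  n <- n_families
  eaf <- panel$eaf
  draw_parents <- function() {
    matrix(rbinom(n * m, 2L, rep(eaf, each = n)), nrow = n, ncol = m)
  }
  DM <- draw_parents()
  DF <- draw_parents()

  if (parent_pgs_cor != 0) {
    w <- if (any(panel$w_maternal != 0)) panel$w_maternal else rep(1, m)
    sm <- as.numeric(DM %*% w)
    sf <- as.numeric(DF %*% w)
    # couple father ranks to a noisy copy of the mother's score rank
    latent <- parent_pgs_cor * scale(sm)[, 1] +
      sqrt(1 - parent_pgs_cor^2) * rnorm(n)
    DF <- DF[order(sf)[rank(latent, ties.method = "first")], , drop = FALSE]
  }

  transmit <- function(D) {
    het <- matrix(rbinom(n * m, 1L, 0.5), nrow = n, ncol = m)
    (D == 2L) * 1L + (D == 1L) * het
  }

  fam <- sprintf("fam%05d", seq_len(n))
  rtrunc_age <- function(k, mean, sd, lower) {
    x <- rnorm(k, mean, sd)
    while (any(x < lower)) x[x < lower] <- rnorm(sum(x < lower), mean, sd)
    x
  }

  child_blocks <- vector("list", n_children)
  child_dos <- vector("list", n_children)
  for (k in seq_len(n_children)) {
    ck <- transmit(DM) + transmit(DF)
    child_dos[[k]] <- ck
    child_blocks[[k]] <- tibble::tibble(
      family_id = fam,
      individual_id = sprintf("%s_C%d", fam, k),
      role = "CHILD",
      sex = sample(c("F", "M"), n, replace = TRUE),
      age = rtrunc_age(n, child_age_mean, child_age_sd, 18),
      mother_id = sprintf("%s_M", fam),
      father_id = sprintf("%s_F", fam)
    )
  }
  children <- dplyr::bind_rows(child_blocks)
  parent_age <- children$age[seq_len(n)] + rtrunc_age(n, 27, 4, 16)

  members <- dplyr::bind_rows(
    tibble::tibble(family_id = fam, individual_id = sprintf("%s_M", fam),
                   role = "MOTHER", sex = "F", age = parent_age,
                   mother_id = NA_character_, father_id = NA_character_),
    tibble::tibble(family_id = fam, individual_id = sprintf("%s_F", fam),
                   role = "FATHER", sex = "M",
                   age = parent_age + rnorm(n, 2, 3),
                   mother_id = NA_character_, father_id = NA_character_),
    children
  )

  dos <- rbind(DM, DF, do.call(rbind, child_dos))
  dosages <- tibble::as_tibble(as.data.frame(dos))
  names(dosages) <- panel$variant_id
  dosages <- dplyr::bind_cols(
    tibble::tibble(individual_id = members$individual_id), dosages)

  structure(list(members = members, dosages = dosages, panel = panel),
            class = "family_cohort")
}

#' @export
print.family_cohort <- function(x, ...) {
  n_fam <- dplyr::n_distinct(x$members$family_id)
  n_child <- sum(x$members$role == "CHILD")
  cat(sprintf(
    "<family_cohort> %d families, %d individuals (%d children), %d variants\n",
    n_fam, nrow(x$members), n_child,
    ncol(x$dosages) - 1L))
  invisible(x)
}

#' Assign birth weight with partitioned maternal and fetal genetic effects
#'
#' A child's birth weight is built as
#' `sum(w_maternal * G_mother) + sum(w_fetal * G_child) + noise`,
#' with the two genetic components standardized empirically and mixed so
#' they explain `h2_maternal` and `h2_fetal` of the phenotypic variance, then
#' rescaled to `mean_g` / `sd_g` grams. The maternal component acts through
#' the mother's genotype only, emulating an intrauterine-growth effect; the
#' fetal component acts through the child's own genotype.
#'
#' @param cohort A `family_cohort`.
#' @param panel Panel providing the weights; defaults to the cohort's panel.
#' @param h2_maternal,h2_fetal Variance fractions in `[0, 1)` with
#'   `h2_maternal + h2_fetal < 1`.
#' @param mean_g,sd_g Target mean and SD of birth weight in grams.
#' @param seed Optional integer seed.
#' @return A phenotype tibble for the children: `individual_id`,
#'   `family_id`, `mother_id`, `father_id`, `sex`, `age`, `birth_weight`.
#' @export
assign_birthweight <- function(cohort, panel = NULL,
                               h2_maternal = 0.02, h2_fetal = 0.05,
                               mean_g = 3500, sd_g = 500, seed = NULL) {
  stopifnot(inherits(cohort, "family_cohort"))
  panel <- validate_panel(panel %||% cohort$panel)
  if (h2_maternal < 0 || h2_fetal < 0) {
    abort("Variance fractions must be non-negative.")
  }
  if (h2_maternal + h2_fetal >= 1) {
    abort("h2_maternal + h2_fetal must be < 1.")
  }
  set_seed_if(seed)

  children <- dplyr::filter(cohort$members, .data$role == "CHILD")
  G <- dosage_matrix(cohort$dosages)[, panel$variant_id, drop = FALSE]
  comp_m <- as.numeric(G[children$mother_id, , drop = FALSE] %*% panel$w_maternal)
  comp_f <- as.numeric(G[children$individual_id, , drop = FALSE] %*% panel$w_fetal)

  std0 <- function(x, h2) {
    if (h2 == 0) return(rep(0, length(x)))
    s <- sd(x)
    if (s == 0) abort("Requested a genetic variance fraction but the weighted component has zero variance.")
    (x - mean(x)) / s
  }
  bw_z <- sqrt(h2_maternal) * std0(comp_m, h2_maternal) +
    sqrt(h2_fetal) * std0(comp_f, h2_fetal) +
    sqrt(1 - h2_maternal - h2_fetal) * rnorm(nrow(children))

  dplyr::mutate(
    children[c("individual_id", "family_id", "mother_id", "father_id",
               "sex", "age")],
    birth_weight = mean_g + sd_g * bw_z)
}

#' Define a disease-generating scenario
#'
#' Binary disease status is generated from the logistic risk
#' `risk = plogis(alpha + beta_child * PGS_child + beta_mother * PGS_mother)`
#' with the intercept `alpha` calibrated so the expected risk equals the
#' target prevalence. Under `mediation = "via_birthweight"` the maternal
#' term is replaced by `beta_mother` per SD of the generated birth weight,
#' routing the maternal effect through intrauterine growth.
#'
#' @param beta_mother,beta_child Log odds ratios per SD of the mother's /
#'   child's PGS (or per SD of birth weight under `via_birthweight`).
#' @param prevalence Target case fraction in (0, 1).
#' @param mediation `"direct_pgs"` (disease depends on the PGSs directly) or
#'   `"via_birthweight"`.
#' @param rho Assumed mother-child PGS correlation used when calibrating the
#'   intercept for `direct_pgs` scenarios.
#' @return A `disease_scenario` list.
#' @export
disease_scenario <- function(beta_mother = 0, beta_child = 0, prevalence,
                             mediation = c("direct_pgs", "via_birthweight"),
                             rho = 0.5) {
  mediation <- match.arg(mediation)
  assert_scalar_prob(prevalence, "prevalence")
  stopifnot(is.numeric(beta_mother), is.numeric(beta_child),
            abs(rho) < 1)
  structure(list(beta_mother = beta_mother, beta_child = beta_child,
                 prevalence = prevalence, mediation = mediation, rho = rho),
            class = "disease_scenario")
}

#' Calibrate the logistic intercept to a target prevalence
#'
#' Solves `E[plogis(alpha + s * Z)] = prevalence` for `alpha` by 1-D
#' root-finding, integrating over the standard normal with Gauss-Hermite
#' quadrature. For a joint maternal + child model with standardized
#' bivariate-normal PGSs of correlation `rho`, the linear predictor minus the
#' intercept is normal with
#' `s^2 = beta_mother^2 + beta_child^2 + 2 * rho * beta_mother * beta_child`.
#' Deterministic (no simulation), so the calibration is seed-independent.
#'
#' @inheritParams disease_scenario
#' @param nodes Number of Gauss-Hermite nodes.
#' @return The intercept `alpha` (scalar).
#' @export
#' @examples
#' calibrate_intercept(0, 0, prevalence = 0.167)  # = qlogis(0.167)
calibrate_intercept <- function(beta_mother = 0, beta_child = 0, prevalence,
                                rho = 0.5, nodes = 60) {
  assert_scalar_prob(prevalence, "prevalence")
  s2 <- beta_mother^2 + beta_child^2 + 2 * rho * beta_mother * beta_child
  calibrate_intercept_sd(sqrt(max(s2, 0)), prevalence, nodes)
}

calibrate_intercept_sd <- function(s, prevalence, nodes = 60) {
  if (s == 0) return(qlogis(prevalence))
  gh <- statmod::gauss.quad(nodes, kind = "hermite")
  z <- sqrt(2) * gh$nodes
  w <- gh$weights / sqrt(pi)
  f <- function(alpha) sum(w * plogis(alpha + s * z)) - prevalence
  uniroot(f, lower = qlogis(prevalence) - 6 * s - 1,
          upper = qlogis(prevalence) + 6 * s + 1, tol = 1e-12)$root
}

calibrate_intercept_empirical <- function(eta, prevalence) {
  f <- function(alpha) mean(plogis(alpha + eta)) - prevalence
  uniroot(f, lower = qlogis(prevalence) - max(abs(eta)) - 1,
          upper = qlogis(prevalence) + max(abs(eta)) + 1, tol = 1e-12)$root
}

#' Assign binary disease status under a scenario
#'
#' Computes each child's risk from the scenario's logistic risk function and
#' draws case status as Bernoulli(risk). For `direct_pgs` scenarios the
#' intercept comes from [calibrate_intercept()] (Gauss-Hermite, assuming
#' standardized bivariate-normal PGSs); for `via_birthweight` it is
#' root-found on the empirical linear predictor. The realized case fraction
#' therefore matches the target prevalence up to binomial noise.
#'
#' @param phenotypes A tibble of children carrying standardized score columns
#'   `pgs_mother` and `pgs_child` (for `direct_pgs`) or `birth_weight` and
#'   `pgs_child` (for `via_birthweight`).
#' @param scenario A [disease_scenario()].
#' @param outcome Name of the 0/1 column to add.
#' @param seed Optional integer seed.
#' @return `phenotypes` with added `risk` and outcome columns.
#' @export
assign_disease <- function(phenotypes, scenario, outcome = "case",
                           seed = NULL) {
  stopifnot(inherits(scenario, "disease_scenario"))
  phenotypes <- tibble::as_tibble(phenotypes)
  set_seed_if(seed)
  if (scenario$mediation == "direct_pgs") {
    need <- c("pgs_mother", "pgs_child")
    if (!all(need %in% names(phenotypes))) {
      abort("direct_pgs scenarios need `pgs_mother` and `pgs_child` columns.")
    }
    eta <- scenario$beta_mother * phenotypes$pgs_mother +
      scenario$beta_child * phenotypes$pgs_child
    alpha <- calibrate_intercept(scenario$beta_mother, scenario$beta_child,
                                 scenario$prevalence, scenario$rho)
  } else {
    need <- c("birth_weight", "pgs_child")
    if (!all(need %in% names(phenotypes))) {
      abort("via_birthweight scenarios need `birth_weight` and `pgs_child` columns.")
    }
    bw_z <- scale(phenotypes$birth_weight)[, 1]
    eta <- scenario$beta_mother * bw_z +
      scenario$beta_child * phenotypes$pgs_child
    alpha <- calibrate_intercept_empirical(eta, scenario$prevalence)
  }
  risk <- plogis(alpha + eta)
  phenotypes$risk <- risk
  phenotypes[[outcome]] <- rbinom(length(risk), 1L, risk)
  phenotypes
}

#' Sample correlated mother-child PGS pairs
#'
#' Draws `n` pairs from the bivariate normal with means 0, variances 1 and
#' correlation `rho` -- the distribution of standardized mother and child
#' polygenic scores under random mating, where Mendelian transmission makes
#' the parent-child score correlation 0.5.
#'
#' @param n Number of pairs.
#' @param rho Correlation in (-1, 1); 0.5 reflects mother-child pairs.
#' @param seed Optional integer seed.
#' @return A tibble with columns `pgs_mother` and `pgs_child`.
#' @export
sample_pgs_pairs <- function(n, rho = 0.5, seed = NULL) {
  n <- assert_count(n, "n")
  if (!(is.numeric(rho) && length(rho) == 1L && abs(rho) < 1)) {
    abort("`rho` must be a single correlation in (-1, 1).")
  }
  set_seed_if(seed)
  sigma <- matrix(c(1, rho, rho, 1), 2)
  z <- mvtnorm::rmvnorm(n, sigma = sigma)
  tibble::tibble(pgs_mother = z[, 1], pgs_child = z[, 2])
}
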