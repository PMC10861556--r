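#' duomr: within-family Mendelian randomization in parent-child duos
#'
#' Separates maternal (intrauterine) from fetal (pleiotropic) effects of
#' birth-weight polygenic scores on binary disease outcomes using genotyped
#' mother-child, father-child and full-sibling pairs. The package bundles a
#' synthetic family-cohort generator, polygenic score construction, the
#' single-score and joint mother+child logistic association models, a
#' matched discordant-sibling conditional-logistic analysis, and a
#' simulation-based power calculator for the joint model.
#'
#' @keywords internal
#' @importFrom rlang .data abort warn .env
#' @importFrom stats rnorm runif rbinom plogis qlogis uniroot qnorm pnorm
#'   setNames complete.cases sd var cor quantile
#' @importFrom dplyr %>%
"_PACKAGE"

PANEL_CLASSES <- c("M_ONLY", "F_ONLY", "SHARED_CONC", "SHARED_OPP", "UNCLASSIFIED")

# Counter-based expansion of one user-facing seed into per-stage /
# per-replicate seeds. Arithmetic stays in doubles well below 2^53 so the
# modulus is exact; results fit in a 32-bit integer for set.seed().
derive_seed <- function(seed, stage, index = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  stage_id <- if (is.character(stage)) {
    sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage))) %% 1000003
  } else {
    as.numeric(stage)
  }
  val <- (abs(seed) %% 2147483647) * 69069 + stage_id * 1000003 + index
  as.integer(val %% 2147483629 + 1)
}

set_seed_if <- function(seed) {
  if (!is.null(seed)) set.seed(seed)
  invisible(seed)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

assert_scalar_prob <- function(x, name, open = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (open) x > 0 && x < 1 else x >= 0 && x <= 1)
  if (!ok) {
    abort(sprintf("`%s` must be a single number in %s.", name,
                  if (open) "(0, 1)" else "[0, 1]"))
  }
  invisible(x)
}

assert_count <- function(x, name, min = 1) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min &&
    x == floor(x)
  if (!ok) abort(sprintf("`%s` must be a single integer >= %s.", name, min))
  invisible(as.integer(x))
}

dosage_matrix <- function(dosages) {
  stopifnot(is.data.frame(dosages), "individual_id" %in% names(dosages))
  m <- as.matrix(dosages[setdiff(names(dosages), "individual_id")])
  rownames(m) <- dosages$individual_id
  m
}
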