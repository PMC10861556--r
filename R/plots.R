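#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Forest plot of the MR model triplet
#'
#' Displays the parent and child PGS log odds ratios (with 95% Wald
#' intervals) across the parent-only, child-only and joint models -- the
#' attenuation of the parent term after conditioning on the child's score
#' is the visual signature of a fetal (pleiotropic) rather than maternal
#' (intrauterine) effect.
#'
#' @param object An `mr_triplet`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot mr_triplet
#' @export
autoplot.mr_triplet <- function(object, ...) {
  d <- dplyr::filter(tidy(object),
                     .data$term %in% c("PARENT_PGS", "CHILD_PGS"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$estimate, y = .data$model,
                                  colour = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(
      ggplot2::aes(xmin = .data$estimate - 1.96 * .data$std.error,
                   xmax = .data$estimate + 1.96 * .data$std.error),
      position = ggplot2::position_dodge(width = 0.4)) +
    ggplot2::labs(x = "logOR per SD of PGS", y = NULL, colour = NULL,
                  title = sprintf("Outcome: %s", object$outcome)) +
    ggplot2::theme_minimal()
}

#' Power curves from a simulated power grid
#'
#' @param object A `power_grid` tibble.
#' @param term `"mother"` or `"child"`: which coefficient's power to draw.
#' @param ... Unused.
#' @return A ggplot of power (with Monte-Carlo error bars) against the
#'   odds ratio.
#' @method autoplot power_grid
#' @export
autoplot.power_grid <- function(object, term = c("mother", "child"), ...) {
  term <- match.arg(term)
  xcol <- paste0("or_", term)
  ycol <- paste0("power_", term)
  secol <- paste0("mc_se_", term)
  d <- tibble::as_tibble(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data[[xcol]], y = .data[[ycol]])) +
    ggplot2::geom_hline(yintercept = 0.8, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data[[ycol]] - .data[[secol]],
                   ymax = .data[[ycol]] + .data[[secol]])) +
    ggplot2::geom_line() +
    ggplot2::labs(x = sprintf("true %s OR per SD of PGS", term),
                  y = "simulated power") +
    ggplot2::theme_minimal()
}
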