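#' @exportS3Method ggplot2::autoplot
autoplot.saxs_curve <- function(object, log_y = TRUE, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$q, y = .data$I)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.6) +
    ggplot2::labs(x = expression(q ~ (ring(A)^-1)), y = "I(q)")
  if (has_sigma(object)) {
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$I - .data$sigma, ymax = .data$I + .data$sigma),
      linewidth = 0.2, alpha = 0.3)
  }
  if (log_y) p <- p + ggplot2::scale_y_log10()
  p + ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.kratky_curve <- function(object, ...) {
  pk <- attr(object, "peak")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$qrg, y = .data$y)) +
    ggplot2::geom_line() +
    ggplot2::annotate("point", x = pk$qrg, y = pk$height, colour = "red") +
    ggplot2::labs(x = expression(q ~ R[g]),
                  y = expression((q ~ R[g])^2 ~ I(q) / I(0))) +
    ggplot2::coord_cartesian(xlim = c(0, 10)) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.pair_distribution <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$r, y = .data$p)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = expression(r ~ (ring(A))), y = "P(r)") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.guinier_fit <- function(object, curve, ...) {
  stopifnot(inherits(curve, "saxs_curve"))
  df <- tibble(q2 = curve$q^2, lnI = log(pmax(curve$I, .Machine$double.xmin)),
               inside = curve$q >= object$qmin & curve$q <= object$qmax)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$q2, y = .data$lnI,
                                   colour = .data$inside)) +
    ggplot2::geom_point(size = 0.5) +
    ggplot2::geom_abline(intercept = log(object$i0),
                         slope = -object$rg^2 / 3, linetype = 2) +
    ggplot2::coord_cartesian(xlim = c(0, (2 * object$qmax)^2)) +
    ggplot2::labs(x = expression(q^2), y = "ln I(q)",
                  colour = "in window") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.refinement_result <- function(object, ...) {
  ggplot2::ggplot(object$trace,
                  ggplot2::aes(x = .data$generation, y = .data$chi2,
                               group = .data$run,
                               colour = factor(.data$run))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "generation", y = expression(best ~ chi^2),
                  colour = "run") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.ensemble_selection <- function(object, binwidth = 0.5, ...) {
  df <- dplyr::bind_rows(
    tibble(rg = object$rg_pool, set = "pool"),
    tibble(rg = object$rg_selected, set = "selected"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rg, fill = .data$set)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(.data$density)),
                            position = "identity", alpha = 0.5,
                            binwidth = binwidth) +
    ggplot2::labs(x = expression(R[g] ~ (ring(A))), y = "density") +
    ggplot2::theme_minimal()
}
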