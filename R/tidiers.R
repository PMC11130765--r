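#' Tidy a stiffness result
#'
#' One row per reported elastic quantity, with units.
#'
#' @param x A `stiffness_result`.
#' @param ... Unused.
#' @return Tibble (`quantity`, `value`, `units`).
#' @export
tidy.stiffness_result <- function(x, ...) {
  K <- x$K
  tibble(
    quantity = c(
      "A1", "A2", "C_twist", "G", "G_tilt_roll", "G_tilt_twist", "B",
      "K_tau_tau", "K_rho_rho", "K_omega_omega", "K_rho_omega",
      "K_tau_rho", "K_tau_omega"
    ),
    value = c(
      x$A1, x$A2, x$C_twist, x$G, x$G_tilt_roll, x$G_tilt_twist, x$B,
      K["tau", "tau"], K["rho", "rho"], K["omega", "omega"],
      K["rho", "omega"], K["tau", "rho"], K["tau", "omega"]
    ),
    units = c(rep("nm", 7), rep("pN nm", 6))
  )
}

#' @rdname tidy.stiffness_result
#' @export
glance.stiffness_result <- function(x, ...) {
  tibble(
    temperature = x$temperature, L0 = x$L0, n_snapshots = x$n,
    A1 = x$A1, A2 = x$A2, C_twist = x$C_twist, G = x$G, B = x$B
  )
}

#' Tidy a worm-like-chain fit
#'
#' @param x A `wlc_fit`.
#' @param ... Unused.
#' @return `tidy()`: the bin table with `y`, fit and retention columns;
#'   `glance()`: a one-row summary with `l_B` and its standard error.
#' @export
tidy.wlc_fit <- function(x, ...) {
  x$bins
}

#' @rdname tidy.wlc_fit
#' @export
glance.wlc_fit <- function(x, ...) {
  tibble(
    l_B = x$l_B, l_B_se = x$l_B_se, l = x$l,
    a0 = x$coefficients[["a0"]], a1 = x$coefficients[["a1"]],
    a2 = x$coefficients[["a2"]],
    n_angles = x$n, n_bins_fit = sum(x$bins$retained)
  )
}

#' Tidy a temperature scan
#'
#' @param x A `temperature_scan`.
#' @param ... Unused.
#' @return `tidy()`: the slope table (one row per quantity); `glance()`: the
#'   per-temperature results table.
#' @export
tidy.temperature_scan <- function(x, ...) {
  x$slopes
}

#' @rdname tidy.temperature_scan
#' @export
glance.temperature_scan <- function(x, ...) {
  x$results
}

#' Plot a worm-like-chain fit
#'
#' Log-density-over-sine values per bin against the bending angle, with the
#' fitted quadratic; retained bins are solid, excluded bins hollow.
#'
#' @param object A `wlc_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.wlc_fit <- function(object, ...) {
  bins <- object$bins[!is.na(object$bins$y), ]
  ggplot2::ggplot(bins, ggplot2::aes(x = rad2deg(.data$mid))) +
    ggplot2::geom_point(ggplot2::aes(y = .data$y, shape = .data$retained)) +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 1)) +
    ggplot2::geom_line(
      data = bins[bins$retained, ],
      ggplot2::aes(y = .data$fitted), colour = "firebrick"
    ) +
    ggplot2::labs(
      x = "bending angle (deg)", y = "ln[p / sin(theta)]",
      shape = "in fit",
      title = sprintf("l_B = %.2f +/- %.2f nm", object$l_B, object$l_B_se)
    )
}

#' Plot a temperature scan
#'
#' Per-temperature values of selected quantities with their ordinary
#' least-squares trend lines, one facet per quantity.
#'
#' @param object A `temperature_scan`.
#' @param quantities Character vector of quantities to show; defaults to the
#'   stiffness-related ones.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.temperature_scan <- function(object,
                                      quantities = c("l_B", "A1", "A2", "B"),
                                      ...) {
  long <- tidyr::pivot_longer(
    object$results[, c("temperature", quantities)],
    cols = -"temperature", names_to = "quantity"
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$temperature, .data$value)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
      linewidth = 0.4, colour = "firebrick"
    ) +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(x = "temperature (K)", y = NULL)
}

#' Plot a per-step variance profile
#'
#' Tilt and roll variances per step, labelled by the flanking base pairs.
#'
#' @param profile Output of [per_step_variances()].
#' @return A ggplot.
#' @export
plot_variance_profile <- function(profile) {
  long <- tidyr::pivot_longer(profile,
    cols = c("var_tilt", "var_roll"),
    names_to = "component", values_to = "variance"
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$step, .data$variance,
    colour = .data$component
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(
      breaks = profile$step, labels = profile$bases
    ) +
    ggplot2::labs(x = "step", y = "variance (rad^2)")
}
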