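#' One-temperature elasticity analysis
#'
#' Convenience pipeline: segment selection, cumulative angles, fluctuation
#' summary and covariance inversion in one call.
#'
#' @param table A [step_table()].
#' @param temperature Temperature of the trajectory, K.
#' @param trim_each_end,burn_in,burn_in_frac Passed to [select_segment()].
#' @param L0 Contour length policy passed to [cumulative_angles()].
#' @return A `stiffness_result` (see [stiffness_from_covariance()]).
#' @examples
#' tab <- generate_trajectory(ground_truth(), n_snapshots = 2000, seed = 1)
#' analyze_elasticity(tab, temperature = 300)
#' @export
analyze_elasticity <- function(table, temperature = 300, trim_each_end = 3,
                               burn_in = NULL, burn_in_frac = 0.1,
                               L0 = "auto") {
  table |>
    select_segment(trim_each_end, burn_in = burn_in, burn_in_frac = burn_in_frac) |>
    cumulative_angles(L0 = L0) |>
    fluctuation_summary() |>
    stiffness_from_covariance(temperature = temperature)
}

#' One-temperature bending persistence length
#'
#' Segment selection, pooled window bending angles, histogram and
#' worm-like-chain fit in one call.
#'
#' @inheritParams analyze_elasticity
#' @param span Base pairs per bending window.
#' @param profile_length Window arc length policy, see [window_bend_angles()].
#' @param bin_width,fit_range,min_count Passed to [bend_angle_histogram()]
#'   and [wlc_fit()].
#' @return A `wlc_fit` (see [wlc_fit()]).
#' @export
fit_bend_persistence <- function(table, trim_each_end = 3, burn_in = NULL,
                                 burn_in_frac = 0.1, span = 6,
                                 profile_length = "auto",
                                 bin_width = pi / 180,
                                 fit_range = c(2, 25) * pi / 180,
                                 min_count = 10) {
  table |>
    select_segment(trim_each_end, burn_in = burn_in, burn_in_frac = burn_in_frac) |>
    window_bend_angles(span = span, profile_length = profile_length) |>
    bend_angle_histogram(bin_width = bin_width) |>
    wlc_fit(fit_range = fit_range, min_count = min_count)
}

#' Ordinary least-squares temperature trend
#'
#' Fits `value = intercept + slope * T` by ordinary least squares. Exact on
#' collinear input; points are unweighted.
#'
#' @param points Data frame whose first two columns are temperature (K) and
#'   value (or columns named `temperature` and `value`).
#' @return Tibble with `slope`, `intercept`, `slope_se`.
#' @examples
#' linear_trend(data.frame(temperature = 280 + 10 * 0:4, value = 1:5))
#' @export
linear_trend <- function(points) {
  points <- as_tibble(points)
  if (all(c("temperature", "value") %in% names(points))) {
    T_ <- points$temperature
    v <- points$value
  } else {
    T_ <- points[[1]]
    v <- points[[2]]
  }
  if (length(unique(T_)) < 2) {
    abort("need at least 2 distinct temperatures for a trend",
      class = "helixbend_domain_error"
    )
  }
  fit <- lm(v ~ T_)
  tibble(
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    # suppressWarnings: collinear input ("essentially perfect fit") is a
    # legitimate case here, with slope_se ~ 0
    slope_se = if (length(T_) > 2) {
      suppressWarnings(sqrt(diag(vcov(fit)))[[2]])
    } else {
      NA_real_
    }
  )
}

scan_quantities <- c(
  "l_B", "theta_mean", "rho_mean", "tau_mean", "A1", "A2", "B",
  "var_tau", "var_rho", "c_tau_rho", "c_tau_omega", "c_rho_omega"
)

#' Full analysis across a temperature series
#'
#' Runs the elasticity and worm-like-chain analyses at every temperature
#' with one shared configuration, then fits ordinary least-squares
#' temperature trends for the twelve reported quantities: `l_B`, the mean
#' step angles, `A1`, `A2`, `B`, the cumulative tilt/roll variances and the
#' three Pearson coefficients. Because least squares is linear and
#' `B = (A1 - A2) / 2` pointwise, the directly fitted `B` slope must equal
#' `(slope(A1) - slope(A2)) / 2`; both values and their difference are
#' reported so the identity is visible rather than assumed.
#'
#' @param tables Named list of [step_table()]s; names are temperatures in K
#'   (or pass `temperatures`).
#' @param temperatures Numeric temperatures matching `tables`.
#' @inheritParams analyze_elasticity
#' @inheritParams fit_bend_persistence
#' @param fit_range Fit window for the per-temperature WLC fits, radians.
#'   The scan default (2-45 degrees) is wider than the [wlc_fit()] default
#'   because pooled 6-bp angles of an A-form-like helix include the intrinsic
#'   superhelical bend and therefore centre at larger angles.
#' @return Object of class `temperature_scan`: list with `results` (one row
#'   per temperature), `slopes` (one row per quantity), `b_slope` (fitted vs
#'   identity B slope and their difference), `config`, and the per-T result
#'   objects in `details`.
#' @export
scan_temperatures <- function(tables, temperatures = NULL, trim_each_end = 3,
                              burn_in = NULL, burn_in_frac = 0.1, L0 = "auto",
                              span = 6, profile_length = "auto",
                              bin_width = pi / 180,
                              fit_range = c(2, 45) * pi / 180,
                              min_count = 10) {
  temperatures <- temperatures %||% as.numeric(names(tables))
  if (anyNA(temperatures) || length(temperatures) != length(tables)) {
    abort("temperatures must be supplied as list names or explicitly",
      class = "helixbend_config_error"
    )
  }
  if (is.unsorted(temperatures, strictly = TRUE)) {
    abort("temperatures must be strictly increasing",
      class = "helixbend_config_error"
    )
  }
  per_t <- purrr::map2(tables, temperatures, function(tab, T_i) {
    tryCatch(
      {
        sel <- select_segment(tab, trim_each_end,
          burn_in = burn_in,
          burn_in_frac = burn_in_frac
        )
        st <- sel |>
          cumulative_angles(L0 = L0) |>
          fluctuation_summary() |>
          stiffness_from_covariance(temperature = T_i)
        wf <- sel |>
          window_bend_angles(span = span, profile_length = profile_length) |>
          bend_angle_histogram(bin_width = bin_width) |>
          wlc_fit(fit_range = fit_range, min_count = min_count)
        ma <- mean_step_angles(sel)
        fs <- st$summary
        list(
          row = tibble(
            temperature = T_i,
            l_B = wf$l_B, l_B_se = wf$l_B_se,
            theta_mean = ma$theta_mean, rho_mean = ma$rho_mean,
            tau_mean = ma$tau_mean,
            A1 = st$A1, A2 = st$A2, C_twist = st$C_twist, G = st$G, B = st$B,
            var_tau = fs$variances[["tau"]], var_rho = fs$variances[["rho"]],
            c_tau_rho = fs$pearson["tau", "rho"],
            c_tau_omega = fs$pearson["tau", "omega"],
            c_rho_omega = fs$pearson["rho", "omega"]
          ),
          stiffness = st, wlc = wf
        )
      },
      error = function(e) {
        abort(
          sprintf("analysis failed at T = %g K: %s", T_i, conditionMessage(e)),
          class = "helixbend_scan_error", parent = e
        )
      }
    )
  })
  results <- dplyr::bind_rows(purrr::map(per_t, "row"))
  slopes <- purrr::map_dfr(scan_quantities, function(q) {
    dplyr::mutate(
      linear_trend(tibble(temperature = results$temperature, value = results[[q]])),
      quantity = q, .before = 1
    )
  })
  slopes$units <- c(
    "nm/K", "deg/K", "deg/K", "deg/K", "nm/K", "nm/K", "nm/K",
    "rad^2/K", "rad^2/K", "1/K", "1/K", "1/K"
  )
  k1 <- slopes$slope[slopes$quantity == "A1"]
  k2 <- slopes$slope[slopes$quantity == "A2"]
  k3 <- slopes$slope[slopes$quantity == "B"]
  b_slope <- tibble(
    fitted = k3, identity = (k1 - k2) / 2, difference = k3 - (k1 - k2) / 2
  )
  structure(
    list(
      results = results, slopes = slopes, b_slope = b_slope,
      config = list(
        trim_each_end = trim_each_end, burn_in = burn_in,
        burn_in_frac = burn_in_frac, L0 = L0, span = span,
        profile_length = profile_length, bin_width = bin_width,
        fit_range = fit_range, min_count = min_count
      ),
      details = purrr::map(per_t, function(p) p[c("stiffness", "wlc")])
    ),
    class = "temperature_scan"
  )
}

#' @export
print.temperature_scan <- function(x, ...) {
  cat(sprintf(
    "<temperature_scan> %d temperatures (%g-%g K)\n",
    nrow(x$results), min(x$results$temperature), max(x$results$temperature)
  ))
  print(x$slopes)
  invisible(x)
}
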