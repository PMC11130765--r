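#' Histogram of pooled bending angles
#'
#' Bins bending angles on a regular grid from 0 and normalises counts to a
#' density (midpoint rule): `sum(density * bin_width) == 1`. Empty bins
#' inside the occupied range are retained with zero density so the fit stage
#' sees the full grid.
#'
#' @param sample Numeric vector of bending angles in radians, or the tibble
#'   returned by [window_bend_angles()] (its `theta` column is used and its
#'   `profile_length` attribute is forwarded).
#' @param bin_width Bin width in radians; default 1 degree.
#' @return Tibble (`bin_lo`, `bin_hi`, `mid`, `count`, `density`) with
#'   attributes `n` and (when available) `profile_length`.
#' @export
bend_angle_histogram <- function(sample, bin_width = pi / 180) {
  profile_length <- attr(sample, "profile_length")
  if (is.data.frame(sample)) sample <- sample$theta
  stopifnot(is.numeric(sample), length(sample) > 0, bin_width > 0)
  n_bins <- max(1L, ceiling(max(sample) / bin_width + 1e-12))
  idx <- pmin(floor(sample / bin_width), n_bins - 1L)
  counts <- tabulate(idx + 1L, nbins = n_bins)
  lo <- (seq_len(n_bins) - 1L) * bin_width
  out <- tibble(
    bin_lo = lo, bin_hi = lo + bin_width, mid = lo + bin_width / 2,
    count = counts,
    density = counts / (length(sample) * bin_width)
  )
  structure(out, n = length(sample), profile_length = profile_length)
}

#' Worm-like-chain fit of the bending-angle distribution
#'
#' Under a worm-like chain of bending persistence length `l_B`, the bending
#' angle `theta` subtended by a segment of arc length `l` has density
#' `p(theta) ~ sin(theta) * exp(-l_B * theta^2 / (2 l))`, so
#' `y = ln(p / sin theta)` is quadratic in `theta` with curvature
#' `-l_B / (2 l)`. This routine fits `y = a0 + a1 theta + a2 theta^2` at the
#' bin midpoints by least squares weighted by the bin counts (the noise of a
#' log-density scales as `1 / sqrt(count)`) and reports
#' `l_B = -2 * l * a2` with a standard error propagated from `a2`.
#'
#' Bins outside `fit_range` or with fewer than `min_count` entries are
#' excluded: the lower cut avoids the noisy `sin(theta) -> 0` log
#' singularity, the upper cut keeps the fit in the quadratic regime.
#'
#' @param hist Histogram from [bend_angle_histogram()].
#' @param l Window arc length in nm; `"auto"` uses the histogram's
#'   `profile_length` attribute.
#' @param fit_range Length-2 numeric, radians; default 2-25 degrees.
#' @param min_count Minimum bin count retained; default 10.
#' @return Object of class `wlc_fit`: list with `l_B`, `l_B_se`,
#'   `coefficients` (a0, a1, a2), `bins` (with `y` and `retained` columns),
#'   `l`, `fit_range`, `min_count`, `n`.
#' @export
wlc_fit <- function(hist, l = "auto", fit_range = c(2, 25) * pi / 180,
                    min_count = 10) {
  stopifnot(all(c("mid", "count", "density") %in% names(hist)))
  if (identical(l, "auto")) {
    l <- attr(hist, "profile_length")
    if (is.null(l)) {
      abort("histogram carries no profile length; pass l explicitly",
        class = "helixbend_config_error"
      )
    }
  }
  stopifnot(is.numeric(l), l > 0, length(fit_range) == 2)
  n_total <- attr(hist, "n") %||% sum(hist$count)
  hist <- as_tibble(hist)
  hist$retained <- hist$count >= min_count &
    hist$mid >= fit_range[1] & hist$mid <= fit_range[2]
  hist$y <- ifelse(hist$count > 0, log(hist$density / sin(hist$mid)), NA_real_)
  fit_bins <- hist[hist$retained, ]
  if (nrow(fit_bins) < 4) {
    abort("fewer than 4 usable bins in the fit range",
      class = "helixbend_data_error"
    )
  }
  fit <- lm(y ~ mid + I(mid^2), data = fit_bins, weights = fit_bins$count)
  a <- unname(coef(fit))
  a2_se <- sqrt(diag(vcov(fit)))[3]
  if (a[3] >= 0) {
    abort(
      sprintf(
        "non-physical fit: quadratic coefficient a2 = %.4g >= 0", a[3]
      ),
      class = "helixbend_nonphysical_fit_error"
    )
  }
  hist$fitted <- a[1] + a[2] * hist$mid + a[3] * hist$mid^2
  structure(
    list(
      l_B = -2 * l * a[3],
      l_B_se = 2 * l * unname(a2_se),
      coefficients = setNames(a, c("a0", "a1", "a2")),
      bins = hist, l = l, fit_range = fit_range, min_count = min_count,
      n = n_total
    ),
    class = "wlc_fit"
  )
}

#' @export
print.wlc_fit <- function(x, ...) {
  cat(sprintf(
    "<wlc_fit> l_B = %.2f +/- %.2f nm (l = %.4g nm, %d angles, fit %g-%g deg)\n",
    x$l_B, x$l_B_se, x$l, x$n, rad2deg(x$fit_range[1]), rad2deg(x$fit_range[2])
  ))
  invisible(x)
}

#' Sample bending angles from the worm-like-chain density
#'
#' Draws from `p(theta) ~ sin(theta) * exp(-l_B * theta^2 / (2 l))` on
#' `[0, pi]` by rejection from a Rayleigh proposal of scale `sqrt(l / l_B)`
#' (acceptance probability `sin(theta) / theta`, which is near 1 in the stiff
#' regime). Used to validate [wlc_fit()] against declared ground truth.
#'
#' @param n Number of samples.
#' @param l_B Bending persistence length, nm.
#' @param l Segment arc length, nm.
#' @return Numeric vector of angles in radians.
#' @export
rbend_angle <- function(n, l_B, l) {
  stopifnot(n >= 1, l_B > 0, l > 0)
  sigma <- sqrt(l / l_B)
  out <- numeric(0)
  while (length(out) < n) {
    m <- ceiling((n - length(out)) * 1.3) + 16
    theta <- sigma * sqrt(-2 * log(runif(m)))
    keep <- theta <= pi & runif(m) < sin(theta) / theta
    out <- c(out, theta[keep])
  }
  out[seq_len(n)]
}

#' Ensemble-mean step angles
#'
#' Means over all snapshots and steps of the tilt and roll, plus the mean
#' per-step bending angle `<theta> = <sqrt(tilt^2 + roll^2)>` (the mean of
#' the per-occurrence bending magnitudes, not the magnitude of the means).
#'
#' @param table A [step_table()], angles in degrees.
#' @return Tibble with `theta_mean`, `rho_mean`, `tau_mean` (degrees).
#' @export
mean_step_angles <- function(table) {
  stopifnot(inherits(table, "step_table"))
  tibble(
    theta_mean = mean(per_step_bend_identity(table$tilt, table$roll)),
    rho_mean = mean(table$roll),
    tau_mean = mean(table$tilt)
  )
}
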