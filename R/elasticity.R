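#' Cumulative segment angles per snapshot
#'
#' Sums tilt, roll and twist over all steps of the (already trimmed) segment
#' for each snapshot, converting to radians. These cumulative angles are the
#' deformation variables whose thermal covariance determines the elastic
#' modulus matrix.
#'
#' @param table A [step_table()], angles in degrees.
#' @param L0 Contour length of the segment in nm, or `"auto"` to use
#'   `n_steps * mean(rise)` (requires a rise column).
#' @return Tibble (`snapshot`, `tau`, `rho`, `omega`; radians) with
#'   attributes `L0` (nm) and `n_steps`.
#' @examples
#' gt <- ground_truth()
#' tab <- generate_trajectory(gt, n_snapshots = 100, seed = 1)
#' ca <- cumulative_angles(select_segment(tab, 3, burn_in = 0), L0 = 2.954)
#' attr(ca, "L0")
#' @export
cumulative_angles <- function(table, L0 = "auto") {
  stopifnot(inherits(table, "step_table"))
  if (identical(L0, "auto")) {
    if (!"rise" %in% names(table)) {
      abort("L0 = \"auto\" needs a rise column; pass L0 explicitly",
        class = "helixbend_config_error"
      )
    }
    L0 <- n_steps(table) * mean(table$rise)
  }
  stopifnot(is.numeric(L0), L0 > 0)
  out <- tibble(
    snapshot = unique(table$snapshot),
    tau = deg2rad(rowSums(step_matrix(table, "tilt"))),
    rho = deg2rad(rowSums(step_matrix(table, "roll"))),
    omega = deg2rad(rowSums(step_matrix(table, "twist")))
  )
  structure(out, L0 = L0, n_steps = n_steps(table))
}

#' Means, fluctuations and correlations of the cumulative angles
#'
#' Computes the snapshot-ensemble first and second moments of the cumulative
#' tilt, roll and twist: means (reported in degrees), sample variances
#' (denominator `n - 1`, in rad^2), the 3x3 Pearson correlation matrix and
#' the covariance matrix, which satisfy `cov(i, j) = c_ij * sigma_i * sigma_j`
#' by construction.
#'
#' @param series Output of [cumulative_angles()].
#' @return Object of class `fluctuation_summary`: a list with `means_deg`,
#'   `variances` (rad^2), `pearson`, `covariance` (rad^2), `n`, `L0`.
#' @export
fluctuation_summary <- function(series) {
  stopifnot(all(c("tau", "rho", "omega") %in% names(series)))
  m <- as.matrix(series[, c("tau", "rho", "omega")])
  if (nrow(m) < 3) {
    abort("need at least 3 snapshots to estimate fluctuations",
      class = "helixbend_degenerate_data_error"
    )
  }
  v <- apply(m, 2, var)
  zero <- names(v)[v == 0]
  if (length(zero) > 0) {
    abort(
      paste0(
        "zero variance in component(s): ",
        paste(zero, collapse = ", ")
      ),
      class = "helixbend_degenerate_data_error"
    )
  }
  C <- cov(m)
  structure(
    list(
      means_deg = rad2deg(colMeans(m)),
      variances = v,
      pearson = cor(m),
      covariance = C,
      n = nrow(m),
      L0 = attr(series, "L0")
    ),
    class = "fluctuation_summary"
  )
}

#' @export
print.fluctuation_summary <- function(x, ...) {
  cat(sprintf("<fluctuation_summary> n = %d snapshots\n", x$n))
  cat("means (deg):", sprintf("%.4f", x$means_deg), "\n")
  cat("variances (rad^2):", sprintf("%.3e", x$variances), "\n")
  invisible(x)
}

#' Persistence length from an elastic modulus
#'
#' Converts one element of the elastic modulus matrix (energy units, pN nm)
#' into the equivalent stiffness length: `A = K * L0 / (kB * T)` with
#' `kB = 0.0138065` pN nm / K. With the modulus of the cumulative tilt, for
#' instance, this yields the tilt persistence length.
#'
#' @param K Elastic modulus, pN nm.
#' @param L0 Contour length, nm.
#' @param temperature Temperature, K.
#' @return Stiffness length in nm.
#' @examples
#' persistence_from_modulus(169.39, 2.954, 300) # ~120.80 nm
#' @export
persistence_from_modulus <- function(K, L0, temperature) {
  stopifnot(L0 > 0, temperature > 0)
  K * L0 / (.kB * temperature)
}

#' Elastic modulus matrix and stiffness lengths from the angle covariance
#'
#' Inverts the 3x3 covariance of the cumulative angles: the elastic modulus
#' matrix is `K = kB * T * C^-1` (pN nm) and the stiffness lengths are the
#' elements of `L0 * C^-1` (nm): tilt stiffness `A1`, roll stiffness `A2`,
#' twist stiffness `C_twist` and the roll-twist (twist-bend) coupling `G`.
#' The tilt-roll and tilt-twist couplings are retained and reported as well,
#' so the assumption that they are small can be checked rather than imposed.
#' The bending-anisotropy parameter is `B = (A1 - A2) / 2`.
#'
#' @param summary A [fluctuation_summary()].
#' @param L0 Contour length in nm; defaults to the one recorded in `summary`.
#' @param temperature Temperature in kelvin.
#' @return Object of class `stiffness_result`: list with `K` (pN nm),
#'   `stiffness` (nm, `L0 * C^-1`), `A1`, `A2`, `C_twist`, `G`,
#'   `G_tilt_roll`, `G_tilt_twist`, `B`, `temperature`, `L0`, `n`, plus the
#'   input summary.
#' @export
stiffness_from_covariance <- function(summary, L0 = NULL, temperature = 300) {
  stopifnot(inherits(summary, "fluctuation_summary"))
  L0 <- L0 %||% summary$L0
  if (is.null(L0)) {
    abort("L0 not recorded in the summary; pass it explicitly",
      class = "helixbend_config_error"
    )
  }
  stopifnot(L0 > 0, temperature > 0)
  C <- summary$covariance
  ch <- tryCatch(chol(C), error = function(e) NULL)
  if (is.null(ch)) {
    abort(
      sprintf(
        "covariance matrix is not positive definite (condition number %.3g)",
        kappa(C)
      ),
      class = "helixbend_numerical_error"
    )
  }
  Cinv <- chol2inv(ch)
  dimnames(Cinv) <- dimnames(C)
  S <- L0 * Cinv
  A1 <- S["tau", "tau"]
  A2 <- S["rho", "rho"]
  structure(
    list(
      K = .kB * temperature * Cinv,
      stiffness = S,
      A1 = A1, A2 = A2,
      C_twist = S["omega", "omega"],
      G = S["rho", "omega"],
      G_tilt_roll = S["tau", "rho"],
      G_tilt_twist = S["tau", "omega"],
      B = asymmetry(A1, A2),
      temperature = temperature, L0 = L0, n = summary$n,
      summary = summary
    ),
    class = "stiffness_result"
  )
}

#' @export
print.stiffness_result <- function(x, ...) {
  cat(sprintf(
    "<stiffness_result> T = %g K, L0 = %g nm, n = %d snapshots\n",
    x$temperature, x$L0, x$n
  ))
  cat(sprintf(
    "A1 = %.2f nm  A2 = %.2f nm  C = %.2f nm  G = %.2f nm  B = %.2f nm\n",
    x$A1, x$A2, x$C_twist, x$G, x$B
  ))
  invisible(x)
}

#' Bending-anisotropy parameter
#'
#' `B = (A1 - A2) / 2`: half the difference between the tilt and roll
#' stiffness lengths. Zero for isotropic bending; negative if the roll mode
#' is the stiffer one.
#'
#' @param A1 Tilt stiffness length, nm.
#' @param A2 Roll stiffness length, nm.
#' @return Anisotropy in nm.
#' @examples
#' asymmetry(120.80, 22.46) # 49.17
#' @export
asymmetry <- function(A1, A2) {
  stopifnot(is.finite(A1), is.finite(A2))
  (A1 - A2) / 2
}

#' Diagonal (correlation-free) stiffness approximation
#'
#' The fluctuation approximation ignores all correlations and estimates the
#' bending stiffnesses from the marginal variances alone:
#' `A1 ~ L0 / var(tau)`, `A2 ~ L0 / var(rho)` (variances in rad^2). Equal to
#' the full covariance inversion exactly when all Pearson off-diagonals
#' vanish; correlations (notably roll-twist coupling) make the exact
#' stiffnesses larger than these approximations.
#'
#' @inheritParams stiffness_from_covariance
#' @return Tibble with `A1_approx`, `A2_approx` (nm).
#' @export
approximate_stiffness <- function(summary, L0 = NULL) {
  stopifnot(inherits(summary, "fluctuation_summary"))
  L0 <- L0 %||% summary$L0
  stopifnot(is.numeric(L0), L0 > 0)
  v <- summary$variances
  stopifnot(all(v[c("tau", "rho")] > 0))
  tibble(A1_approx = L0 / v[["tau"]], A2_approx = L0 / v[["rho"]])
}

#' Per-step tilt and roll variance profile
#'
#' Sample variance (rad^2) of the tilt and roll of every individual step
#' across the snapshot ensemble, labelled by the flanking base pairs. This is
#' the sequence-resolved counterpart of the segment-cumulative fluctuations:
#' it exposes which dinucleotide steps are soft.
#'
#' @param table A [step_table()], angles in degrees.
#' @return Tibble (`step`, `bases`, `var_tilt`, `var_roll`; rad^2).
#' @export
per_step_variances <- function(table) {
  stopifnot(inherits(table, "step_table"))
  if (n_snapshots(table) < 3) {
    abort("need at least 3 snapshots for per-step variances",
      class = "helixbend_degenerate_data_error"
    )
  }
  col_var <- function(m) apply(m, 2, var)
  tibble(
    step = seq_len(n_steps(table)),
    bases = step_labels(table),
    var_tilt = col_var(deg2rad(step_matrix(table, "tilt"))),
    var_roll = col_var(deg2rad(step_matrix(table, "roll")))
  )
}
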