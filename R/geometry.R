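#' Rotation matrix of one base-pair step
#'
#' Maps the step angles to the rotation carried by one base-pair step using
#' the rotation-vector (matrix-exponential) convention: the triple
#' `(tilt, roll, twist)` is read as a rotation vector and the returned matrix
#' is its exponential, evaluated in closed form (Rodrigues). The convention is
#' symmetric in its three components and exactly invertible by
#' [extract_step_angles()]; it agrees with mid-step-triad conventions (e.g.
#' 3DNA's) to first order and differs only at O(angle^2), which is below the
#' quadratic-energy level at which stiffnesses are defined.
#'
#' @param tilt,roll,twist Step angles in radians.
#' @return 3x3 rotation matrix; its third column maps the helical tangent.
#' @examples
#' step_rotation(0, 0, pi / 2) # quarter turn about the helical axis
#' @export
step_rotation <- function(tilt, roll, twist) {
  stopifnot(is.finite(tilt), is.finite(roll), is.finite(twist))
  matrix(rodrigues_rows(tilt, roll, twist), nrow = 3)
}

# Vectorised Rodrigues formula. Inputs are equal-length vectors of rotation
# vector components; returns an n x 9 matrix of rotation entries in
# column-major order (r11 r21 r31 r12 r22 r32 r13 r23 r33).
rodrigues_rows <- function(x, y, z) {
  th2 <- x^2 + y^2 + z^2
  th <- sqrt(th2)
  small <- th < 1e-4
  a <- ifelse(small, 1 - th2 / 6 + th2^2 / 120, sin(th) / th)
  b <- ifelse(small, 0.5 - th2 / 24 + th2^2 / 720, (1 - cos(th)) / th2)
  cth <- cos(th)
  cbind(
    cth + b * x * x, a * z + b * x * y, -a * y + b * x * z,
    -a * z + b * x * y, cth + b * y * y, a * x + b * y * z,
    a * y + b * x * z, -a * x + b * y * z, cth + b * z * z
  )
}

# (A %*% B) for row-encoded column-major 3x3 matrices (n x 9 each).
rowmat_mul <- function(A, B) {
  out <- matrix(0, nrow(A), 9)
  for (q in 1:3) {
    for (p in 1:3) {
      out[, p + 3 * (q - 1)] <-
        A[, p] * B[, 1 + 3 * (q - 1)] +
        A[, p + 3] * B[, 2 + 3 * (q - 1)] +
        A[, p + 6] * B[, 3 + 3 * (q - 1)]
    }
  }
  out
}

rowmat_identity <- function(n) {
  matrix(rep(c(1, 0, 0, 0, 1, 0, 0, 0, 1), each = n), n, 9)
}

#' Recover step angles from a step rotation
#'
#' Inverse of [step_rotation()] (the matrix logarithm): valid for rotation
#' angles below pi.
#'
#' @param R 3x3 rotation matrix (orthonormal, determinant +1, checked to
#'   1e-8).
#' @return Numeric vector `c(tilt, roll, twist)` in radians.
#' @export
extract_step_angles <- function(R) {
  if (!is.matrix(R) || any(dim(R) != c(3, 3)) ||
    max(abs(crossprod(R) - diag(3))) > 1e-8 || det(R) < 0) {
    abort("input is not a proper rotation matrix",
      class = "helixbend_domain_error"
    )
  }
  v <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) / 2
  cth <- (sum(diag(R)) - 1) / 2
  sth <- sqrt(sum(v^2))
  theta <- atan2(sth, cth)
  if (theta < 1e-8) {
    return(v) # v = sin(theta) * axis ~ theta * axis
  }
  theta * v / sth
}

#' Integrate step rotations into base-pair frames
#'
#' Builds the frame of every base pair by composing step rotations along the
#' helix: frame 0 is the identity at the origin and frame `k` is frame
#' `k - 1` post-multiplied by the rotation of step `k`. Origins advance by
#' the step rise along the mid-step tangent (the tangent of the half-step
#' rotation), so a zero-angle trajectory produces collinear, evenly spaced
#' frames.
#'
#' @param table A [step_table()], angles in degrees.
#' @param rise Rise per step in nm; defaults to the table's `rise` column
#'   (per-row) or 0.2954 nm when absent.
#' @return Tibble with one row per (snapshot, base pair): origin `x,y,z` and
#'   frame axes `e11..e33` (column-major; `e13,e23,e33` is the helical
#'   tangent).
#' @export
accumulate_frames <- function(table, rise = NULL) {
  stopifnot(inherits(table, "step_table"))
  ns <- n_snapshots(table)
  nk <- n_steps(table)
  snaps <- unique(table$snapshot)
  tau <- deg2rad(step_matrix(table, "tilt"))
  rho <- deg2rad(step_matrix(table, "roll"))
  ome <- deg2rad(step_matrix(table, "twist"))
  if (is.null(rise)) {
    rise_m <- if ("rise" %in% names(table)) {
      step_matrix(table, "rise")
    } else {
      matrix(0.2954, ns, nk)
    }
  } else {
    rise_m <- matrix(rise, ns, nk)
  }
  M <- rowmat_identity(ns)
  O <- matrix(0, ns, 3)
  frames <- vector("list", nk + 1)
  frames[[1]] <- list(M = M, O = O)
  for (k in seq_len(nk)) {
    Rk <- rodrigues_rows(tau[, k], rho[, k], ome[, k])
    Hk <- rodrigues_rows(tau[, k] / 2, rho[, k] / 2, ome[, k] / 2)
    Mh <- rowmat_mul(M, Hk)
    O <- O + rise_m[, k] * Mh[, 7:9]
    M <- rowmat_mul(M, Rk)
    frames[[k + 1]] <- list(M = M, O = O)
  }
  out <- purrr::map2_dfr(frames, seq_along(frames) - 1L, function(f, bp) {
    tibble(
      snapshot = snaps, bp = bp,
      x = f$O[, 1], y = f$O[, 2], z = f$O[, 3],
      e11 = f$M[, 1], e21 = f$M[, 2], e31 = f$M[, 3],
      e12 = f$M[, 4], e22 = f$M[, 5], e32 = f$M[, 6],
      e13 = f$M[, 7], e23 = f$M[, 8], e33 = f$M[, 9]
    )
  })
  dplyr::arrange(out, .data$snapshot, .data$bp)
}

# Tangent vectors t_k (third frame axis) for all base pairs of all snapshots,
# as a list of three ns x (nk + 1) matrices. Cheaper than accumulate_frames
# when origins are not needed, but identical algebra.
frame_tangents <- function(table) {
  ns <- n_snapshots(table)
  nk <- n_steps(table)
  tau <- deg2rad(step_matrix(table, "tilt"))
  rho <- deg2rad(step_matrix(table, "roll"))
  ome <- deg2rad(step_matrix(table, "twist"))
  M <- rowmat_identity(ns)
  tx <- matrix(0, ns, nk + 1)
  ty <- matrix(0, ns, nk + 1)
  tz <- matrix(1, ns, nk + 1)
  for (k in seq_len(nk)) {
    M <- rowmat_mul(M, rodrigues_rows(tau[, k], rho[, k], ome[, k]))
    tx[, k + 1] <- M[, 7]
    ty[, k + 1] <- M[, 8]
    tz[, k + 1] <- M[, 9]
  }
  list(x = tx, y = ty, z = tz)
}

#' Pooled bending angles over sliding base-pair windows
#'
#' For every snapshot and every window of `span` consecutive base pairs, the
#' bending angle is the angle between the helical tangents of the window's
#' first and last base-pair frames, `theta = acos(t_s . t_(s+span-1))` (the
#' dot product is clamped to \[-1, 1\] to absorb rounding). All windows of all
#' snapshots are pooled, giving `n_snapshots * (n_bp - span + 1)` samples.
#'
#' @param x A [step_table()] (angles in degrees), or a frame tibble from
#'   [accumulate_frames()].
#' @param span Base pairs per window (default 6, i.e. 5 steps).
#' @param profile_length Arc length of one window in nm, used downstream by
#'   [wlc_fit()]. `"auto"` (default) takes `(span - 1) * mean(rise)` from the
#'   table's rise column, falling back to `(span - 1) * 0.2954` nm.
#' @return Tibble (`snapshot`, `window`, `theta` in radians) with attributes
#'   `span` and `profile_length`.
#' @export
window_bend_angles <- function(x, span = 6, profile_length = "auto") {
  if (span < 2) {
    abort("window span must be at least 2 base pairs",
      class = "helixbend_domain_error"
    )
  }
  if (inherits(x, "step_table")) {
    n_bp <- n_steps(x) + 1
    if (span > n_bp) {
      abort("window span exceeds the number of base pairs",
        class = "helixbend_domain_error"
      )
    }
    tg <- frame_tangents(x)
    snaps <- unique(x$snapshot)
    mean_rise <- if ("rise" %in% names(x)) mean(x$rise) else 0.2954
  } else {
    stopifnot(all(c("snapshot", "bp", "e13", "e23", "e33") %in% names(x)))
    x <- dplyr::arrange(x, .data$snapshot, .data$bp)
    snaps <- unique(x$snapshot)
    n_bp <- length(unique(x$bp))
    if (span > n_bp) {
      abort("window span exceeds the number of base pairs",
        class = "helixbend_domain_error"
      )
    }
    tg <- list(
      x = matrix(x$e13, ncol = n_bp, byrow = TRUE),
      y = matrix(x$e23, ncol = n_bp, byrow = TRUE),
      z = matrix(x$e33, ncol = n_bp, byrow = TRUE)
    )
    mean_rise <- 0.2954
  }
  n_win <- n_bp - span + 1
  starts <- seq_len(n_win)
  thetas <- lapply(starts, function(s) {
    d <- tg$x[, s] * tg$x[, s + span - 1] +
      tg$y[, s] * tg$y[, s + span - 1] +
      tg$z[, s] * tg$z[, s + span - 1]
    acos(pmin(pmax(d, -1), 1))
  })
  out <- tibble(
    snapshot = rep(snaps, times = n_win),
    window = rep(starts, each = length(snaps)),
    theta = unlist(thetas)
  )
  if (identical(profile_length, "auto")) {
    profile_length <- (span - 1) * mean_rise
  }
  structure(out, span = span, profile_length = profile_length)
}

#' Small-angle bending identity
#'
#' At a single step the bending angle satisfies `theta^2 = tilt^2 + roll^2`
#' (twist rotates about the tangent and does not bend it); this helper
#' evaluates `sqrt(tilt^2 + roll^2)`. Unit-agnostic: degrees in, degrees out.
#'
#' @param tilt,roll Step angles (any consistent unit).
#' @return Bending angle in the same unit.
#' @export
per_step_bend_identity <- function(tilt, roll) {
  sqrt(tilt^2 + roll^2)
}
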