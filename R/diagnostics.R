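#' RMSD of a coordinate series against a reference snapshot
#'
#' Root mean square displacement of the atoms (or base-pair centres) of each
#' snapshot from their positions in the reference snapshot:
#' `rmsd(t) = sqrt(mean_i |x_i(t) - x_i(ref)|^2)`. This is the raw
#' displacement formula used to diagnose equilibration on trajectory traces:
#' no optimal superposition (Kabsch fit) is performed, so a rigid translation
#' or rotation of a snapshot registers as displacement. The RMSD at the
#' reference snapshot is exactly zero.
#'
#' @param coords Coordinate tibble (`snapshot`, `atom`, `x`, `y`, `z`),
#'   e.g. from [emit_coordinates()] or [read_coordinate_series()].
#' @param reference Snapshot id used as the reference; defaults to the first.
#' @param time_step Snapshot spacing in ps; defaults to the tibble's
#'   `time_step` attribute, else 2.
#' @return Tibble (`snapshot`, `time` in ps, `rmsd` in nm).
#' @export
rmsd_series <- function(coords, reference = NULL, time_step = NULL) {
  validate_coordinate_series(coords)
  coords <- dplyr::arrange(as_tibble(coords), .data$snapshot, .data$atom)
  snaps <- unique(coords$snapshot)
  reference <- reference %||% snaps[1]
  if (!reference %in% snaps) {
    abort("reference snapshot not present in the series",
      class = "helixbend_domain_error"
    )
  }
  time_step <- time_step %||% attr(coords, "time_step") %||% 2
  n_atoms <- sum(coords$snapshot == snaps[1])
  xyz <- as.matrix(coords[, c("x", "y", "z")])
  ref <- xyz[coords$snapshot == reference, , drop = FALSE]
  d2 <- rowSums((xyz - ref[rep(seq_len(n_atoms), length(snaps)), ])^2)
  tibble(
    snapshot = snaps,
    time = snaps * time_step,
    rmsd = sqrt(colMeans(matrix(d2, nrow = n_atoms)))
  )
}

#' Block-average a time series
#'
#' Averages samples over consecutive half-open time blocks `[t0 + k*block,
#' t0 + (k+1)*block)`, reporting the block midpoint, the mean value, the
#' number of samples, and whether the final block is partial. The standard
#' smoothing used to read an equilibration plateau off an RMSD trace.
#'
#' @param series Data frame whose first two columns are time and value (or
#'   columns named `time` and `value`).
#' @param block Block duration in the series' time unit; must be at least the
#'   sampling stride.
#' @return Tibble (`time` = block midpoint, `value` = block mean, `n_samples`,
#'   `partial`).
#' @export
block_average <- function(series, block) {
  series <- as_tibble(series)
  if (all(c("time", "value") %in% names(series))) {
    t <- series$time
    v <- series$value
  } else {
    t <- series[[1]]
    v <- series[[2]]
  }
  stopifnot(is.numeric(t), is.numeric(v), block > 0)
  if (is.unsorted(t, strictly = TRUE)) {
    abort("time must be strictly increasing", class = "helixbend_domain_error")
  }
  if (length(t) > 1 && block < min(diff(t))) {
    abort("block must be at least the sampling stride",
      class = "helixbend_domain_error"
    )
  }
  idx <- floor((t - t[1]) / block)
  # final block is flagged partial when it holds fewer samples than the first
  last_partial <- sum(idx == max(idx)) < sum(idx == 0)
  agg <- tibble(idx = idx, v = v) |>
    dplyr::group_by(.data$idx) |>
    dplyr::summarise(value = mean(.data$v), n_samples = dplyr::n()) |>
    dplyr::ungroup()
  tibble(
    time = t[1] + (agg$idx + 0.5) * block,
    value = agg$value,
    n_samples = agg$n_samples,
    partial = agg$idx == max(agg$idx) & last_partial
  )
}
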