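#' Construct a step-parameter table
#'
#' A step-parameter table is the pipeline's central container: one row per
#' (snapshot, base-pair step) holding the three step rotations tilt, roll and
#' twist in degrees and, optionally, the translations shift, slide and rise in
#' nanometres. It is an ordinary tibble (so all dplyr verbs apply) carrying
#' three attributes: the base-pair `sequence` (one letter per base pair, so
#' `n_steps + 1` letters), the `time_step` between stored snapshots in
#' picoseconds, and the class `"step_table"`.
#'
#' Snapshots are numbered from 0 so that the time coordinate of snapshot `s`
#' is `s * time_step`; steps are numbered from 1 to `n_steps`.
#'
#' @param data Data frame with columns `snapshot`, `step`, `tilt`, `roll`,
#'   `twist` and optionally `shift`, `slide`, `rise`. Angles in degrees,
#'   translations in nm.
#' @param sequence Base-pair identity string over the A/C/G/U (T and N
#'   tolerated) alphabet, of length `n_steps + 1`. If `NULL`, an
#'   uninformative all-`N` sequence is used.
#' @param time_step Time between stored snapshots, picoseconds. Default 2.
#' @return A `step_table` tibble.
#' @examples
#' step_table(
#'   data.frame(snapshot = 0, step = 1:2, tilt = 0, roll = 9.05, twist = 32.7),
#'   sequence = "GCG"
#' )
#' @export
step_table <- function(data, sequence = NULL, time_step = 2) {
  data <- as_tibble(data)
  required <- c("snapshot", "step", "tilt", "roll", "twist")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    abort(
      paste0("missing required column(s): ", paste(missing_cols, collapse = ", ")),
      class = "helixbend_format_error"
    )
  }
  if (nrow(data) == 0) {
    abort("a step table needs at least one snapshot and one step",
      class = "helixbend_structure_error"
    )
  }
  optional <- intersect(c("shift", "slide", "rise"), names(data))
  data <- data[, c(required, optional)]
  data$snapshot <- as.integer(data$snapshot)
  data$step <- as.integer(data$step)
  data <- dplyr::arrange(data, .data$snapshot, .data$step)

  steps <- sort(unique(data$step))
  snaps <- unique(data$snapshot)
  if (!identical(steps, seq_along(steps))) {
    abort("step indices must be 1..n_steps with no gaps",
      class = "helixbend_structure_error"
    )
  }
  if (nrow(data) != length(steps) * length(snaps) ||
    !all(data$step == rep(steps, times = length(snaps)))) {
    abort("ragged table: every snapshot must contain the same steps",
      class = "helixbend_structure_error"
    )
  }
  ang <- as.matrix(data[, c("tilt", "roll", "twist")])
  if (!all(is.finite(ang))) {
    abort("non-finite angle values", class = "helixbend_structure_error")
  }
  if (any(abs(ang) >= 180)) {
    abort("step angles must have magnitude < 180 degrees",
      class = "helixbend_structure_error"
    )
  }
  if ("rise" %in% names(data) && any(data$rise <= 0)) {
    abort("rise must be positive", class = "helixbend_structure_error")
  }
  n_steps <- length(steps)
  if (is.null(sequence)) {
    sequence <- paste(rep("N", n_steps + 1), collapse = "")
  }
  sequence <- toupper(sequence)
  if (nchar(sequence) != n_steps + 1) {
    abort(sprintf(
      "sequence length (%d) must equal n_steps + 1 (%d)",
      nchar(sequence), n_steps + 1
    ), class = "helixbend_structure_error")
  }
  if (grepl("[^ACGUTN]", sequence)) {
    abort("sequence may only contain A, C, G, U (T, N tolerated)",
      class = "helixbend_structure_error"
    )
  }
  if (!is.numeric(time_step) || length(time_step) != 1 || time_step <= 0) {
    abort("time_step must be a single positive number (ps)",
      class = "helixbend_structure_error"
    )
  }
  structure(data,
    sequence = sequence, time_step = as.numeric(time_step),
    class = c("step_table", class(data))
  )
}

#' @export
print.step_table <- function(x, ...) {
  cat(sprintf(
    "<step_table> %d snapshots x %d steps, sequence %s, dt = %g ps\n",
    n_snapshots(x), n_steps(x), bp_sequence(x), time_step(x)
  ))
  NextMethod()
}

#' Step-table accessors
#'
#' @param x A `step_table`.
#' @return `n_snapshots()` and `n_steps()` return counts; `bp_sequence()` the
#'   base-pair identity string; `time_step()` the snapshot spacing in ps;
#'   `step_labels()` the dinucleotide label of each step (flanking base
#'   pairs, 5' to 3').
#' @name step_table-accessors
NULL

#' @rdname step_table-accessors
#' @export
n_snapshots <- function(x) length(unique(x$snapshot))

#' @rdname step_table-accessors
#' @export
n_steps <- function(x) length(unique(x$step))

#' @rdname step_table-accessors
#' @export
bp_sequence <- function(x) attr(x, "sequence")

#' @rdname step_table-accessors
#' @export
time_step <- function(x) attr(x, "time_step")

#' @rdname step_table-accessors
#' @export
step_labels <- function(x) {
  s <- strsplit(bp_sequence(x), "")[[1]]
  paste0(s[-length(s)], s[-1])
}

# Angles of one component as an n_snapshots x n_steps matrix (row = snapshot).
# Relies on the validated (snapshot, step) ordering of a step_table.
step_matrix <- function(table, component) {
  matrix(table[[component]], ncol = n_steps(table), byrow = TRUE)
}

rebuild_step_table <- function(data, template, sequence = NULL) {
  step_table(data,
    sequence = sequence %||% bp_sequence(template),
    time_step = time_step(template)
  )
}

#' Restrict a trajectory to its equilibrated central segment
#'
#' Drops `trim_each_end` base pairs from each helix end (removing the
#' corresponding steps and trimming the sequence) and discards an initial
#' equilibration transient, given either as a snapshot count (`burn_in`) or a
#' fraction of the trajectory (`burn_in_frac`, default 0.1). End trimming
#' avoids fraying artefacts; the default 10% burn-in reflects the usual
#' practice of discarding the approach to equilibrium identified on
#' block-averaged RMSD traces.
#'
#' @param table A [step_table()].
#' @param trim_each_end Base pairs dropped from each end. Default 3.
#' @param burn_in Number of initial snapshots to discard. Overrides
#'   `burn_in_frac` when given.
#' @param burn_in_frac Fraction of snapshots to discard from the start.
#' @return A smaller `step_table`; with `trim_each_end = 0` and zero burn-in
#'   the input is returned unchanged.
#' @examples
#' gt <- ground_truth()
#' tab <- generate_trajectory(gt, n_snapshots = 20, seed = 1)
#' sel <- select_segment(tab, trim_each_end = 3, burn_in = 2)
#' n_steps(sel) # 9 steps = central 10 bp of the 16-bp helix
#' @export
select_segment <- function(table, trim_each_end = 3, burn_in = NULL,
                           burn_in_frac = 0) {
  stopifnot(inherits(table, "step_table"))
  ns <- n_snapshots(table)
  nk <- n_steps(table)
  if (is.null(burn_in)) burn_in <- floor(burn_in_frac * ns)
  burn_in <- as.integer(burn_in)
  if (burn_in < 0 || burn_in >= ns) {
    abort("burn_in must leave at least one snapshot",
      class = "helixbend_domain_error"
    )
  }
  keep_steps <- seq_len(nk)
  if (trim_each_end > 0) {
    keep_steps <- keep_steps[keep_steps > trim_each_end &
      keep_steps <= nk - trim_each_end]
  }
  if (length(keep_steps) < 1) {
    abort("trimming removes the whole helix",
      class = "helixbend_domain_error"
    )
  }
  snaps <- unique(table$snapshot)
  keep_snaps <- snaps[seq.int(burn_in + 1L, ns)]
  out <- table[table$step %in% keep_steps & table$snapshot %in% keep_snaps, ]
  out$step <- match(out$step, keep_steps)
  seq_full <- strsplit(bp_sequence(table), "")[[1]]
  seq_keep <- seq_full[seq.int(keep_steps[1], keep_steps[length(keep_steps)] + 1L)]
  rebuild_step_table(out, table, sequence = paste(seq_keep, collapse = ""))
}
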