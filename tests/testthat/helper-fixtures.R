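# Shared fixtures built in code.

# Tiny deterministic table: 2 snapshots x 3 steps, hand-enumerable values.
tiny_table <- function() {
  step_table(
    tibble::tibble(
      snapshot = rep(0:1, each = 3),
      step = rep(1:3, 2),
      tilt = c(1, 2, 3, -1, 0.5, 2),
      roll = c(9, 8, 10, 9.5, 9, 8.5),
      twist = c(32, 33, 31, 32.5, 32, 33),
      rise = 0.2954
    ),
    sequence = "GCAU", time_step = 2
  )
}

# Uniform-scale ground truth whose analyzed statistics match the declared
# stiffness matrix exactly (no sequence-dependent softening).
uniform_gt <- function(...) {
  ground_truth(step_scale = c(AU = 1, GC = 1), ...)
}

# Independent Rodrigues oracle via the matrix exponential (Matrix::expm).
expm_rotation <- function(tilt, roll, twist) {
  K <- matrix(c(0, twist, -roll, -twist, 0, tilt, roll, -tilt, 0), 3, 3)
  as.matrix(Matrix::expm(K))
}
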