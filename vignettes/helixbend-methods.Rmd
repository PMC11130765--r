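---
title: "Estimating nucleic-acid bending elasticity from step parameters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating nucleic-acid bending elasticity from step parameters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(helixbend)
```

## The physical model

A duplex nucleic acid is described at the rigid-base-pair level: each
base-pair step carries three rotations — tilt $\tau$ (bending toward the
backbone), roll $\rho$ (bending into the grooves) and twist $\omega$ — and,
optionally, three translations, of which only the rise (the helical advance
per step, in nm) is used here. To lowest order the elastic energy of a
segment is quadratic in these angles, with separate tilt and roll bending
stiffnesses $A_1$ and $A_2$, a twist stiffness $C$, and a roll–twist
("twist–bend") coupling $G$, all expressed as lengths (nm). Tilt couples
only weakly to the other two modes by the symmetry of the duplex; the
package nevertheless estimates and reports the full $3\times 3$ structure so
that assumption can be checked on data instead of imposed.

Thermal equilibrium of a quadratic energy makes the fluctuations Gaussian,
which yields the central estimator: if $\mathbf{C}$ is the covariance
matrix (rad$^2$) of the *cumulative* angles — each step angle summed over
the analyzed segment of contour length $L_0$ for one snapshot — then the
elastic modulus matrix is

$$\mathbf{K} = k_B T\, \mathbf{C}^{-1} \quad (\mathrm{pN\,nm}),$$

and the stiffness lengths are the elements of $L_0\,\mathbf{C}^{-1}$:
$A_1$ from the tilt–tilt element, $A_2$ from roll–roll, $C$ from
twist–twist, $G$ from roll–twist. With $k_B = 0.0138065$ pN nm K$^{-1}$
(CODATA, rounded to six significant figures), a tilt modulus of
$K_{\tau\tau} = 169.39$ pN nm with $L_0 = 2.954$ nm at $T = 300$ K converts
to $A_1 = 120.80$ nm:

```{r}
persistence_from_modulus(169.39, L0 = 2.954, temperature = 300)
```

The bending anisotropy is summarised by $B = (A_1 - A_2)/2$, zero for
isotropic bending. When all correlations vanish the full inversion
collapses onto the diagonal approximation $A_1 \approx L_0/\sigma_\tau^2$,
$A_2 \approx L_0/\sigma_\rho^2$ (`approximate_stiffness()`); nonzero
roll–twist coupling makes the exact stiffnesses larger than these
approximations, and the package reports both so the size of the correction
is visible.

Independently of the covariance route, the worm-like chain (WLC) describes
bending with a single persistence length $l_B$: the angle $\theta$
subtended by a segment of arc length $l$ has density
$p(\theta) \propto \sin\theta\, \exp[-l_B \theta^2/(2l)]$, so
$\ln[p(\theta)/\sin\theta]$ is quadratic in $\theta$ with curvature
$-l_B/(2l)$ and `wlc_fit()` reports $l_B = -2 l a_2$ from the fitted
quadratic. The two routes answer different questions — the covariance gives
the mode-resolved stiffnesses, the WLC fit the single effective bending
stiffness — and agreement between them is a physical statement, not an
identity.

## The analysis pipeline and its parameters

`read_step_table()` ingests either a flat native TSV or a 3DNA-style
`.par`-like block format (angles in degrees). Snapshots are numbered from 0
so time is snapshot × `time_step` (default 2 ps, the typical storage stride
of the trajectories this format comes from).

Tunable parameters, their defaults and the reasons:

* **`trim_each_end = 3` base pairs.** Terminal base pairs fray and their
  step parameters are not representative of duplex elasticity; trimming
  three from each end of a 16-bp helix leaves the central 10 bp (9 steps)
  analyzed throughout.
* **`burn_in_frac = 0.1`.** Trajectories approach equilibrium from their
  starting structure; the first 10% of snapshots are discarded by default,
  matching the usual practice of cutting the initial rise seen on
  block-averaged RMSD traces (`rmsd_series()` + `block_average()`; the RMSD
  is the raw displacement from the reference snapshot, with no Kabsch
  superposition, so rigid drift is visible by design).
* **`L0`.** The contour length is never inferred silently: `"auto"` uses
  `n_steps × mean(rise)` of the *analyzed* segment, or the caller passes an
  explicit value. Stiffness lengths scale linearly with $L_0$, so a
  mismatch between $L_0$ and the segment actually summed biases all of
  them by the same factor; keeping it explicit makes that choice auditable.
* **Window span 6 bp, profile length `l = (span − 1) × mean(rise)`.**
  Bending angles are pooled over all 6-bp windows (5 steps ≈ 1.477 nm for
  an A-form rise of 0.2954 nm) of all snapshots. The profile length of a
  6-bp window is ambiguous between 5 and 6 rise units; 5 is used (the arc
  between the first and last base-pair frames) and the fitted $l_B$ scales
  linearly with `l`, so the alternative reading is one multiplication away.
  Both are config-exposed.
* **Histogram bin width 1°, fit range 2–25°, `min_count = 10`.** The lower
  cut avoids the noisy $\sin\theta \to 0$ region of the log-density, the
  upper cut stays in the quadratic regime for WLC-like samples, and
  near-empty bins are excluded because the log of a small count is both
  biased and noisy. Weighting the least squares by bin counts reflects the
  $1/\sqrt{\mathrm{count}}$ noise of a log-density. For pooled 6-bp angles
  of a strongly intrinsically bent A-form-like helix (mean roll ≈ 9°, twist
  ≈ 33° per step) the distribution centres near 30–35° — the intrinsic
  superhelical bend, not fluctuation — so `scan_temperatures()` widens its
  default fit window to 2–45° to cover it.
* **Temperature trends.** Unweighted ordinary least squares across the
  temperature points, with standard errors from the usual OLS variance
  estimate. Because least squares is linear and $B = (A_1 - A_2)/2$
  pointwise, the fitted $B$ slope must equal half the difference of the
  $A_1$ and $A_2$ slopes; the scan reports the directly fitted slope, the
  identity value and their difference rather than choosing one silently.

## The synthetic-trajectory generator

`ground_truth()` + `generate_trajectory()` are first-class, tested modules,
not fixtures: they sample the Gaussian ensemble the estimators assume, from
declared parameters, so the whole pipeline can be validated by parameter
recovery. Per step and snapshot, $(\tau, \rho, \omega)$ is multivariate
normal with covariance $\mathrm{rise} \times S(T)^{-1}$, where

$$S(T) = \begin{pmatrix} A_1(T) & g & 0 \\ g & A_2(T) & G \\ 0 & G & C(T)
\end{pmatrix}$$

is the stiffness-length matrix ($g$ is an optional tilt–roll coupling,
default 0, present to exercise the analyzer's full reporting). Steps are
independent, so the cumulative covariance over $n$ steps is exactly
$L_0 S^{-1}$ with $L_0 = n \times \mathrm{rise}$ — the analytic oracle the
recovery tests invert.

Defaults are a dsRNA-like parameterisation at the 300 K reference:
$A_1 = 120.80$, $A_2 = 22.46$, $C = 100$, $G = -20$ nm; intrinsic tilt
0.08°, roll 9.05°, twist 32.7° (A-form); rise 0.2954 nm; the 16-bp sequence
GCGCAAUGGAGUACGC; stiffness softening $dA_1/dT = -0.580$ and
$dA_2/dT = -0.167$ nm K$^{-1}$ with the mean roll growing by
0.021° K$^{-1}$; and steps containing A or U 1.3× softer than G/C steps.
The twist stiffness and its temperature slope (0 by default) and the mean
twist are not constrained by the bending estimators and are config-exposed.
An optional equilibration transient adds an exponentially decaying offset to
the roll mean of early snapshots so burn-in diagnostics have something to
find.

Two deliberate simplifications, and what they mean for the tests:

* **No along-helix correlations.** Real trajectories have correlated
  neighbouring steps; the covariance estimator does not assume them absent,
  but independence gives exact closed-form cumulative covariances for
  oracles. Passing recovery tests therefore validates the estimator
  algebra, not robustness to inter-step coupling.
* **No temporal autocorrelation.** Snapshots are i.i.d.; trajectory
  snapshots 2 ps apart are not, so effective sample sizes on real data are
  smaller than the snapshot count and real uncertainties correspondingly
  larger.

The sequence-dependent multipliers scale each step's whole covariance, so
with non-uniform multipliers the segment-cumulative covariance corresponds
to the *segment-averaged* stiffness (e.g. the default 16-bp helix analyzes
≈ 21% softer than its declared per-step C/G-step stiffnesses). Recovery
tests therefore declare uniform multipliers, where the correspondence is
exact.

Per-temperature seeds derive from the master seed by the stated rule
`(seed + 7919 × round(T)) mod (2^31 − 1)`, so a scan is reproducible both
piecewise and as a whole; equal seeds give bit-identical tables.

## Numerical choices

* Step rotations use the rotation-vector (matrix-exponential) convention,
  evaluated by the closed-form Rodrigues formula with series fallbacks
  below $10^{-4}$ rad; it is symmetric in its components and exactly
  invertible (`extract_step_angles()`, valid below π), and agrees with
  mid-step-triad conventions such as 3DNA's to first order, differing only
  at $O(\text{angle}^2)$ — below the quadratic-energy level at which
  stiffnesses are defined. Absolute angle values from different upstream
  tools can differ at that order.
* The $\arccos$ argument in bending angles is clamped to $[-1, 1]$;
  covariances are inverted via Cholesky (`chol2inv`) with a
  positive-definiteness check that reports the condition number on failure.
* Sample variances use the $n - 1$ denominator throughout; at the snapshot
  counts involved the choice is immaterial but it is stated for
  reproducibility.
* The WLC fit carries a small negative finite-sample bias (≈ 0.4% at
  $10^5$ angles with 1° bins, measured over 200 seeded replicates), from
  bin discretisation and the count-weighting of log-densities; it is well
  inside the fit's own standard error and shrinks with more data.
* Ties in `block_average()` cannot arise (half-open blocks); a final block
  with fewer samples than the first is flagged `partial` rather than
  dropped.

## Problem sizes used by the tests

The test-suite and acceptance problem sizes are chosen so every recovery
has comfortable statistical margin while the whole suite runs in well under
a minute of compute per module: 200,000 snapshots for elastic-constant
recovery (sampling error ≈ 0.3%, tolerance 3%), $5\times10^5$ angles for
the WLC recovery (tolerance 2%), and five temperatures × 50,000 snapshots
for slope recovery (tolerance 10%). File round-trip properties are
exercised at 2,000 snapshots; the property is elementwise and
size-independent.

## Known limitations

* The estimators assume the upstream base-pair frames (and hence step
  angles) are correct; no frame fitting from atomic coordinates is done.
* The RMSD diagnostic is deliberately superposition-free and so conflates
  rigid drift with internal change; it mirrors the displacement-from-start
  convention used for equilibration checks, not a structural-similarity
  measure.
* The WLC fit window must cover the bulk of the pooled angle distribution;
  for strongly intrinsically bent helices the defaults of the single-fit
  API (2–25°) are meant for fluctuation-dominated samples and the scan
  default (2–45°) for A-form-like geometries. A misplaced window raises a
  non-physical-fit error rather than returning a clamped value.
* No sequence-resolved stiffness model is fitted (per-step variances are
  reported, not decomposed), and no force-extension or melting behaviour is
  modelled.
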