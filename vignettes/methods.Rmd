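---
title: "Methods: descriptors, onion clustering and information frustration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: descriptors, onion clustering and information frustration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dynenv)
```

## The problem

A particle system in dynamic coexistence — ice and liquid water at the
melting point, a colloid layer crossed by a motility wave — is locally
heterogeneous: each particle carries, at each instant, a signature of the
environment it currently belongs to, blurred by thermal noise. `dynenv`
turns raw trajectories into per-particle time series of environment
descriptors and then asks, as a function of the time resolution Δt, how
many statistically distinct metastable environments those series support.

Two statistical ideas organize the package. First, an environment is only
real if particles *dwell* in it: classification requires a signal to stay
within a state's band for at least Δt consecutive frames, so Δt acts as a
minimum-lifetime filter rather than a smoothing window. Second, variance
is not relevance: a descriptor component carrying a tiny share of the
dataset variance can separate environments that the dominant components
(or their PCA combinations) cannot, and combining an informative dimension
with a noisy one can *lose* resolvable states ("frustrated information").

## SOAP power spectra

For each center the neighbor density is a sum of Gaussians (width
`sigma_atom`, default 0.5 length units) at the positions of all other
particles within `r_cut`, tapered by a cosine ramp over the outer 10% of
`r_cut` so the descriptor is continuous as neighbors cross the cutoff.
The density is expanded as c~nlm~ in `n_max` orthonormal radial functions
times real spherical harmonics up to `l_max`, and summarized by the
rotation-invariant power spectrum

p~nn′l~ = π √(8/(2l+1)) Σ~m~ c~nlm~ c~n′lm~,

emitted for all ordered radial pairs, giving n_max² (l_max+1) components —
576 at n_max = l_max = 8, 80 at n_max = l_max = 4.

Numerical choices:

* **Radial basis.** Gaussian primitives centered evenly on [0, r_cut]
  with width r_cut/n_max, orthonormalized sequentially (Cholesky-based
  Gram–Schmidt of the numerical overlap matrix under the r² dr measure).
  Different reasonable bases give different coefficient values; the tests
  therefore validate the coefficients against a direct three-dimensional
  quadrature of the density–basis overlap using the *same* basis, and
  validate the spectrum's invariances (rotation, translation, permutation,
  additivity) which hold for any basis.
* **Coefficient evaluation.** Each neighbor contributes through the
  partial-wave kernel 4π Y~lm~(û) ∫ r² g~n~(r) e^((−r²−R²)/2σ²)
  i~l~(rR/σ²) dr with i~l~ the modified spherical Bessel function,
  evaluated in exponentially scaled form (the scaled Bessel times
  e^(−(r−R)²/2σ²)) so no overflow occurs at large r R/σ². The radial
  integral uses 120-point Gauss–Legendre quadrature on
  [0, r_cut + 5 max(width, σ)].
* **Ordering convention.** l varies slowest; within each l block the
  ordered pairs (n, n′) are laid out n-major, 0-based:
  flat = l n_max² + (n−1) n_max + (n′−1). Component #0 is (1,1,0) and,
  at n_max = 8, component #63 is (8,8,0) — the last spherical (l = 0)
  entry. The spherical family is exactly the first n_max² indices.
* **Center inclusion.** The central particle is excluded from its own
  density by default (`include_center = FALSE`): the environment is
  "all other" particles. The flag exists because published pipelines
  differ and the choice only shifts the l = 0 components by a constant.
* **Normalization.** Spectra are not normalized per vector by default;
  an optional flag rescales to unit norm. Variance-based component
  ranking is convention-dependent either way, which is why the ranking
  function reports raw variances rather than percentages of a fixed
  total.

2D trajectories (tracking data) are embedded at z = 0; periodic boxes use
minimum-image neighbor search, with a warning when r_cut exceeds half the
smallest periodic box length.

## Active-matter descriptors

`min_neighbor_distance()` is the distance to the closest other particle (a
density proxy); `local_alignment()` is the mean cosine between a
particle's velocity and its neighbors' within `r_c` (15 pixels is the
conventional choice for tracked Quincke-roller data), bounded in [−1, 1].
The particle itself is excluded from the neighbor sum — self-inclusion
would bias the value toward +1. Particles with no neighbors in range, or
with zero speed, get `NA`: inventing a value for an undefined alignment
would contaminate the clustering, so missing frames simply break runs and
count toward ENV0. Velocities may be supplied or derived as forward
finite differences (`velocities_from_positions()`, periodic-aware).

## Spatial denoising

`spatial_average()` replaces each particle's signal (scalar or vector,
componentwise) by the unweighted mean over the particle and its neighbors
within a cutoff at the same frame. No kernel weighting is applied — the
operation is deliberately the simplest consistent local average, and with
a cutoff spanning a non-periodic box it degenerates to the frame mean.
Denoising of descriptor vectors happens *before* any PCA projection, so
projections are of denoised data rather than the reverse. Note the
averaging radius matters near thin interfaces: averaging across a
boundary layer only a couple of particle diameters thick mixes the two
phases' signatures, which on very small toy systems can blur states
rather than sharpen them (the test suite's smallest two-phase fixture
resolves its phases best without denoising, while ensembles with many
particles per environment benefit from it).

## Variance views

`descriptor_pca()` pools all (particle, frame) rows — the ergodic view in
which temporal order is ignored — performs covariance PCA (correlation
PCA via `scale. = TRUE`), and reshapes the leading scores back to
per-particle series, which is what "the PC1 time series" means throughout.
PC signs are fixed by making each loading's largest-magnitude entry
positive, since eigenvector signs are otherwise arbitrary and
reproducibility across platforms matters more than any particular
orientation. `component_variances()` ranks raw components and tags each
as spherical (l = 0) or angular (l > 0) when SOAP metadata is present.

## Onion clustering

`onion(x, delta_t)` peels Gaussian states from an ensemble of N series of
length T (univariate or d-variate):

1. estimate the probability density of all currently unassigned points —
   univariate: Gaussian KDE with Silverman's bandwidth; multivariate:
   a d-dimensional histogram with Freedman–Diaconis bins per axis;
2. fit a Gaussian to the highest peak: univariate, nonlinear least
   squares of A e^(−(x−μ)²/2σ²) against the KDE restricted to the local
   minima flanking the peak (fallback: moments of the points in that
   window); multivariate, trimmed moments seeded from the peak cell,
   iterated with a Mahalanobis trim at `k_sigma`;
3. assign every maximal contiguous run of ≥ Δt frames whose points all
   lie within μ ± k_sigma σ (Mahalanobis ≤ k_sigma) to the state;
4. remove assigned points and repeat until a candidate state gains less
   than `min_population` (default 1%) of all points; finally dissolve
   any state that ends below 1% into ENV0 and re-fit each surviving
   state's parameters once from its assigned points.

Numerical choices that required a decision:

* **`k_sigma` (default 3).** The assignment rule is strict — one
  excursion breaks a run. At ±2σ a genuinely in-state Gaussian point
  escapes with probability 4.6%, fragmenting long dwells into segments
  of mean length ≈ 22 frames and pushing >10% of perfectly clean
  two-state data into ENV0; at ±3σ the escape rate is 0.27% (mean
  segment ≈ 370 frames), which keeps clean states classifiable across
  the Δt range while still separating states a few σ apart. The value
  is a parameter and is echoed in the fitted object.
* **Bandwidth deconvolution.** The KDE peak is the state Gaussian
  convolved with the kernel, so the fitted spread is corrected to
  √(σ_fit² − bw²). Without this, the univariate spread is inflated by
  the (multimodality-driven) Silverman bandwidth while the multivariate
  moment fit is not, and the two paths disagree on identical data.
* **Truncation correction.** Trimmed moments at Mahalanobis k
  underestimate the covariance by the chi-square factor
  P(χ²~d+2~ ≤ k²)/P(χ²~d~ ≤ k²); each trim pass divides by it.
  The multivariate covariance additionally floors eigenvalues at
  max(10⁻¹⁸, 10⁻¹⁰ λ_max) so exactly collinear inputs (a signal
  combined with a copy of itself) remain usable.
* **Merging.** A re-fitted Gaussian whose mean lies within one spread of
  an existing state (Mahalanobis < 1) is the same state seen through its
  leftover tail points; its runs are assigned to the existing state
  instead of minting a duplicate.
* **Degeneracies and ties.** A zero-variance point set gets spread 10⁻⁹;
  equal-height peaks resolve to the lower mean (the density grid is
  scanned in increasing order); missing values break runs and are never
  classified; states are reported in increasing-mean order.

`delta_t_scan()` repeats the fit over a log-spaced integer grid of about
30 window lengths from 2 frames to T (endpoints forced), reporting the
state count and ENV0 fraction per Δt. `predict()` classifies new series
against the fitted states; `plot()` shows the fitted Gaussians over the
data density (univariate) or the labelled scatter (bivariate).

## Frustration, detection windows, sampling scans

`frustration_gap()` aligns three scans (two univariate, one combined) on
one Δt grid and reports max(n₁, n₂) − n₁₂ both raw and clamped at zero —
the clamped part is the information lost by combining the dimensions; a
negative raw gap (the combination resolving *more* states) is legitimate
and is preserved in `gap_raw`. `detection_window()` extracts the maximal
grid intervals where at least k states are resolved; windows are reported
grid-wise, with no interpolation between scanned resolutions, because
interpolating a step function of Δt would manufacture precision.
`sampling_scan()` resamples the ensemble by integer strides (frames kept:
1, 1+s, 1+2s, …; dt multiplied by s), rescans, and reports windows in
absolute time so they are comparable across strides. Since strides change
the grid, cross-stride agreement is judged to within one grid step of the
coarser scan — the finest statement the discrete scans support.

## The synthetic generators

The generators produce exactly the statistical structure the clustering
assumes, plus ground-truth labels:

* `gen_state_ensemble()`: independent hidden Markov chains with Gaussian
  emissions. The master seed spawns separate substreams for the state
  paths and the emission noise, so the two can be varied independently;
  identical seeds give bit-identical output.
* `gen_two_phase_toy()`: a cubic-lattice slab (site + i.i.d. Gaussian
  jitter) against a reflected-random-walk liquid at ~90% of the lattice
  density, with particles within one lattice constant of the slab
  boundary stochastically swapping behavior — a minimal analogue of an
  interface layer with short residence times. The slab is non-periodic
  along x, so it has genuine surface layers: a frozen slab exposes
  several *static* environments, not one.
* `gen_wave_toy()`: a static 2D particle field traversed by a periodic
  band of coherent +x motion over isotropic jitter — the minimal analogue
  of a velocity wave crossing a driven colloid layer. Positions are
  fixed so band membership is a pure geometric sweep.

The reference fixture used throughout the tests is a three-state chain
with outer dwells of 1000 frames, a middle (interface-like) dwell of 50
frames, emission σ = 0.25 at means −2/0/2; the frustration fixture pairs
that signal with a second dimension that distinguishes only the two outer
states and carries noise σ = 4 — twice the middle state's separation from
its neighbors. These sizes (up to 200 series × 5000 frames for recovery
runs, 100 × 1000–2000 with 10–12-point Δt grids for scan-based suites, 20
seeds for stochastic claims) keep a full suite run in a few minutes while
leaving each state thousands of points.

What the generators do *not* emulate: spatial correlation between
neighboring particles' signals (each series is independent), non-Gaussian
emission tails, drifts, or any coupling between descriptor components
beyond shared labels. Passing tests therefore demonstrate the pipeline's
correctness under its own model assumptions — not that real MD or
tracking data satisfy those assumptions.

## Known limitations

* The SOAP implementation is single-species, without gradients, and not
  bit-compatible with other codes' radial bases; cross-code comparisons
  should be made on invariants and on relative component structure.
* Onion clustering inherits the resolution limits of density estimation:
  states whose peak is buried under a dominant state's tail are found
  only after the dominant state is peeled, and states below the 1%
  population floor are unrecoverable by design.
* At very large Δt the strict run rule classifies little (ENV0 → 1);
  this is a feature of the lifetime semantics, not a convergence failure.
* The pipeline treats time in frames internally; physical-time
  comparisons are only as good as the `dt` metadata on the containers.
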