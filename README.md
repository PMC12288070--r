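# dynenv

Detection of dynamical environments in noisy particle trajectories.

Molecular and colloidal systems are often a patchwork of coexisting local
environments — solid and liquid domains, interfaces, moving flocks — that
exchange particles over time. `dynenv` implements a complete pipeline for
extracting such environments from raw trajectories:

1. **Descriptors.** Per-particle, per-frame signals: single-species SOAP
   (Smooth Overlap of Atomic Positions) power spectra
   *p<sub>nn′l</sub>* = π √(8/(2l+1)) Σ<sub>m</sub> c<sub>nlm</sub> c<sub>n′lm</sub>,
   where c<sub>nlm</sub> are the expansion coefficients of the
   Gaussian-smeared neighbor density in an orthonormal radial basis times
   real spherical harmonics; and, for active-matter (tracking) data, the
   minimum neighbor distance d<sub>min</sub> and the local velocity
   alignment φ<sub>i</sub> = (1/n<sub>c</sub><sup>i</sup>) Σ<sub>j</sub>
   **v**<sub>i</sub>·**v**<sub>j</sub>/(|**v**<sub>i</sub>||**v**<sub>j</sub>|).
2. **Spatial denoising.** Each particle's signal is averaged with its
   neighbors' within a cutoff (the "\_dn" variants), suppressing
   uncorrelated noise while keeping the environment signal.
3. **Variance views.** Covariance PCA of the pooled descriptor dataset with
   explained-variance accounting, and per-component variance ranking split
   into spherical (l = 0) and angular (l > 0) families.
4. **Onion clustering.** Iterative Gaussian peeling of single-particle time
   series at a time resolution Δt: only signal stretches that dwell in a
   state for at least Δt frames are classified; states below 1% population
   dissolve into the unclassified cluster ENV0. A scan over Δt (from 2
   frames to the whole trajectory) maps which environments are resolvable
   at which time resolutions.
5. **Frustration diagnostics.** The information lost when dimensions are
   combined, max(n₁, n₂) − n₁₂ cluster counts per Δt; detection windows
   for a target state count; and sampling-frequency (stride) scans.

Ground-truth-labelled synthetic generators (Markov-switching Gaussian
ensembles, a two-phase lattice/liquid toy with an exchanging interface, a
coherent velocity wave through a 2D particle field) make every stage
testable end to end.

The package is aimed at researchers in molecular simulation and soft
matter who want to find metastable states and their lifetimes in
high-dimensional, noisy per-particle signals — and to see when *adding*
dimensions destroys information rather than adding it.

## Worked example

Three metastable states: two long-lived phases (mean dwell 1000 frames) at
signal levels −2 and +2, exchanging through a short-lived interface state
(mean dwell 50 frames) at 0, all with emission noise σ = 0.25:

```r
library(dynenv)
tr <- matrix(c(0.999, 0.001, 0,
               0.01,  0.98,  0.01,
               0,     0.001, 0.999), 3, 3, byrow = TRUE)
spec <- markov_spec(c(-2, 0, 2), 0.25, tr)
sim <- gen_state_ensemble(spec, n_series = 200, n_frames = 5000, seed = 1)

fit <- onion(sim$ensemble, delta_t = 10)
summary(fit)
#> Onion clustering at delta_t = 10 frames
#>  state          mean    spread population
#>      1 -2.0005133024 0.2463906   0.485393
#>      2  0.0005106616 0.2463489   0.053547
#>      3  2.0002877656 0.2464186   0.456681
#> ENV0 fraction: 0.0044
```

At a fine time resolution (Δt = 10 frames) all three generating states are
recovered, with means and spreads matching the ground truth and under 0.5%
of points unclassified. At a coarse resolution the interface state — whose
dwells rarely reach 200 frames — disappears into ENV0:

```r
delta_t_scan(sim$ensemble, grid = c(2, 10, 50, 200, 1000, 5000))
#>  delta_t_frames delta_t_time n_states env0_fraction
#>               2            2        3      0.002769
#>              10           10        3      0.004379
#>              50           50        3      0.035728
#>             200          200        2      0.229384
#>            1000         1000        2      0.920811
#>            5000         5000        0      1.000000
```

The `n_states` column is the blue curve of an onion scan plot, the
`env0_fraction` column the orange one: the short-lived environment is
detectable only in a window of time resolutions bounded above by its dwell
time. `frustration_gap()` compares such scans for two single dimensions
against their bivariate combination, and `sampling_scan()` repeats the
analysis at reduced sampling frequencies.

SOAP descriptors for a trajectory come from
`soap_descriptors(traj, soap_params(r_cut = 10, n_max = 8, l_max = 8))`
(576 components per particle per frame; component #63 is the all-radial
(n = n′ = 8, l = 0) term), alignment signals from
`local_alignment(traj, r_c = 15)`, denoised variants from
`spatial_average(series, traj, cutoff)`, and `run_pipeline()` chains all
stages from a single JSON-serializable config.

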