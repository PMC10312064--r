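# synaptrack

Single-particle tracking analysis of synaptic receptor surface mobility.

Membrane receptors such as NMDA receptors reach and leave the synapse by
lateral diffusion. Live-cell tracking of quantum-dot- or dye-labelled
receptors produces thousands of trajectories per field of view, and the
scientific questions — how mobile is a receptor subtype, how much of it is
synaptic, how long does it stay, how fast does it exchange with the
extrasynaptic membrane — all hinge on a chain of careful geometry and
statistics. `synaptrack` implements that chain as tidyverse-style R
functions (tibbles in, tibbles out), for researchers analysing
single-particle tracking experiments in neurons and for method developers
who need a fully simulatable reference pipeline.

## What it computes

* **Detection & linking** — Laplacian-of-Gaussian spot detection with
  subpixel refinement; optimal frame-to-frame assignment (cost = squared
  displacement, links forbidden beyond 0.25 µm) with greedy gap closing
  (≤ 0.5 µm, ≤ 10 missed frames).
* **Drift correction** — fiducial-free: the median frame-to-frame
  displacement over the whole trajectory ensemble, accumulated and
  anchored to the first frame, is subtracted from every track.
* **Synaptic regions** — subpixel polygons from a scaffold-marker image
  (4× bicubic oversampling, refined centers, half-maximum contours),
  uniform 120 nm buffering, and 25 nm concentric distance zones.
* **Classification** — three standard rules: >50 % of localizations
  inside the region (Method 1), inside the 120 nm-buffered region
  (Method 2), or mean distance to the nearest synapse center < 550 nm
  (Method 3).
* **Mobility** — time-averaged MSD per trajectory; the short-time
  diffusion coefficient `D = slope/4` from an ordinary least-squares fit
  of the first five lag points with a free intercept that absorbs the
  localization-noise offset `4σ²`; mean frame-to-frame displacements;
  D-versus-distance and D-versus-synaptic-fraction profiles.
* **Kinetics** — per-frame synaptic/extrasynaptic labelling, merging of
  visits shorter than 3 frames (≤ 100 ms at 50 ms sampling), synaptic
  residence time and exchange rate for trajectories with ≥ 4 transitions,
  and log-scale summaries for these right-skewed quantities.
* **Localization density** — signed distance-to-edge histograms and
  zone densities (counts per µm² in each 25 nm band).
* **Auxiliary models** — single-species FCS autocorrelation
  `G(t) = 1 + N⁻¹(1 + t/τ_D)⁻¹(1 + S⁻²t/τ_D)^(-1/2)` with dye
  calibration (`ω² = 4Dτ_D`) and Stokes–Einstein radius
  `R_H = k_BT/(6πηD)`; Hill concentration–response
  `I = I_max/(1 + (EC₅₀/c)^h)`; biexponential desensitization with the
  weighted constant `τ_des = (τ_f A_f + τ_s A_s)/(A_f + A_s)`; and
  fixed-probe localization error (pooled per-axis SD).
* **Synthetic data** — a seeded generator for every input: two-state
  Brownian trajectories with confined synaptic motion, marker images,
  FCS curves, dose–response data, desensitization traces and fixed
  probes, all with ground truth returned.

## A worked example

Simulate one field of view — 60 tracked receptors switching between three
synapses, with drift, noise and missed detections — then run the whole
pipeline:

```r
library(synaptrack)

cfg <- sim_config(seed = 7, n_frames = 300, frame_interval = 0.05,
                  D_syn = 0.002, D_extra = 0.05,
                  dwell_syn = 3, dwell_extra = 2,
                  synapse_centers = matrix(c(3, 3, 9, 3, 6, 8), 3, byrow = TRUE),
                  loc_noise_sigma = 0.007, p_missed = 0.02,
                  field_size = c(12, 12),
                  drift = list(mode = "linear", rate = c(0.001, -0.0005)))
sim <- simulate_trajectories(cfg, 60)
img <- simulate_marker_image(cfg)

res <- run_pipeline(trajectories = sim$trajectories, marker_image = img,
                    seed = 7)

res$regions[, 1:4]
#> # A tibble: 3 × 4
#>   region_id  x_um  y_um area_um2
#>       <int> <dbl> <dbl>    <dbl>
#> 1         1  3.00  3.00    0.251
#> 2         2  9.00  3.00    0.251
#> 3         3  6.00  8.00    0.252

dplyr::count(res$classifications, label)
#> # A tibble: 2 × 2
#>   label             n
#>   <chr>         <int>
#> 1 extrasynaptic    10
#> 2 synaptic         50

median(res$diffusion$D_um2_s)
#> [1] 0.04422342

log_summary(residence_time(res$visits))
#> # A tibble: 1 × 7
#>       n mean_log sd_log geo_mean ci_lo ci_hi median
#>   <int>    <dbl>  <dbl>    <dbl> <dbl> <dbl>  <dbl>
#> 1    48    0.660  0.823     1.93  1.52  2.46   2.08
```

The three marker puncta (Gaussian σ = 240 nm) are recovered as ~0.25 µm²
half-maximum polygons — the analytic value is π(σ√(2 ln 2))² ≈ 0.2509 µm².
50 of 60 trajectories are synaptic by the >50 % rule, matching the
simulated 3 s / 2 s dwell split plus the boundary-lingering bias the
vignette discusses. The residence-time summary is computed on the log
scale (these durations are right-skewed): the geometric mean of 1.93 s and
median of 2.08 s sit below the simulated 3 s mean dwell because visits are
clipped by the 15 s observation window and transitions shorter than 100 ms
are filtered.

`plot_trajectories(res$trajectories, res$regions)`,
`plot_msd()`, `plot_drift()`, `plot_density_profile()` and
`plot_D_profile()` give ggplot views of each result; `tidy()` and
`glance()` work on every model fit.

See `vignettes/synaptrack-methods.Rmd` for the models, parameter choices,
numerical details and limitations.

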