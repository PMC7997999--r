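# melanokin

Quantitative analysis of intracellular organelle transport from tracked 2D
trajectories, built for brightfield video microscopy of pigmented
melanosomes but applicable to any slowly moving, pixel-resolution-tracked
cargo.

Melanosomes are carried along microtubules by kinesin (outward,
centrifugal) and dynein (inward, centripetal) motors. Perturbing one arm of
this tug-of-war — for example knocking down a dynein light chain — changes
how far melanosomes travel, how often they pause, and how *directional*
their trajectories are. `melanokin` provides the full measurement chain
needed to quantify such phenotypes from tracking-plugin output:

- **Kinematic descriptors** per trajectory: total distance (sum of
  frame-to-frame step lengths), Euclidean (start-to-end) distance, average
  distance per frame and average velocity, pause fraction (steps whose
  pixel-quantized displacement is exactly zero; 1 pixel = 0.16 μm by
  default), and net centrifugal/centripetal direction relative to the
  nucleus.
- **MSD power-law analysis**: the time-averaged mean-square displacement
  MSD(τ) = ⟨[r(t+τ) − r(t)]²⟩ is fitted with *b·τ^α* by log–log least
  squares. α ≈ 1 indicates diffusion (MSD = 4Dτ in 2D), α = 2 pure
  directional transport (MSD = V²τ²), α < 1 tethered/confined motion or
  localization noise (which offsets the MSD by 4σ²).
- **Directional/non-directional classification**: each trajectory is
  summarized by its second moments of displacement at a short and a long
  lag, (μ2S, μ2L). In the log10(μ2L) vs log10(μ2S) plane, slope-1 frontier
  lines calibrated on a simulated Brownian reference (for which
  s = log10 μ2L − log10 μ2S is independent of D) split trajectories into
  directional (D), non-directional (ND) and an intermediate uncertainty
  band; the same frontiers are applied to every population, and the D count
  is reported as a range [n_D, n_D + n_intermediate].
- **Perinuclear quantification**: particles ≥ 150 nm are counted inside the
  band extending 2 μm outward from the nucleus border, clipped to the cell
  outline, and normalized by the band area.
- **Group statistics**: unpaired two-sided rank-sum (Mann–Whitney/Wilcoxon)
  tests — exact by enumeration for small samples, even with the heavy ties
  that quantized descriptors produce — and Welch t-tests.
- **A seeded simulation toolkit** generating Brownian, directional,
  drifting, tethered (exact Ornstein–Uhlenbeck) and confined (reflected)
  trajectories with localization noise and pixel quantization, so every
  stage above can be validated against planted ground truth.

## Worked example

Simulate two 75-trajectory populations at the default acquisition settings
(601 frames at 0.5 s, 0.16 μm pixels): a control-like mix dominated by
diffusive/tethered motion, and a knockdown-like mix with a larger, faster
directional fraction. Then run the whole pipeline:

```r
library(melanokin)

config <- list(
  seed = 42, quantize = TRUE,
  populations = list(list(label = "wt_like", preset = "wt_like", n = 75),
                     list(label = "kd_like", preset = "knockdown_like", n = 75)),
  classify = list(n_reference = 2000))
report <- run_pipeline(config)
print(report)
#> Trajectory-analysis report
#>   wt_like: n = 75, mean total 12.79 um, mean pause 0.87, directional 15-15
#>   kd_like: n = 75, mean total 20.09 um, mean pause 0.81, directional 40-41
#>   4 pairwise comparisons computed

compare_alpha(report$alphas$wt_like, report$alphas$kd_like)
#> wt_like vs kd_like (mann_whitney): n = 75/75, mean = 0.631/1.244,
#>   statistic = 1029, two-sided p = 2.06e-11
```

The knockdown-like population travels farther per 5-minute recording
(20.1 vs 12.8 μm mean total distance), pauses less (81% vs 87% of steps),
carries 40–41 directional trajectories out of 75 against 15 for the
control-like mix, and its α distribution is shifted to the right
(p ≈ 2×10⁻¹¹) — the transport signature expected when retrograde dynein
transport is impaired.

Individual stages are plain functions: `read_tracks()` /
`write_tracks()` for plugin tables, `summarize_population()` for
descriptors, `compute_msd()` + `fit_power_law()` for α,
`calibrate_frontiers()` + `count_directional()` for classification,
`perinuclear_density()` for spatial quantification. A thin command-line
wrapper lives at `inst/scripts/melanokin-report.R`.

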