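# nactin

Simulation and quantification of calcium-triggered nuclear actin assembly
(NAA).

Stimulation of GPCR/calcium signalling triggers a transient burst of actin
polymerization inside the nucleus: filaments appear within tens of seconds,
elongate at ~1.5 µm/s, persist for ~50 s, and disappear again. In live-cell
imaging this is read out indirectly — an F-actin chromobody probe that is
uniform in the resting nucleus becomes spatially heterogeneous as filaments
concentrate it — and the accompanying chromatin response is measured in
electron microscopy as the fraction of the nucleus occupied by electron-dense
heterochromatin. `nactin` packages the quantitative core of that workflow for
people who want to analyse such experiments or test the analysis itself:

* **simulator** — two-channel (actin probe + calcium sensor) nuclear
  time-lapses with Poisson-process filament nucleation (mean inter-arrival
  τ = 20 s, onset latency 16 s after the stimulus), constant 1.5 µm/s
  elongation inside a 10-µm nuclear disc, exponential filament lifetimes
  (mean 50 s), Gaussian PSF and Poisson shot noise, with full ground truth
  retained;
* **quantification** — the NAA statistic: the spatial intensity variance
  (population variance over the nuclear ROI,
  $\sigma^2 = \tfrac{1}{N}\sum_i (I_i - \bar I)^2$), its min–max
  normalization, ROI mean traces for the calcium channel, and a
  `baseline + k·sd` per-cell positive/negative score with
  `percent_positive()`;
* **temporal analysis** — sustained half-max onset detection with linear
  interpolation, calcium-to-NAA lag estimation, and validation that the
  heterogeneity trace tracks ground-truth filament mass (Spearman);
* **EM chromatin** — four-class pixel segmentation (heterochromatin /
  euchromatin / nucleolus / background) by deterministic k-means, a binary
  heterochromatin mask, the nuclear area fraction it covers, and a synthetic
  EM-image generator with exact ground truth.

## Worked example

```r
library(nactin)

tl <- simulate_timelapse(seed = 1)
tl
#> <timelapse> 51 frames (0.0-150.0 s), channels: actin_probe, calcium,
#>   120 x 120 px (0.100 um/px), 6 nucleation events

het <- heterogeneity_trace(tl)     # spatial intensity variance per frame
ca  <- roi_mean_trace(tl)          # nuclear calcium trace

estimate_lag(ca, het)
#> <lag_result> lag 42.52 s (NAA 74.39 s, calcium 31.87 s)

score_cell(het, tl$stimulus_time_s)
#> <cell_score> POSITIVE (peak 120 vs baseline 101 +/- 1.7)

validate_heterogeneity_proxy(tl, het)
#> <proxy_validation> Spearman rho = 0.772 over 51 frames
```

The lag is positive: the half-max onset of the heterogeneity (NAA) trace comes
42.5 s after the nuclear calcium onset in this run — nucleation cannot start
until 16 s after the stimulus and the statistic needs filament mass to clear
its shot-noise floor, whereas the calcium transient rises within seconds. The
cell is scored NAA-positive because its post-stimulus peak variance (120
photons²) exceeds the pre-stimulus baseline (101 ± 1.7) by more than 5
standard deviations, and the heterogeneity trace rank-correlates with the
ground-truth filament length per frame (ρ = 0.77 under shot noise; exactly 1
noise-free for nested growth).

EM side:

```r
syn <- generate_em_image(0.35, seed = 1)     # ground-truth fraction 0.350
measure_chromatin(syn$image, syn$nucleus_mask)
#> <chromatin_stats> 4195 / 12831 px heterochromatin (fraction 0.327)
```

The segmentation recovers the known heterochromatin fraction to within 0.023
on this image.

A command-line front end covering `simulate`, `quantify`, `lag`, `em-synth`,
`em-quant` and `run-all` is installed at
`system.file("cli.R", package = "nactin")`; `run_pipeline()` is the same
entry point as a function. See `vignettes/nactin-methods.Rmd` for the models,
defaults and design decisions.

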