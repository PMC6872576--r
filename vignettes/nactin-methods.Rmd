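---
title: "Models and methods behind nactin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind nactin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

nactin implements the quantitative workflow around transient nuclear actin
assembly (NAA): a stochastic simulator of two-channel nuclear time-lapses, the
spatial intensity-variance statistic used to read out NAA, onset/lag analysis
relating NAA to calcium elevation, per-cell positive scoring, and an EM
heterochromatin area-fraction measurement. This vignette explains the models,
the defaults, and the design choices; nothing here states an empirical result
that the test suite or `scripts/acceptance.R` does not itself compute.

## The filament kinetics model

The nucleus is a 2-D disc, 10 µm in diameter. After a stimulus at
`stimulus_time_s`, filament nucleation is a homogeneous Poisson process that
starts after a deterministic latency (default 16 s, matching the observed
delay between ionophore addition and the first polymerization) with mean
inter-arrival time 20 s. Inter-arrival times are i.i.d. exponential, so the
event count over a window $T$ has mean $T/\tau$ and the process is memoryless.
Each filament:

* nucleates at a uniformly random interior point with a uniformly random
  direction (`origin_mode = "uniform_interior"`), or, in
  `"inm_anchored"` mode, on the nuclear boundary with an inward-pointing
  direction — filaments elongating from the inner nuclear membrane. Both
  observations appear in live-cell data; neither mode is privileged, the
  interior mode is the default because it matches the validation simulation
  the statistic was designed against.
* elongates at a constant 1.5 µm/s; the tip clamps at the nuclear boundary
  (the positive root of $|o + L d - c| = r$ along the growth ray);
* disappears instantaneously after an exponential lifetime with mean 50 s
  (polymerization persisted for ~50 s before depolymerizing). No shrink
  phase is modelled because only the lifetime, not the depolymerization
  kinetics, is characterized; an exponential is the maximum-entropy choice
  given a mean.

## Rendering and noise

The actin-probe channel has expected intensity `background_mean_photons`
(default 100) at every nucleus pixel and 0 outside, plus each filament's line
signal — `filament_gain_photons_per_um` (default 1000) per µm of length,
rasterized with anti-aliased bilinear deposition at 0.25-px steps — convolved
with an isotropic Gaussian PSF (σ = 0.2 µm, a typical confocal lateral width).
With `noise = "poisson"` every pixel is an independent Poisson draw of its
expectation: pure shot noise, which dominates the unstimulated probe signal.
Rendering is additive by default; a `conserve_total` flag redistributes
(rather than adds) intensity so the total expected photon count is invariant
to filament content. The heterogeneity statistic responds to either convention;
additive is the default because the probe's filament-bound enrichment is not
mass-calibrated.

The calcium channel is spatially uniform per compartment: a
difference-of-exponentials transient
$A\,(e^{-t/\tau_d} - e^{-t/\tau_r})$, rescaled to peak amplitude, on a
constant baseline, with the nuclear compartment delayed by `nuclear_delay_s`.
Defaults (baseline 50, amplitude 150, rise 2 s, decay 15 s, delay 1 s) are
phenomenological values typical of fast GCaMP transients; the source study
measures but does not parameterize the transient, so this channel is plumbing
for the temporal analysis, not a claim about calcium dynamics.

Default acquisition: one frame every 3 s (the acquisitions being emulated used
2–4 s), 150 s duration, stimulus at 30 s. The pre-stimulus window of 10 frames
exists to give the scoring rule a usable baseline; three frames are the hard
minimum. The 120 × 120 px grid at 0.1 µm/px keeps a full 10-µm nucleus with
margin; population runs default to 72 × 72 px at 0.15 µm/px so that scoring
hundreds of cells stays light — the statistic is intensive and unaffected by
the grid beyond sampling noise.

## The heterogeneity statistic and its normalization

NAA is scored by the population variance (divide by $N$) of actin-probe pixel
intensities inside the nuclear ROI. Uniform probe + shot noise puts the
statistic at its Poisson floor (variance ≈ mean); filaments concentrate signal
and raise it; depolymerization returns it to the floor. The population
convention is deliberate: this is a descriptive statistic of the full ROI, not
an inference about a larger population of pixels. Traces are min–max
normalized ("by the changing range"); a flat trace normalizes to zeros with a
`degenerate` flag rather than an error, because non-responding cells are
expected inputs.

The simulator exists to validate this proxy: per-frame ground-truth filament
length is retained, and `validate_heterogeneity_proxy()` reports the Spearman
correlation between filament mass and the heterogeneity trace. Under noise-free
rendering with nested filament growth the correlation is exactly 1 (additive
rendering is monotone in added signal); across whole noise-free simulations two
*different* filament configurations with nearly equal total length can swap
ranks, so exact unity is asserted only where the monotonicity argument applies.

## Onset, lag and scoring rules

The source observation is an order — NAA followed calcium elevation — without
a stated onset rule, so the package declares one: the first time a normalized
trace crosses a threshold (default 0.5, half-max) and stays above it for
`sustain_frames = 2` frames, with the crossing time linearly interpolated
between the bracketing frames. Half-max sustained crossing is parameter-light
and robust to single-frame noise; the lag (`NAA onset − calcium onset`,
nuclear calcium by default since NAA is nuclear) is exactly equivariant under
time shifts, which the tests assert. Onset is monotone non-decreasing in the
threshold.

Per-cell scoring replaces the by-eye "filaments detectable" call with a
z-type rule: positive iff the post-stimulus peak of the *raw* heterogeneity
trace exceeds `baseline_mean + k * baseline_sd` over the pre-stimulus frames,
`k = 5` by default. The rule is scale-covariant (multiplying all intensities
rescales both sides), but its detection power depends on the Poisson
signal-to-noise, so the tests assert empirical power and false-positive rate
on simulated responders and non-responders rather than algebraic invariance.
`percent_positive()` is the positive count over the total, as a percentage.

## EM heterochromatin quantification

The EM workflow reimplements a four-class pixel labelling (heterochromatin,
euchromatin, nucleolus, extranuclear background; electron-dense = dark)
followed by a binary heterochromatin mask and the fraction of nuclear pixels
it covers. In place of an interactively trained classifier, segmentation is
unsupervised: k-means (k = 4) on a per-pixel feature vector (raw intensity,
Gaussian-smoothed intensity at σ = 1 and 2 px, local standard deviation) with
deterministic initialization. The initial centres sit at four intensity
landmarks — the mean of the darkest 2% of nuclear pixels, the nuclear median,
the midpoint of those two, and the extranuclear median. Landmarks rather than
fixed global quantiles are used because class proportions vary wildly between
images: on background-dominated frames, fixed quantiles of the global
histogram place several centres on the background mode and the dark classes
merge.

Clusters map to classes by statistics, never by index (so any relabelling of
clusters leaves the result unchanged): the lightest outside-dominant cluster
is background; the darkest remaining cluster is heterochromatin; within the
dark-intermediate cluster, connected components of at least
`min_nucleolus_px` (150) pixels become nucleolus, while the thin remainder —
blurred heterochromatin-patch rims whose mixed gray level lands between the
classes — is split between heterochromatin and euchromatin at their intensity
midpoint. Without that split the rim band systematically erodes the measured
patches and biases the fraction downward. Everything outside the nucleus mask
is background. The nucleus mask is user-supplied (nuclei were manually
segmented in the source workflow) or derived by smoothing + Otsu threshold,
hole filling and largest-component selection; no attempt is made at robust
nucleus detection on difficult real-world EM. The fraction's denominator
includes the nucleolus by default (the nucleus is everything inside the
nuclear boundary); `exclude_nucleolus = TRUE` removes it, since the original
accounting is unstated.

The synthetic EM generator draws an elliptical nucleus, one compact nucleolus,
and heterochromatin patches carved as the top-$k$ pixels of a smoothed
Gaussian random field biased toward the nuclear rim (where heterochromatin
preferentially sits), with $k$ chosen so the ground-truth fraction is exact.
Class gray levels (0.28 / 0.42 / 0.62 / 0.85) and Gaussian texture noise
(σ = 0.04) give contrast comparable to stained thin sections; a 0.7-px blur
softens class boundaries. The generator does not emulate section artefacts,
uneven staining, or membrane ultrastructure — recovery results on it bound the
method's behaviour under clean contrast, not on degraded real sections.

## Numerical choices and degenerate inputs

* All stochastic entry points take an explicit integer seed; child seeds are
  derived from a master seed, global RNG state is saved and restored, and
  identical seeds give bit-identical stacks.
* Physical coordinates are µm with the origin at the top-left pixel centre;
  pixel membership in the nucleus disc is centre-in-disc.
* Zero-range traces normalize to zeros with a flag; onset on a degenerate
  trace is absent, not an error; a missing onset makes the lag absent with a
  stated reason.
* The Gaussian-blur kernel is capped at the image size so tiny images remain
  valid inputs.
* Constant (blank) EM images raise a segmentation error; images with no
  convincing dark region segment as all-background.
* Variance uses a single numerically stable two-pass form; the tests compare
  it against an independently coded oracle at 1e-9 relative tolerance.

## Problem sizes used in the tests

Unit tests run on 4-µm nuclei in 60 × 60 px frames and 60-s acquisitions; the
end-to-end checks use the full default configuration (10 µm, 120 × 120 px,
150 s, 51 frames) with 20–50 replicate simulations, 300-cell populations on
the coarser population grid, and 20 synthetic EM images per ground-truth
fraction in {0.1, 0.2, 0.35, 0.5}. These sizes make the stochastic assertions
stable at the stated tolerances while keeping the whole suite to a couple of
minutes.

## Known limitations

* 2-D nuclei only; no probe binding chemistry, photobleaching, or
  mechanochemical filament models.
* The calcium transient is phenomenological; lag estimates on simulations
  validate the estimator, not calcium biology.
* The scoring rule's power and false-positive rate are properties of the
  simulated noise model; on real data they depend on acquisition settings and
  should be re-examined per dataset.
* EM segmentation assumes the four classes are intensity-separable; heavily
  textured or unevenly stained sections may need the supplied-mask route and
  parameter adjustment.
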