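---
title: "Digital bead assay quantification: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Digital bead assay quantification: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's account of the science it implements: the
statistical model behind the digital readout, what the synthetic micrograph
generator does and does not emulate, the numerical choices in each stage,
and the design decisions taken where more than one reasonable option
existed.

## 1. The digital counting model

A bead suspension is exposed to analyte; each bead captures a number of
molecules that is well described as Poisson(λ), with

λ = κ · C · η,

where C is the analyte concentration (ng/mL), κ converts concentration to
expected molecules per bead (it absorbs bead count, volume, affinity and
kinetics), and η is the probability that a captured molecule is
successfully converted into an amplified, fluorescent label. On-bead
amplification makes a *single* labeled molecule detectable, so a bead is
"on" iff it carries ≥ 1 labeled molecule:

P(on) = 1 − e^(−λ)   ⇒   AMB = −ln(1 − f_on)

estimates λ from the observed on-fraction f_on. `amb_from_fraction()` is
this inversion; `compute_amb()` applies it to counts. The delta-method
standard error, `amb_se()`, is √(f_on / ((1 − f_on) n)).

Two non-obvious consequences shape the package's estimators:

* **The threshold has a built-in false-positive rate.** "On" beads are
  those whose maximum pixel exceeds the blank Gaussian's mean + 2 SD, so a
  true blank bead is "on" with probability 1 − Φ(2) ≈ 0.02275, and a blank
  *measurement* has AMB ≈ −ln(1 − 0.02275) ≈ 0.0230, not 0. When the goal
  is estimating λ itself (rather than calibrating against a curve, where
  the blank offset is absorbed by the lower asymptote), the package's
  examples subtract the measured blank AMB; the variance of the corrected
  estimator is the sum of the two delta-method variances. Because one
  threshold (fitted on the pooled blank) is shared by all conditions,
  threshold-estimation noise largely cancels in the difference.
* **Saturation.** When all beads (or all but one) are on, the inversion
  diverges. `compute_amb()` then reports the capped value at
  (n − 0.5)/n on-beads and sets `saturated = TRUE`: a finite lower bound,
  never infinity or NaN. Downstream, the pipeline's calibration excludes
  saturated points from the fit, since they carry a bound, not an estimate.

## 2. What the synthetic generator emulates

`simulate_bead_loading()` draws per-bead molecule counts i.i.d.
Poisson(λ); `render_frames()` images a Binomial(n_beads, imaged_fraction)
subset of the population spread uniformly over `n_frames` fields of view.
The defaults (imaged_fraction = 0.21, n_frames = 120) mirror the practical
acquisition regime in which roughly a fifth of the bead suspension is
ever imaged, across 100–150 fields. Key rendering choices:

* **Geometry.** Beads are filled disks of mean radius `bead_radius_px`
  (default 5 px, a ~2.8 µm bead at moderate magnification) with 5% relative
  radius jitter; centers are rejection-sampled so no two beads in a frame
  are closer than 2.2× radius and no bead is clipped by the border. This
  is deliberate: the detection contract is defined for resolvable disks,
  and clumped or clipped beads are what a practitioner excludes anyway. An
  `allow_overlap` switch exists for stress testing. Coordinates are
  0-based (row, col) at pixel centers; all radii in pixels.
* **Intensities.** "Off" beads draw their peak from Normal(blank_mean,
  blank_sd) — the blank is Gaussian by assumption, matching the analysis
  that fits it with a Gaussian — and "on" beads from
  LogNormal(on_intensity_mu, on_intensity_sigma): positive and
  right-skewed, as amplified signals are. No instrument publishes these
  parameters in absolute units, so the defaults (blank 1500 ± 120 a.u.,
  "on" median 8000 a.u., σ_log = 0.4, on a 300 a.u. background in a 16-bit
  range) were chosen once to sit comfortably in the separable regime the
  assay requires; the constructor warns if a configuration leaves it.
  Fluorescence disks are flat at the drawn peak, so with noise off the
  disk maximum equals the drawn peak exactly — the property the
  noiseless rendering tests assert.
* **Noise.** Per-pixel Gaussian read noise (default 30 a.u.) plus a
  *per-frame* background offset (`background_jitter_sd`, default 30 a.u.,
  10% of background). The per-frame term emulates illumination and
  autofluorescence drift between fields — a feature of real micrographs
  that a constant-background simulator would miss. It shifts all pixels of
  a frame jointly: the analog (frame-mean) readout inherits it directly,
  while the digital classification is nearly immune (bead peaks and the
  blank distribution shift together, and the marginal blank stays
  Gaussian). This asymmetry is precisely the robustness argument for
  digital readouts, so the generator must contain it for the
  digital-vs-analog comparison to be meaningful.

**What is not modeled:** optical point-spread functions (disks have sharp
edges), amplification-reaction kinetics, bead clumping, focus variation,
frame-to-frame bead duplication at field borders, and sample-matrix
chemistry (a matrix can be emulated only coarsely as elevated blank_sd or
reduced κ). Passing tests on this generator therefore validate the
*statistical* chain — detection, thresholding, inversion, calibration — not
robustness to real-world optical artifacts.

## 3. Bead detection

`detect_beads()` is a gradient circular Hough accumulator: Sobel edge
pixels vote along their gradient direction at each candidate radius
(integer steps over [radius_min, radius_max], default the nominal radius
± 40%); votes are pooled over 3×3 bins and normalized by the circle
perimeter 2πr. Peaks above (1 − sensitivity) perimeter-fractions are
accepted greedily, merging anything closer than `min_separation` and
keeping the stronger peak. Numerical details worth knowing:

* Edge pixels are selected adaptively (95th percentile of gradient
  magnitude, with a floor of 0.2× the maximum) plus a robust noise floor of
  6× the *median* magnitude. Since most pixels are background, the median
  estimates the noise scale; a pure-noise frame then yields no edge pixels
  at all, and blank or constant frames return an empty detection list
  rather than an error.
* Centers are refined to sub-pixel precision by vote centroiding over the
  3×3 peak neighbourhood; radii by the median center-distance of edge
  pixels whose gradient points at the center (within cos⁻¹ 0.8).
* Circles extending past the border are discarded, with a half-pixel
  tolerance: the intensity read is over pixel centers, and no pixel center
  is lost until a disk extends more than 0.5 px beyond the outermost pixel
  center. Without the tolerance, the detector's small (~0.1 px) outward
  radius bias would discard legitimate beads sitting exactly at one radius
  from the border.
* Polarity is a flag: dark disks on a bright field (brightfield) or bright
  on dark (darkfield); nothing else in the pipeline changes between the
  two. No flat-field correction is applied.

`extract_bead_intensity()` defines "within the circle" as *pixel center
inside or on the circle* — deterministic and testable against brute-force
pixel enumeration. The detector's acceptance is by contract, not by
implementation: recall and precision ≥ 0.99 with ≤ 1 px center error on
noiseless non-overlapping disks, and ≥ 0.95 recall at the default noisy
density.

## 4. Quantification

`fit_blank()` uses moment estimators (sample mean, n−1 SD) — the Gaussian
MLE up to the variance denominator — with no histogram binning or trimming.
A configurable floor (default 30 beads) guards against meaningless fits and
a zero-variance blank is an error. "Above the threshold" is resolved as
*strictly* greater, so ties count as "off" — the conservative choice for
false positives. The threshold is computed per experiment from that
experiment's own blank condition. The analog readout is the unweighted
grand mean over all pixels of all fluorescence frames — beads and
background, no masking — and is independent of frame order.

## 5. Calibration and LOD

The 4PL is fixed as f(x) = d + (a − d)/(1 + (x/c)^b), the standard Hill
form: f(0) = a, f(∞) = d, monotone for b > 0. Fitting choices:

* **Linear response scale.** The fit minimizes least squares of the
  response (AMB or a.u.) against *linear* concentration; log–log axes are
  presentation only. Fitting log(AMB) would be an alternative; linear AMB
  was adopted because the digital response's sampling error is known on
  the linear scale (binomial counting), which also motivates the weighting
  below.
* **Blank handling.** x = 0 is a removable boundary of the Hill form, so
  the blank is excluded from the residuals; it initializes `a` and defines
  the LOD level. Multi-start (b ∈ {0.5, 1, 2} × c at the geometric
  quartiles of x) with Levenberg–Marquardt (`minpack.lm::nlsLM`, c and b
  bounded positive) takes the best converged fit; flat responses raise a
  fit-failure, and non-monotone level means beyond ~2 replicate SDs raise
  a warning, not an error.
* **Weighting.** `fit_4pl()` is unweighted by default. The *pipeline's*
  digital calibration weights each point by 1/SE², with the delta-method
  SE from that point's own (f_on, n) — model-based weights, stable even
  with 3 replicates. This matters because AMB values span orders of
  magnitude across a ladder: unweighted, the top of the curve dominates
  and the lower asymptote can drift above the LOD level, leaving the LOD
  undefined. The analog readout is roughly homoscedastic and stays
  unweighted.
* **LOD.** y_lod = blank mean + 3·blank SD *across blank replicate
  measurements*, on the same readout scale as the curve. The LOD
  concentration is the closed-form inverse x = c·((a − d)/(y_lod − d) −
  1)^(1/b), cross-checked internally against `uniroot`; if y_lod does not
  lie strictly between the fitted asymptotes the package raises an
  `lod-undefined` error rather than clipping. Mass equivalents use
  mass [pg] = concentration [ng/mL] × volume [µL], exact for decimal
  inputs. Increasing blank SD can never decrease the LOD (tested as a
  property).

**Blank replicates.** Because the blank SD enters the LOD with only
(replicates − 1) degrees of freedom, a 3-replicate SD is highly unstable
(it falls below 0.6 of the true σ about 40% of the time), which can push
y_lod below the fitted lower asymptote purely by chance. The dilution
series generator therefore supports `blank_replicates` > `replicates`, and
the package's own comparison experiments measure the blank 10 times while
keeping 3 replicates per positive calibrator — the same asymmetry that
formal limit-of-blank protocols (e.g. CLSI EP17) prescribe. The ladder in
those experiments also includes a near-blank anchor concentration so the
lower asymptote is data-anchored.

## 6. The digital-vs-analog comparison

Both readouts are computed from the *same* rendered frame sets, so the
comparison is matched by construction: digital = AMB from counted beads,
analog = frame-mean intensity, each calibrated with its own 4PL and its own
blank statistics, each LOD on its own scale. Digital wins because at low λ
its signal (extra "on" beads over a 2.275% floor) is resolved against
binomial counting noise, whereas the analog signal (a small shift of the
frame mean) must be resolved against frame-level background drift that
counting is immune to. The package asserts the direction (digital LOD <
analog LOD), not a specific ratio: the magnitude depends on optics defaults
that real instruments would override.

## 7. Problem sizes and reproducibility

All simulation functions are pure functions of their arguments and an
integer seed (`with_seed` restores the caller's RNG state), and the
dilution-series driver derives per-run seeds reproducibly from one master
seed, so reruns are bit-identical down to the TIFF bytes. The package's own
validation experiments use sizes chosen to make sampling error small
relative to the tested tolerances while remaining desk-scale: 10^5–10^6
beads for closed-form Poisson/Gaussian checks, 2×10^4 beads over 120
frames at the 21% imaged fraction for end-to-end λ recovery
(λ ∈ [0.05, 1]), 500 disks for the detector contract, and a 9-level ladder
(blank + 0.03–100 ng/mL, 3 replicates, 10 blank replicates, 4000 beads per
run) for the LOD comparison.

## 8. Known limitations

* The detector is specified for resolvable, non-overlapping disks; there
  is no declumping, no tracking across frames, and no deduplication of
  beads imaged twice at adjacent field borders (frames are treated as
  independent samples).
* AMB assumes every labeled molecule renders its bead detectably "on";
  partial labeling is absorbed into η and cannot be separated from κ by
  this package.
* The capped saturated AMB is a reporting convenience, not an estimator;
  quantification above f_on ≈ 1 − 1/n requires fewer beads or dilution.
* Real micrograph artifacts (PSF blur, vignetting, debris, focus drift)
  are outside the generator; results on real TIFF stacks depend on
  detector parameter choices (`detection_params()`) that the synthetic
  regime cannot validate.
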