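---
title: "Modelling and measuring biological washout from point-source PET"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and measuring biological washout from point-source PET}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(washoutpet)
```

## The problem

PET-based dose monitoring in hadron therapy images the β⁺ activity the
beam induces in tissue. Between irradiation and imaging, part of that
activity is transported away biologically — by perfusion and diffusion —
so the measured distribution underestimates and distorts the produced
one. Quantifying this *washout* per tissue is the purpose of the
point-source protocol this package implements: inject a ~1 µL deposit of
a ¹¹C tracer directly into the tissue, acquire a dynamic PET series
starting at injection, and repeat the acquisition post mortem, where
perfusion is absent but passive diffusion remains.

## Model and assumptions

The measured activity factorizes into biology and physics,
$A_{meas}(t) = A_0\,C_{bio}(t)\,A_{phys}(t)$, with
$A_{phys}(t) = e^{-\lambda_{phys} t}$ the physical decay of the isotope.
After decay correction the biological part is modelled as the product of
two mono-exponential components,

$$C_{bio,alive}(t) = e^{-\lambda_{wash} t} e^{-\lambda_{tiss} t},
\qquad C_{bio,dead}(t) = e^{-\lambda_{tiss} t},$$

so the alive-condition decay constant is the *sum* of the two rates. The
assumptions this encodes:

* the deposit acts as a point source — transport out of the ROI is what
  is measured, not redistribution within it;
* passive diffusion is unchanged by death, so the dead acquisition
  isolates $\lambda_{tiss}$;
* each component is adequately described by a single exponential over
  the one-hour acquisition. The classical three-exponential
  (fast/medium/slow) washout parameterization is retained as an optional
  model (`fit_mizuno()`), with fractions constrained to the simplex and
  rates ordered; with one component it reduces exactly to the
  single-exponential fit.

Results are reported as half-lives $T_{1/2} = \ln 2/\lambda$. A rate of
zero is legal (no washout) and reported as an infinite half-life rather
than an error, which makes the dead condition a parameter subset of the
alive one.

The ¹¹C physical half-life is fixed at 1223.4 s (20.39 min, standard
nuclear data) in `isotope_11c()`; any other isotope can be supplied via
`isotope_spec()`.

## What the simulator emulates

`simulate_study()` generates the study the analysis expects, for testing
and power exploration:

* **Acquisition**: 25 frames — 10×30 s, 5×60 s, 10×300 s (3600 s total),
  starting at injection. Frame values are time-*averages* over the frame,
  computed in closed form, because a scanner histograms counts; fitting
  frame midpoints instead would bias rates by order $(\lambda\Delta t)^2/24$
  on the 300 s frames.
* **Spatial model**: the imaged spot is an isotropic Gaussian whose
  variance is the quadrature sum of the deposit spread and the scanner
  PSF (default 1.5 mm FWHM). The default deposit spread is
  `source_sigma = 0.6` mm — the linear scale of a 1 µL sphere (radius
  0.62 mm) — giving a predicted spot FWHM of
  $\sqrt{1.5^2 + (2.3548\cdot 0.6)^2} = 2.06$ mm, within the 2–3 mm range
  typical of such injections. Voxel weights are integrated Gaussians
  (differences of the normal CDF over voxel edges), so mass is conserved
  exactly on the grid; sources closer than 3 PSF FWHM to the boundary are
  rejected with the truncated mass fraction reported.
* **Counting statistics**: expected counts per voxel and frame are
  `weight × activity × sensitivity × duration` (default sensitivity 10%,
  injected activity drawn from 0.7–1.1 MBq); Poisson noise is optional
  and seeded. In noiseless mode expectations are returned exactly, which
  is what makes sub-0.1% parameter recovery testable.
* **Biological variability**: per-animal rates are drawn lognormally
  around the group mean. The default coefficient of variation of 0.1 is a
  package choice producing SD-to-mean ratios of the magnitude seen in
  small-animal groups; it is a free knob, not a measured quantity.
  Default group size is N = 4.
* **Determinism**: all randomness flows from the single study seed;
  per-series sub-seeds are drawn from it and recorded, so reruns are
  bit-identical.

What it does *not* emulate: attenuation, scatter, randoms,
reconstruction artefacts (images are produced post-reconstruction with
those corrections assumed ideal), motion, partial-volume effects, and
any non-exponential kinetics such as the post-mortem pressure transient
seen in tumors. Passing recovery tests therefore demonstrate that the
estimator chain is unbiased under the model's own assumptions — not that
real tissue obeys the model.

## The extraction and fitting pipeline

* **ROI rule**: voxels strictly above 50% of the first-frame maximum
  (`select_roi()`). "Strictly above" replaces a manual selection with a
  deterministic rule; the peak voxel always qualifies. All qualifying
  voxels are taken — for a point source this coincides with the central
  connected blob.
* **TAC**: the mask is fixed and applied to every frame; values are ROI
  *sums* converted to activity (counts / sensitivity / duration). Sums
  and means differ by a constant factor and give identical half-lives;
  the choice is recorded in the TAC provenance.
* **Decay correction** divides each frame by the frame-averaged physical
  decay factor — exact for histogrammed counts of a purely physical
  exponential. For a decaying *biological* signal the frame average of a
  product is not the product of frame averages, leaving a residual bias
  of order $\lambda_{bio}\lambda_{phys}\Delta t^2/12$ on 300 s frames;
  this is well inside the recovery tolerances tested and is the standard
  correction scanners apply.
* **Fitting** (`fit_single_exponential()`): unweighted least squares of
  the frame-averaged model, initialized at the log-linear regression
  slope over positive frames and refined by Levenberg–Marquardt with
  rates bounded at zero. Optional Poisson (inverse-variance) weighting is
  available; unweighted is the default since no weighting scheme is
  canonical for this protocol. Non-positive frames are excluded from the
  log-linear initialization; fewer than three usable frames is an error;
  non-convergence is flagged, never silent. A fitted rate whose total
  decay across the window is below 10⁻⁹ is reported as an infinite
  half-life.
* **Fit window**: defaults to the full acquisition. Tumor dead-condition
  data can show an early transient from post-mortem pressure
  re-equilibration; the documented recipe is `window = c(600, Inf)` for
  that case.
* **Decomposition** (`decompose_washout()`): the default `"subtraction"`
  mode computes $\lambda_{wash} = \lambda_{alive} - \lambda_{tiss}$,
  which is what the product-of-exponentials model implies. A `"direct"`
  mode reporting the alive rate unmodified is provided because published
  descriptions of the protocol can be read either way; the package
  treats subtraction as correct and self-consistent (the simulator's
  alive curves carry the summed rate). If the alive rate does not exceed
  the dead rate the result is flagged "no detectable washout" with an
  infinite half-life, not an error.
* **Multi-exponential fits** use variable projection: the outer
  optimization runs over log rates (Brent for one component,
  Nelder–Mead with a polish restart otherwise) while amplitudes are
  solved by non-negative least squares, which enforces the simplex
  constraint by construction. Rates that collapse within 0.1% are merged
  and the fit flagged, with the log-rate gap as diagnostic.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `psf_fwhm` | 1.5 | mm | scanner resolution |
| `sensitivity` | 0.10 | – | counts per decay |
| `source_sigma` | 0.6 | mm | deposit spread |
| `activity` | 0.7–1.1×10⁶ | Bq | injected activity range |
| `threshold_fraction` | 0.5 | – | ROI isocontour |
| `inter_animal_cv` | 0.1 | – | biological spread |
| `n_animals` | 4 | – | group size |
| `half_life` (¹¹C) | 1223.4 | s | physical decay |

Tissue presets (`tissue_presets()`) store published group-mean
half-lives as generative defaults: brain 2878/330 s, muscle 2132/361 s,
tumor 2019/621 s (tissular/washout), with necrotic (613 s) and active
(418 s) tumor washout regimes sharing the tumor tissular value.

## Problem sizes and verification

The test-suite and acceptance experiments run on a 32³ grid of 0.5 mm
voxels (24³ in the fastest unit tests), one animal per noiseless
recovery, and 20 seeded replicates for the Poisson-noise experiment at
0.9 MBq and 10% sensitivity — sizes chosen so the full chain remains a
few seconds while keeping first-frame counts at the realistic ~2.7×10⁶
scale. Noiseless recoveries through the full image pipeline reproduce
the generative tissular half-lives to well within 0.5% and washout
half-lives to within 1%; the Poisson experiment recovers the brain
washout group mean to within 5%. These figures are computed, not quoted:
see `tests/testthat/test-acceptance.R` and `scripts/acceptance.R`.

## Known limitations

* The two-condition design assumes the tissue is otherwise unchanged by
  death; pressure-driven transients in tumors violate this early in the
  acquisition and are handled only by the fit window.
* Decay correction by frame-averaged factors leaves the small cross-term
  bias noted above; it is negligible at these rates but grows with
  $\lambda \Delta t$.
* The noise model is pure Poisson counting statistics scaled by a global
  sensitivity; reconstruction noise correlations are not modelled, so
  real-data uncertainties will be larger than simulated ones.
* No compartmental modelling, blood input functions, motion or
  partial-volume correction: the method is deliberately source-local.
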