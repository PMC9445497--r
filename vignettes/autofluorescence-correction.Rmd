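---
title: "Spectral autofluorescence correction by inter-channel regression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectral autofluorescence correction by inter-channel regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(saibr)
```

## The problem and the model

In many specimens — *C. elegans* embryos are the motivating case — endogenous
autofluorescence (AF) from yolk and gut granules contributes a large and
variable share of the signal measured in a GFP acquisition channel. AF varies
both spatially within a sample and by roughly two-fold in overall magnitude
between samples, so subtracting one cohort-average AF scalar leaves large
errors and can even produce apparently negative protein concentrations in dim
strains.

The correction implemented here exploits the breadth of the AF emission
spectrum. Alongside the primary channel \(G\) (GFP-like: 488 nm excitation,
~535 nm emission), a red-shifted *AF predictor channel* \(A\) is acquired
under the same excitation. Because AF behaves as a single spectral component,
its contributions to the two channels are linearly proportional, while the
narrow GFP emission contributes almost nothing to \(A\). Per pixel,

\[
G = G_{\mathrm{gfp}} + G_{\mathrm{af}}, \qquad
G_{\mathrm{af}} = m\,A + c ,
\]

with \(c\) absorbing the background-offset difference between the channels.
On unlabeled samples \(G_{\mathrm{gfp}} = 0\), so ordinary least squares of
pooled pixel values \(g\) on \(a\) recovers \((m, c)\); applied to an
experimental image, \(\widehat{AF} = m A + c\) is subtracted pixel-wise to
leave the true fluorophore signal. With a red fluorophore present, 488 nm
illumination weakly excites it and inflates \(A\); the RFP-specific channel
\(R\) (itself essentially AF-free) then enters as a second predictor,

\[
G_{\mathrm{af}} = m_1 A + m_2 R + c ,
\]

fitted on red-fluorophore-only samples. Since RFP adds to \(A\) but not to
\(G_{\mathrm{af}}\), the fitted \(m_2\) is negative (for bleedthrough slope
\(k\) into \(A\), \(m_2 = -m_1 k\)).

## Calibration choices

**Pixel pooling and filtering.** Calibration pools all ROI pixels from the
calibration stacks; ROIs should cover the whole sample plus a little
background, which anchors the intercept (the pool diagnostic
`low_intensity_fraction` reports the share of near-background pixels). Raw
pixel pairs correlate poorly because independent read noise enters both
channels, so each channel is Gaussian-smoothed before regression. The default
radius is 2 px (configurable; useful values are 1–2): the larger default
favors stability on noisy detectors. Boundary handling is symmetric
reflection so border pixels are not darkened into the pool. Saturated pixels
at a declared bit-depth maximum are excluded with a logged count, since
saturation breaks linearity.

**One global line.** A single \((m, c)\) is fitted across all pooled
samples. Per-sample slopes, intercepts and \(R^2\) are reported as
diagnostics only — they feed `prediction_se()`, the between-sample standard
error of the inferred AF, which treats the calibration sample (not the pixel)
as the unit of replication; pooled-OLS standard errors are overconfident once
smoothing has correlated neighbouring pixels. Fewer than three calibration
samples triggers a warning, not an error. The solver is `lm`'s QR
decomposition; for exact inputs it reproduces hand-solved normal equations to
floating-point accuracy.

**Whole-sample mode.** `fit_whole_sample()` runs the same regression on one
ROI-mean observation per sample. Because both estimators target the same
generating line, pixel and whole-sample coefficients agree on homogeneous
cohorts; the pixel method simply has far more observations and is the
default.

## Correction choices

At correction time the predictor channels are smoothed at the model's stored
radius and the primary channel is not: subtraction otherwise combines pixel
noise from every channel, and smoothing only the predictors suppresses that
amplification at full primary-channel resolution. The trade-off is fidelity
of the AF estimate where AF changes abruptly — most visibly at a sample's
edge, where smoothing smears the AF step a few pixels in both directions.
Two practical consequences, both visible in the tests:

* ROI means should be taken over a region that contains the whole smeared
  edge (the sample plus a narrow margin); there the smearing cancels exactly
  because the filter preserves total intensity.
* For sharp structures such as cross-membrane linescans,
  `filter_predictors = FALSE` evaluates the model on raw predictors and
  avoids any edge blur, at the cost of passing AF-channel noise through at
  slope \(m\).

The corrected image is signed and negative values are never clipped: they
are the diagnostic signature of over-subtraction (for example, a two-channel
model applied to a red-fluorophore-expressing sample), summarized by
`overcorrection_report()`. A zero-clipped copy is available for display
exports only.

**Exact decomposition.** The inferred AF image is quantized to multiples of
\(2^{-26}\) detector units (a perturbation below \(10^{-8}\), orders of
magnitude under any detector noise). For integer-valued detector images
below \(2^{26}\) counts this places `primary`, `inferred_af` and `corrected`
on one binary grid, so `corrected + inferred_af` reproduces the primary
channel bit-for-bit.

**Spillover.** The long GFP emission tail leaks a fraction \(s\) of true
fluorophore signal into \(A\), inflating the inferred AF in proportion to
the signal itself; uncompensated, the corrected image is scaled by
\(1 - m s\). Because the effect is purely proportional it can be ignored for
normalized comparisons, or compensated by dividing by \(1 - m s\)
(`s` stored in the model; `m s < 1` required). `estimate_spillover()`
determines \(s\) in a second pass from fluorophore-bright samples: each
stack is corrected with the base model, the filtered AF channel and the
filtered first-pass corrected image are centered per sample (removing each
sample's AF level), pooled, and regressed through the origin; the slope
\(b = s/(1-ms)\) gives \(\hat s = b/(1+mb)\). This assumes residual AF
texture is spatially uncorrelated with the fluorophore layout, which is why
the estimation ROIs should cover the sample interior — ROIs spanning the
sample boundary couple the two spatial supports and bias \(b\) upward. When
fluorophore variation does not exceed AF variation in the corrected image,
\(s\) is declared unidentifiable and set to 0 with a warning rather than
fitted from leakage; a negative estimate within noise is likewise reported
as 0.

## Quantification

`roi_mean()` and `coefficient_of_variation()` (sample sd over mean) follow
the usual definitions. `cross_membrane_profiles()` samples the image along
local normals of a user-supplied membrane contour — 50 px profiles at 1 px
arc steps by default — using Keys bicubic convolution interpolation
(\(a = -0.5\); exact on locally quadratic images). Pixel centers sit at
integer coordinates, x rightwards, y downwards; the distance axis is
centered on the membrane with negative values outside, resolved from the
contour's signed area so either winding works. Profiles leaving the frame
are dropped with a count. `average_profiles()` averages pointwise over a
contiguous arc fraction centered on a user-supplied anchor (e.g. a posterior
pole); no axis-detection heuristic is attempted.

## The synthetic scene generator

End-to-end validation uses simulated scenes whose latent components obey the
channel model exactly and are stored as ground truth. Each scene renders a
fixed elliptical "embryo" in a 64×96 px frame (about 2 500 embryo pixels;
the stack ROI adds a background margin):

* **AF field**: white noise smoothed at a 6 px correlation length, scaled to
  a per-sample level drawn uniformly over a 2:1 range (mean 400 AF-channel
  units) — the observed ~2-fold inter-sample variation — with 25% relative
  spatial texture at the default scale. Texture amplitude is referenced to
  the default correlation length, so longer correlation lengths flatten the
  field (constant in the limit). An optional interior void mimics local AF
  exclusion.
* **Fluorophore layouts**: none, uniform cytoplasm, a Gaussian-profile
  membrane band along the ellipse boundary (ground-truth profile peak at
  distance 0), or cytoplasm with a nuclear void.
* **Channel truths**: `m_true = 1.8`, `c_true = 100` (AF mapping),
  optional RFP bleedthrough into \(A\) and GFP spillover `s_true`.
* **Noise**: additive Gaussian (sd 10 detector units by default), optional
  signal-proportional variance, and rounding to integer counts as a camera
  would (`quantize = FALSE` exposes the exact latent identities).

All randomness flows from one explicit seed (scene \(i\) of a cohort uses
`seed + i`), so every simulation is bit-reproducible. What the generator
does *not* emulate: optics (no point-spread function), photobleaching,
motion between channels, and realistic AF spectra — passing tests show the
estimators are correct under the stated linear model, not that any
particular specimen satisfies that model. A deliberately pathological second
AF component with a different inter-channel slope is available
(`af_extra_amplitude`) to exercise the known failure mode: with two
independently varying AF sources a single linear predictor cannot represent
the mixture, and calibration \(R^2\) visibly degrades. Likewise, eggshell-type
fluorescence is handled by the ordinary three-channel path with an
eggshell-bearing calibration set; eggshell and a red fluorophore cannot be
compensated simultaneously.

## Numerical and scale choices

Tests and the acceptance analysis run on desk-scale problems chosen to keep
Monte-Carlo error well inside the asserted tolerances: cohorts of 5–20
scenes, pixel pools of \(10^2\)–\(4\times10^4\), and 8–20 scenes for
cohort-level claims (the dose-ratio analysis uses 10 + 10 + 10 scenes and
recovers the 2:1 full/half-dose ratio to well within 5%). Model JSON stores
coefficients at 17 significant digits (exact double round trip) with a
schema version; files written by a newer schema are refused. Because the
TIFF writer stores unsigned integer samples, signed corrected images are
written as 32-bit samples of affinely rescaled values with the offset/scale
in a JSON sidecar — a round trip is exact to one part in \(2^{32}\) and
idempotent after the first save.

## Known limitations

* One AF component: multiple independently varying AF sources are out of
  scope by design (see above).
* Calibration and experimental images must share acquisition settings; the
  tool warns on shape/bit-depth mismatches but cannot detect changed
  excitation or emission parameters.
* No registration, segmentation, or 3-D handling beyond plane-by-plane use;
  membrane contours and ROI masks are supplied by the user.
* Spillover estimation requires genuinely bright samples; with weak
  expression it reports 0 rather than an estimate dominated by leakage.
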