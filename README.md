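# saibr

Spectral autofluorescence correction for multi-channel fluorescence
microscopy, as a scriptable R package with a command-line front end.

## The problem

In specimens such as *C. elegans* embryos, endogenous autofluorescence (AF)
can account for a large fraction of the signal measured in a GFP channel,
varies spatially within each sample, and varies ~2-fold in magnitude between
samples. Subtracting a single cohort-average AF value therefore corrupts
quantification — dim reporters can even come out negative. This package
implements per-pixel spectral AF correction: because AF has a broad emission
spectrum, its contribution to the GFP channel can be predicted from a
red-shifted AF channel acquired under the same excitation and subtracted
pixel by pixel.

## The model

Per pixel, observed primary-channel signal decomposes additively, and the AF
components of the two channels are linearly proportional:

```
G = G_gfp + G_af,    G_af = m·A + c            (two-channel)
G_af = m1·A + m2·R + c                         (three-channel)
```

`(m, c)` are fitted by ordinary least squares on Gaussian-prefiltered pixel
values pooled from the ROIs of unlabeled calibration samples (for which
`G = G_af`). The three-channel form adds the RFP-specific channel `R` as a
second predictor, fitted on RFP-only samples, to absorb red-fluorophore
bleedthrough into `A` (so `m2 < 0`). Correction evaluates the fitted mapping
on an experimental image's predictor channels and subtracts it:
`corrected = G − (m·A + c)`, with optional rescaling by `1/(1 − m·s)` to
compensate the small proportional spillover `s` of fluorophore emission into
the AF channel. Negative corrected values are kept — they diagnose
over-subtraction (e.g. a two-channel model applied to an RFP-expressing
sample).

A fully synthetic scene generator with stored per-pixel ground truth
(`scene_params()`, `make_scene()`, `make_cohort()`) makes the whole pipeline
testable end to end without any real data.

## Worked example

```r
library(saibr)

# 1. Calibrate on simulated unlabeled samples
calib <- make_cohort(scene_params(seed = 1), 5)
model <- saibr_calibrate(scene_stacks(calib))
model
#> <saibr_model> two_channel (pixel): m = 1.80037, c = 99.7679
#>   R^2 = 0.9999 on 18,920 pixels, filter radius 2 px

# 2. Correct a labeled sample (ROI = embryo plus margin)
labeled <- make_scene(scene_params(gfp_layout = "uniform_cytoplasm",
                                   gfp_amplitude = 300, seed = 42))
res <- saibr_correct(labeled$stack, model)
res
#> <saibr_correction> scene_00042: ROI mean 880.8 raw -> 192.4 corrected; 30.5% negative
mean(labeled$truth$G_gfp[labeled$stack$roi])  # ground truth
#> [1] 192.1776

# 3. Over-subtraction diagnostics over the embryo itself
emb <- labeled$stack; emb$roi <- embryo_mask(labeled)
overcorrection_report(saibr_correct(emb, model))
#>   sample_id   negative_fraction mean_negative flagged
#> 1 scene_00042                 0             0 FALSE

rfp <- make_scene(scene_params(rfp_bleed = 0.3, rfp_amplitude = 800,
                               include_rfp = TRUE,
                               gfp_layout = "uniform_cytoplasm",
                               gfp_amplitude = 300, seed = 43))
emb_rfp <- rfp$stack; emb_rfp$roi <- embryo_mask(rfp)
overcorrection_report(saibr_correct(emb_rfp, model))  # wrong mode: flagged
#>   sample_id   negative_fraction mean_negative flagged
#> 1 scene_00043             0.822         -123. TRUE
```

The calibration slope recovers the generator's truth (`m_true = 1.8`,
`c_true = 100`) to a fraction of a percent, the corrected ROI mean matches
the ground-truth fluorophore mean (192.4 vs 192.2 detector units; the raw
mean was 880.8), and the 30.5% negative pixels in the full ROI are just
noise in the GFP-free background margin. The same correction applied to a
red-fluorophore-expressing sample is caught by the diagnostic: 82% of embryo
pixels go negative until the three-channel model is used instead.

Fitted models are tibble-friendly (`tidy()`, `glance()`), plot via
`autoplot()`, and serialize to versioned JSON (`save_model()` /
`load_model()`). Quantification helpers cover ROI means, coefficients of
variation, and averaged cross-membrane linescan profiles
(`cross_membrane_profiles()`, `average_profiles()`).

## Command line

A thin CLI over the same functions lives at `inst/cli/afcorrect.R`
(installed under `system.file("cli", "afcorrect.R", package = "saibr")`):

```sh
afcorrect simulate  --preset unlabeled --n 10 --seed 17 --out calib/
afcorrect calibrate --unlabeled calib/ --mode 2ch --out model.json
afcorrect correct   --model model.json --input exp/ --out corrected/
afcorrect quantify  --input exp/ --report report.csv
```

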