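#' Infer the autofluorescence image in the primary channel
#'
#' Evaluates the fitted linear mapping on the predictor channel(s):
#' `AF* = m * A + c` (two-channel) or `AF* = m1 * A + m2 * R + c`
#' (three-channel), per pixel. Predictor channels are Gaussian-filtered at
#' the model's stored radius before evaluation (set
#' `filter_predictors = FALSE` to evaluate on raw predictors).
#'
#' @param stack A [channel_stack()].
#' @param model A fitted `saibr_model`.
#' @param filter_predictors Smooth predictors at the model's radius first
#'   (default `TRUE`). Smoothing the predictors suppresses the pixel noise
#'   that subtraction would otherwise combine from multiple channels, while
#'   the primary channel is never smoothed, preserving its resolution.
#' @return Numeric matrix of inferred autofluorescence, primary-channel units.
#' @export
infer_af <- function(stack, model, filter_predictors = TRUE) {
  stopifnot(inherits(stack, "channel_stack"), inherits(model, "saibr_model"))
  r <- if (filter_predictors) model$gaussian_radius else 0
  a <- gaussian_filter(stack$predictor_af, r)
  if (model$mode == "two_channel") {
    model$m * a + model$c
  } else {
    if (is.null(stack$predictor_rfp)) {
      saibr_abort(sprintf(
        "three-channel model requires an RFP predictor, absent in `%s`",
        stack$sample_id), class = "config")
    }
    rr <- gaussian_filter(stack$predictor_rfp, r)
    model$m1 * a + model$m2 * rr + model$c
  }
}

#' Subtract inferred autofluorescence from the primary channel
#'
#' The corrected, signed true-fluorophore image is
#' `corrected = primary - AF*` (the primary channel is never filtered; only
#' predictors are). When the model carries a spillover factor `s`, the
#' subtraction over-corrects by the proportional spillover of fluorophore
#' into the AF channel, and the result is rescaled:
#' `corrected = (primary - AF*) / (1 - m*s)` (with `m1` in three-channel
#' mode). Negative pixels are retained; they are the diagnostic signature of
#' over-subtraction.
#'
#' The decomposition `corrected + inferred_af == primary` is exact
#' (bit-for-bit) when `s` is absent: the inferred AF image is quantized to
#' multiples of 2^-26 detector units (a perturbation of at most 7.5e-9,
#' far below any detector noise) so that, for integer-valued detector
#' images below 2^26 counts, all three quantities live on one binary grid
#' and the subtraction and re-addition are free of rounding error.
#'
#' @inheritParams infer_af
#' @return A `saibr_correction`: list with `corrected`, `inferred_af`,
#'   `negative_fraction` (fraction of ROI pixels below zero),
#'   `roi_mean_corrected`, `roi_mean_raw`, `sample_id` and `model_ref`.
#' @examples
#' st <- channel_stack(matrix(15, 2, 2), matrix(5, 2, 2))
#' m <- saibr:::new_saibr_model("two_channel", m = 2, c = 1,
#'                              gaussian_radius = 0, n_pixels = 3,
#'                              r_squared = 1)
#' saibr_correct(st, m)$corrected[1, 1]  # 15 - (2*5+1) = 4
#' @export
saibr_correct <- function(stack, model, filter_predictors = TRUE) {
  af0 <- infer_af(stack, model, filter_predictors = filter_predictors)
  p <- stack$primary
  if (is.null(model$s) || model$s == 0) {
    af <- round(af0 * 2^26) / 2^26   # grid-align for exact decomposition
    corrected <- p - af
  } else {
    denom <- 1 - slope_primary(model) * model$s
    if (denom <= 0) {
      saibr_abort("spillover factor implies 1 - m*s <= 0; correction undefined",
                  class = "spillover")
    }
    corrected <- (p - af0) / denom
    af <- af0
  }
  roi <- stack$roi
  structure(
    list(corrected = corrected, inferred_af = af,
         negative_fraction = mean(corrected[roi] < 0),
         roi_mean_corrected = mean(corrected[roi]),
         roi_mean_raw = mean(p[roi]),
         roi = roi, sample_id = stack$sample_id,
         model_ref = glance(model)),
    class = "saibr_correction")
}

#' @export
print.saibr_correction <- function(x, ...) {
  cat(sprintf(
    "<saibr_correction> %s: ROI mean %.4g raw -> %.4g corrected; %.1f%% negative\n",
    x$sample_id, x$roi_mean_raw, x$roi_mean_corrected,
    100 * x$negative_fraction))
  invisible(x)
}

#' Correct a batch of stacks
#'
#' Applies the model to each stack; a stack incompatible with the model
#' fails individually without stopping the batch.
#'
#' @param stacks List of `channel_stack`s.
#' @param model A fitted `saibr_model`.
#' @param filter_predictors Passed to [saibr_correct()].
#' @return A tibble with one row per input stack, in order: `sample_id`,
#'   `status` (`"ok"` or the error message), `roi_mean_raw`,
#'   `roi_mean_corrected`, `negative_fraction`, and the full
#'   `saibr_correction` in the `result` list-column (`NULL` on failure).
#' @export
correct_batch <- function(stacks, model, filter_predictors = TRUE) {
  if (!length(stacks)) {
    return(tibble(sample_id = character(), status = character(),
                  roi_mean_raw = double(), roi_mean_corrected = double(),
                  negative_fraction = double(), result = list()))
  }
  stacks <- as_stack_list(stacks)
  purrr::map_dfr(stacks, function(st) {
    res <- tryCatch(
      saibr_correct(st, model, filter_predictors = filter_predictors),
      saibr_error = function(e) e)
    if (inherits(res, "saibr_correction")) {
      tibble(sample_id = st$sample_id, status = "ok",
             roi_mean_raw = res$roi_mean_raw,
             roi_mean_corrected = res$roi_mean_corrected,
             negative_fraction = res$negative_fraction,
             result = list(res))
    } else {
      tibble(sample_id = st$sample_id,
             status = paste("failed:", conditionMessage(res)),
             roi_mean_raw = NA_real_, roi_mean_corrected = NA_real_,
             negative_fraction = NA_real_, result = list(NULL))
    }
  })
}

#' Over-subtraction diagnostics
#'
#' Negative corrected values mark over-subtraction — typically a two-channel
#' model applied to a sample whose AF channel is inflated by a red
#' fluorophore, which the three-channel model would compensate. The report
#' flags results whose negative ROI fraction exceeds `threshold`.
#'
#' @param result A `saibr_correction`.
#' @param threshold Negative-fraction above which the result is flagged
#'   (default 0.05).
#' @return One-row tibble: `sample_id`, `negative_fraction`,
#'   `mean_negative` (mean of negative ROI pixels; 0 when none), `flagged`.
#' @export
overcorrection_report <- function(result, threshold = 0.05) {
  stopifnot(inherits(result, "saibr_correction"))
  neg <- result$corrected[result$roi]
  neg <- neg[neg < 0]
  tibble(sample_id = result$sample_id,
         negative_fraction = result$negative_fraction,
         mean_negative = if (length(neg)) mean(neg) else 0,
         flagged = result$negative_fraction > threshold)
}

#' Cohort-mean autofluorescence reference (baseline method)
#'
#' The naive alternative to per-pixel correction: establish one scalar, the
#' cohort-mean primary-channel ROI intensity of unlabeled samples, and
#' subtract it from every experimental sample's ROI mean. It ignores both
#' per-sample and per-pixel AF variation and is provided purely as the
#' comparison baseline.
#'
#' @param calibration_stacks Unlabeled `channel_stack`s.
#' @return Scalar mean AF reference (primary-channel units).
#' @export
mean_af_reference <- function(calibration_stacks) {
  stacks <- as_stack_list(calibration_stacks)
  mean(purrr::map_dbl(stacks, ~ mean(.x$primary[.x$roi])))
}

#' Mean-AF-subtraction estimates for a batch
#'
#' @param stacks Experimental `channel_stack`s.
#' @param reference Scalar from [mean_af_reference()].
#' @return Tibble of `sample_id` and `corrected_mean`
#'   (`roi_mean(primary) - reference`).
#' @export
mean_af_subtract <- function(stacks, reference) {
  stacks <- as_stack_list(stacks)
  purrr::map_dfr(stacks, function(st) {
    tibble(sample_id = st$sample_id,
           corrected_mean = mean(st$primary[st$roi]) - reference)
  })
}

#' Write a correction result to disk
#'
#' Writes the corrected (signed) and inferred-AF images as 32-bit TIFFs
#' (via the scaled representation of [write_image()]) plus, optionally, a
#' zero-clipped display copy of the corrected image.
#'
#' @param result A `saibr_correction`.
#' @param dir Output directory (created if needed).
#' @param clip_display Also write `<id>_corrected_display.tif` clipped at 0.
#' @return The directory, invisibly.
#' @export
write_correction <- function(result, dir, clip_display = FALSE) {
  stopifnot(inherits(result, "saibr_correction"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  base <- file.path(dir, result$sample_id)
  write_image(result$corrected, paste0(base, "_corrected.tif"))
  write_image(result$inferred_af, paste0(base, "_af.tif"))
  if (clip_display) {
    write_image(result$corrected, paste0(base, "_corrected_display.tif"),
                clip = TRUE)
  }
  invisible(dir)
}
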