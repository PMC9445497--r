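#' @rdname fit_two_channel
#' @section Model: In the two-channel model, observed primary-channel signal
#'   decomposes as true fluorophore plus autofluorescence, and the
#'   autofluorescence components of the primary and predictor channels are
#'   linearly proportional: `G = G_gfp + m * A + c`. On unlabeled samples
#'   `G_gfp = 0`, so ordinary least squares of pooled `g` on `a` recovers
#'   `(m, c)`. The three-channel model adds a red-fluorophore predictor to
#'   absorb bleedthrough into the AF channel: `G = G_gfp + m1*A + m2*R + c`.
#' @keywords internal
new_saibr_model <- function(mode, m = NULL, m1 = NULL, m2 = NULL, c,
                            s = NULL, gaussian_radius, n_pixels, r_squared,
                            per_sample = NULL, sample_ids = NULL,
                            method = "pixel", coef_table = NULL) {
  structure(
    list(mode = mode, m = m, m1 = m1, m2 = m2, c = c, s = s,
         gaussian_radius = gaussian_radius, n_pixels = n_pixels,
         r_squared = r_squared, per_sample = per_sample,
         sample_ids = sample_ids, method = method, coef_table = coef_table),
    class = "saibr_model")
}

#' Fit the two-channel autofluorescence model
#'
#' Fits `g = m * a + c` by ordinary least squares (QR decomposition) over a
#' pixel pool from unlabeled calibration samples, for which all
#' primary-channel signal is autofluorescence. Per-sample slopes and R² are
#' reported as diagnostics only; a single global `(m, c)` is always applied.
#'
#' @param pool A tibble from [build_pixel_pool()] with columns `g`, `a` and
#'   `sample_id` (an `r` column, if present, is ignored).
#' @param gaussian_radius Radius recorded in the model for use at correction
#'   time; defaults to the pool's own filter radius.
#' @return A `saibr_model` with slope `m`, intercept `c`, `r_squared`,
#'   `n_pixels` and a `per_sample` diagnostic tibble.
#' @examples
#' pool <- tibble::tibble(sample_id = "s", a = c(0, 1, 2), g = c(1, 3, 5))
#' fit_two_channel(pool)$m  # exactly 2
#' @export
fit_two_channel <- function(pool, gaussian_radius = NULL) {
  pool <- check_pool(pool, c("g", "a"), min_n = 3)
  if (var(pool$a) == 0) {
    saibr_abort("predictor `a` has zero variance; cannot fit a slope",
                class = "degenerate")
  }
  fit <- lm(g ~ a, data = pool)
  cf <- coef(fit)
  per_sample <- per_sample_diagnostics(pool, mode = "two_channel")
  new_saibr_model(
    mode = "two_channel", m = unname(cf["a"]), c = unname(cf["(Intercept)"]),
    gaussian_radius = gaussian_radius %||% attr(pool, "gaussian_radius") %||% 2,
    n_pixels = nrow(pool), r_squared = summary(fit)$r.squared,
    per_sample = per_sample, sample_ids = unique(pool$sample_id),
    coef_table = lm_coef_table(fit))
}

#' Fit the three-channel autofluorescence model
#'
#' Fits `g = m1 * a + m2 * r + c` by ordinary least squares over a pixel
#' pool from red-fluorophore-only calibration samples. The RFP predictor
#' absorbs red-fluorophore bleedthrough into the AF channel, so `m2` is
#' typically negative: RFP inflates `a` without adding primary-channel
#' autofluorescence.
#'
#' @inheritParams fit_two_channel
#' @return A `saibr_model` in `three_channel` mode.
#' @export
fit_three_channel <- function(pool, gaussian_radius = NULL) {
  pool <- check_pool(pool, c("g", "a", "r"), min_n = 4)
  if (var(pool$r) == 0) {
    saibr_abort("predictor `r` is constant; three-channel fit is rank-deficient",
                class = "collinear")
  }
  if (var(pool$a) == 0) {
    saibr_abort("predictor `a` is constant; three-channel fit is rank-deficient",
                class = "collinear")
  }
  X <- cbind(1, pool$a, pool$r)
  if (qr(X)$rank < 3L) {
    saibr_abort("predictors `a` and `r` are collinear; cannot separate their slopes",
                class = "collinear")
  }
  fit <- lm(g ~ a + r, data = pool)
  cf <- coef(fit)
  new_saibr_model(
    mode = "three_channel", m1 = unname(cf["a"]), m2 = unname(cf["r"]),
    c = unname(cf["(Intercept)"]),
    gaussian_radius = gaussian_radius %||% attr(pool, "gaussian_radius") %||% 2,
    n_pixels = nrow(pool), r_squared = summary(fit)$r.squared,
    per_sample = per_sample_diagnostics(pool, mode = "three_channel"),
    sample_ids = unique(pool$sample_id),
    coef_table = lm_coef_table(fit))
}

check_pool <- function(pool, cols, min_n) {
  if (!is.data.frame(pool) || !all(cols %in% names(pool))) {
    saibr_abort(sprintf("pool must be a data frame with columns %s",
                        paste(cols, collapse = ", ")), class = "config")
  }
  if (nrow(pool) < min_n) {
    saibr_abort(sprintf("pool has %d pixel(s); at least %d required",
                        nrow(pool), min_n), class = "insufficient")
  }
  if (!"sample_id" %in% names(pool)) pool$sample_id <- "pool"
  n_samp <- length(unique(pool$sample_id))
  if (n_samp < 3) {
    warn(sprintf(
      "pool drawn from %d sample(s); pooling from at least 3 is recommended",
      n_samp))
  }
  pool
}

lm_coef_table <- function(fit) {
  sm <- summary(fit)$coefficients
  tibble(term = rownames(sm), estimate = sm[, 1], std.error = sm[, 2],
         statistic = sm[, 3], p.value = sm[, 4])
}

per_sample_diagnostics <- function(pool, mode) {
  pool |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::group_modify(function(d, key) {
      if (nrow(d) < 3 || var(d$a) == 0) {
        return(tibble(slope = NA_real_, intercept = NA_real_,
                      r_squared = NA_real_, n_pixels = nrow(d)))
      }
      f <- lm(g ~ a, data = d)
      tibble(slope = unname(coef(f)["a"]),
             intercept = unname(coef(f)["(Intercept)"]),
             r_squared = summary(f)$r.squared, n_pixels = nrow(d))
    }) |>
    dplyr::ungroup()
}

#' Fit the model on whole-sample ROI means
#'
#' Runs the same regression as the pixel-by-pixel fits, but each observation
#' is one sample's ROI-mean intensity per channel, mirroring whole-sample
#' calibration from a series of samples. Because the generating line is
#' shared, whole-sample and pixel-by-pixel coefficients agree for
#' homogeneous samples; the pixel method simply uses far more observations.
#'
#' @param stacks List of calibration `channel_stack`s, one observation each.
#' @param mode `"two_channel"` or `"three_channel"`.
#' @param gaussian_radius Radius stored in the model for correction-time
#'   filtering (the means themselves are computed on unfiltered pixels;
#'   smoothing does not move an ROI mean appreciably).
#' @return A `saibr_model` with `method = "whole_sample"`.
#' @export
fit_whole_sample <- function(stacks, mode = "two_channel",
                             gaussian_radius = 2) {
  stacks <- as_stack_list(stacks)
  mode <- resolve_mode(stacks, mode)
  p <- if (mode == "two_channel") 2L else 3L
  if (length(stacks) < p + 1L) {
    saibr_abort(sprintf("%s whole-sample fit needs at least %d samples, got %d",
                        mode, p + 1L, length(stacks)),
                class = "insufficient")
  }
  means <- purrr::map_dfr(stacks, function(st) {
    tibble(sample_id = st$sample_id,
           g = mean(st$primary[st$roi]),
           a = mean(st$predictor_af[st$roi]),
           r = if (mode == "three_channel")
             mean(st$predictor_rfp[st$roi]) else NA_real_)
  })
  model <- if (mode == "two_channel") {
    if (var(means$a) == 0) {
      saibr_abort("sample means of `a` are constant", class = "degenerate")
    }
    fit <- lm(g ~ a, data = means)
    new_saibr_model("two_channel", m = unname(coef(fit)["a"]),
                    c = unname(coef(fit)["(Intercept)"]),
                    gaussian_radius = gaussian_radius,
                    n_pixels = nrow(means),
                    r_squared = summary(fit)$r.squared,
                    sample_ids = means$sample_id,
                    method = "whole_sample",
                    coef_table = lm_coef_table(fit))
  } else {
    fit <- lm(g ~ a + r, data = means)
    new_saibr_model("three_channel", m1 = unname(coef(fit)["a"]),
                    m2 = unname(coef(fit)["r"]),
                    c = unname(coef(fit)["(Intercept)"]),
                    gaussian_radius = gaussian_radius,
                    n_pixels = nrow(means),
                    r_squared = summary(fit)$r.squared,
                    sample_ids = means$sample_id,
                    method = "whole_sample",
                    coef_table = lm_coef_table(fit))
  }
  model
}

#' Calibrate a correction model from stacks in one step
#'
#' Convenience wrapper: [build_pixel_pool()] then the fit appropriate to
#' `mode`.
#'
#' @inheritParams build_pixel_pool
#' @return A `saibr_model`.
#' @export
saibr_calibrate <- function(stacks, radius = 2, mode = "auto",
                            saturation_level = NULL) {
  pool <- build_pixel_pool(stacks, radius = radius, mode = mode,
                           saturation_level = saturation_level)
  if (attr(pool, "mode") == "two_channel") {
    fit_two_channel(pool)
  } else {
    fit_three_channel(pool)
  }
}

#' Estimate the GFP spillover factor from fluorophore-bright samples
#'
#' The long emission tail of GFP-like fluorophores leaks a small fraction
#' `s` of the true fluorophore signal into the AF predictor channel,
#' inflating it and causing proportional over-subtraction. `s` is estimated
#' in a second pass from samples with strong fluorophore expression, imaged
#' under the same settings as the calibration set:
#'
#' 1. Each stack is corrected with `base_model` (first pass), giving
#'    `g0 = (1 - m*s) * G_gfp + noise` up to the unknown rescaling.
#' 2. Within each stack, the filtered AF channel and `g0` are centered on
#'    their embryo-ROI means (removing per-sample AF level), then pooled and
#'    regressed through the origin: slope `b = s / (1 - m*s)` under the
#'    assumption that residual AF texture is spatially uncorrelated with the
#'    fluorophore layout.
#' 3. `s = b / (1 + m*b)`.
#'
#' A negative estimate within noise is reported as `s = 0` with a warning;
#' an estimate with `m*s >= 1` is unidentifiable and is an error.
#'
#' The stacks' ROIs should cover the sample interior, where fluorophore
#' structure varies over smooth autofluorescence; ROIs that include large
#' background regions couple the fluorophore and AF spatial supports (both
#' vanish outside the sample) and bias the estimate.
#'
#' @param stacks Fluorophore-expressing `channel_stack`s.
#' @param base_model A fitted `saibr_model` without `s`.
#' @param radius Filter radius for the spillover regression (defaults to the
#'   model's).
#' @return A copy of `base_model` with `s` set.
#' @export
estimate_spillover <- function(stacks, base_model, radius = NULL) {
  stopifnot(inherits(base_model, "saibr_model"))
  stacks <- as_stack_list(stacks)
  radius <- radius %||% base_model$gaussian_radius
  m <- slope_primary(base_model)

  dat <- purrr::map_dfr(stacks, function(st) {
    res <- saibr_correct(st, base_model)
    a_f <- gaussian_filter(st$predictor_af, radius)
    g0 <- gaussian_filter(res$corrected, radius)
    keep <- st$roi
    tibble(a_c = a_f[keep] - mean(a_f[keep]),
           g_c = g0[keep] - mean(g0[keep]))
  })
  if (nrow(dat) < 3 || var(dat$g_c) == 0) {
    saibr_abort("spillover regression has no usable variation in corrected signal",
                class = "insufficient")
  }
  # identifiability guard: the fluorophore must dominate the corrected
  # image's variance, otherwise residual AF leakage (via calibration slope
  # error) masquerades as spillover. This is the "strong expression"
  # precondition made operational.
  if (var(dat$g_c) < var(dat$a_c)) {
    warn(paste("fluorophore variation does not exceed AF variation in the",
               "corrected image; spillover unidentifiable, s set to 0"))
    base_model$s <- 0
    return(base_model)
  }
  b <- sum(dat$a_c * dat$g_c) / sum(dat$g_c^2)
  s_hat <- b / (1 + m * b)
  if (is.na(s_hat) || m * s_hat >= 1) {
    saibr_abort("estimated spillover is unidentifiable (m*s >= 1)",
                class = "spillover")
  }
  if (s_hat < 0) {
    warn(sprintf("estimated spillover %.4g is negative; setting s = 0", s_hat))
    s_hat <- 0
  }
  base_model$s <- s_hat
  base_model
}

slope_primary <- function(model) {
  if (model$mode == "two_channel") model$m else model$m1
}

#' Standard error of the calibrated AF prediction
#'
#' Between-sample standard error of the model's inferred-AF prediction at a
#' given predictor level, computed from the spread of the per-sample
#' calibration lines. Unlike the pooled OLS standard errors — which assume
#' independent pixels and are overconfident once the Gaussian prefilter has
#' correlated neighbours — this treats the calibration sample as the unit of
#' replication. It quantifies the systematic error shared by every image
#' corrected with the same model, e.g. when testing whether corrected
#' unlabeled samples are indistinguishable from zero.
#'
#' @param model A two-channel `saibr_model` fitted on a pixel pool with
#'   per-sample diagnostics.
#' @param a Predictor (AF-channel) level at which to evaluate.
#' @return Standard error of the predicted AF at `a`.
#' @export
prediction_se <- function(model, a) {
  stopifnot(inherits(model, "saibr_model"))
  ps <- model$per_sample
  if (model$mode != "two_channel" || is.null(ps) ||
      !all(c("slope", "intercept") %in% names(ps))) {
    saibr_abort("prediction_se needs a two-channel pixel fit with per-sample diagnostics",
                class = "config")
  }
  pred <- ps$slope * a + ps$intercept
  pred <- pred[is.finite(pred)]
  if (length(pred) < 2) {
    saibr_abort("prediction_se needs at least 2 calibration samples",
                class = "insufficient")
  }
  sd(pred) / sqrt(length(pred))
}

#' @export
print.saibr_model <- function(x, ...) {
  coefs <- if (x$mode == "two_channel") {
    sprintf("m = %.6g, c = %.6g", x$m, x$c)
  } else {
    sprintf("m1 = %.6g, m2 = %.6g, c = %.6g", x$m1, x$m2, x$c)
  }
  cat(sprintf("<saibr_model> %s (%s): %s%s\n  R^2 = %.4f on %s pixels, filter radius %.3g px\n",
              x$mode, x$method, coefs,
              if (!is.null(x$s)) sprintf(", s = %.4g", x$s) else "",
              x$r_squared, format(x$n_pixels, big.mark = ","),
              x$gaussian_radius))
  invisible(x)
}

#' Tidy a fitted correction model
#'
#' @param x A `saibr_model`.
#' @param ... Unused.
#' @return One row per model term with estimate, standard error, statistic
#'   and p-value (when available from the fit).
#' @method tidy saibr_model
#' @export
tidy.saibr_model <- function(x, ...) {
  if (!is.null(x$coef_table)) return(x$coef_table)
  terms <- if (x$mode == "two_channel") {
    tibble(term = c("(Intercept)", "a"), estimate = c(x$c, x$m))
  } else {
    tibble(term = c("(Intercept)", "a", "r"), estimate = c(x$c, x$m1, x$m2))
  }
  terms$std.error <- NA_real_
  terms$statistic <- NA_real_
  terms$p.value <- NA_real_
  terms
}

#' @rdname tidy.saibr_model
#' @return `glance()` returns a one-row model summary.
#' @method glance saibr_model
#' @export
glance.saibr_model <- function(x, ...) {
  tibble(mode = x$mode, method = x$method,
         r.squared = x$r_squared, n_pixels = x$n_pixels,
         gaussian_radius = x$gaussian_radius,
         s = x$s %||% NA_real_,
         n_samples = length(x$sample_ids %||% character()))
}

#' Calibration scatter plot
#'
#' Plots a random subsample of pooled pixels (default 10%) in the predictor
#' vs primary plane, colored by sample, with the fitted line overlaid.
#'
#' @param object A `saibr_model` fitted from a pixel pool.
#' @param pool The pixel pool the model was fitted on.
#' @param fraction Fraction of pixels to draw (default 0.1).
#' @param seed Seed for the subsample.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot saibr_model
#' @export
autoplot.saibr_model <- function(object, pool, fraction = 0.1, seed = 1L, ...) {
  idx <- withr::with_seed(seed,
    sample.int(nrow(pool), size = max(1L, round(fraction * nrow(pool)))))
  d <- pool[idx, , drop = FALSE]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$a, y = .data$g,
                                  colour = .data$sample_id)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.6) +
    ggplot2::geom_abline(intercept = object$c, slope = slope_primary(object)) +
    ggplot2::labs(x = "AF channel (filtered)", y = "primary channel (filtered)",
                  colour = "sample",
                  title = sprintf("calibration fit: R² = %.3f",
                                  object$r_squared)) +
    ggplot2::theme_minimal()
}

#' Export a diagnostic scatter subsample as a tibble
#'
#' @param pool A pixel pool.
#' @param fraction Subsample fraction (default 0.1).
#' @param seed RNG seed for reproducible subsampling.
#' @return A tibble with the sampled rows.
#' @export
pool_scatter_sample <- function(pool, fraction = 0.1, seed = 1L) {
  idx <- withr::with_seed(seed,
    sample.int(nrow(pool), size = max(1L, round(fraction * nrow(pool)))))
  as_tibble(pool[sort(idx), , drop = FALSE])
}
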