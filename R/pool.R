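#' Pool ROI pixels from calibration stacks
#'
#' Gaussian-filters every channel of every stack at the given radius, then
#' concatenates the ROI pixels of all stacks into one tidy tibble with
#' per-pixel sample provenance. This is the pixel-by-pixel data set the
#' calibration regressions are fitted on. The ROI itself is untouched by the
#' filter, so the pool length does not depend on the radius.
#'
#' Pixels saturated at the declared bit-depth maximum (when `meta$bit_depth`
#' is set, or `saturation_level` is given) are excluded before filtering
#' statistics are computed, with the excluded count reported, since
#' saturation breaks the linearity the model relies on.
#'
#' @param stacks A `channel_stack` or list of them.
#' @param radius Gaussian prefilter sigma in pixels (default 2).
#' @param mode `"two_channel"`, `"three_channel"`, or `"auto"` (three-channel
#'   when every stack carries an RFP predictor).
#' @param saturation_level Optional raw intensity treated as saturated;
#'   defaults to `2^bit_depth - 1` when a stack declares `meta$bit_depth`.
#' @return A tibble with columns `sample_id`, `g`, `a` and (three-channel)
#'   `r`, one row per pooled pixel. Attributes: `gaussian_radius`, `mode`,
#'   `n_saturated`, `low_intensity_fraction` (share of pixels in the lowest
#'   fifth of the pooled predictor range — a rough check that the ROIs
#'   include some background, which anchors the intercept).
#' @export
build_pixel_pool <- function(stacks, radius = 2, mode = "auto",
                             saturation_level = NULL) {
  stacks <- as_stack_list(stacks)
  mode <- resolve_mode(stacks, mode)

  rows <- purrr::map(stacks, function(st) {
    sat <- matrix(FALSE, nrow(st$primary), ncol(st$primary))
    lvl <- saturation_level %||%
      (if (!is.null(st$meta$bit_depth)) 2^st$meta$bit_depth - 1 else NULL)
    if (!is.null(lvl)) {
      for (ch in stack_channels(st)) sat <- sat | ch >= lvl
    }
    keep <- st$roi & !sat
    g <- gaussian_filter(st$primary, radius)[keep]
    a <- gaussian_filter(st$predictor_af, radius)[keep]
    out <- tibble(sample_id = st$sample_id, g = g, a = a)
    if (mode == "three_channel") {
      out$r <- gaussian_filter(st$predictor_rfp, radius)[keep]
    }
    attr(out, "n_sat") <- sum(sat & st$roi)
    out
  })
  n_sat <- sum(purrr::map_int(rows, ~ attr(.x, "n_sat")))
  pool <- dplyr::bind_rows(rows)
  if (n_sat > 0) {
    inform(sprintf("excluded %d saturated pixel(s) from the pool", n_sat))
  }
  rng <- range(pool$a)
  low_frac <- if (rng[2] > rng[1]) {
    mean(pool$a < rng[1] + 0.2 * (rng[2] - rng[1]))
  } else 0
  structure(pool,
            gaussian_radius = radius, mode = mode,
            n_saturated = n_sat, low_intensity_fraction = low_frac)
}

as_stack_list <- function(stacks) {
  if (inherits(stacks, "channel_stack")) stacks <- list(stacks)
  if (!length(stacks) || !all(purrr::map_lgl(stacks, inherits, "channel_stack"))) {
    saibr_abort("`stacks` must be one or more channel_stack objects",
                class = "config")
  }
  stacks
}

resolve_mode <- function(stacks, mode) {
  mode <- match.arg(mode, c("auto", "two_channel", "three_channel"))
  have_rfp <- all(purrr::map_lgl(stacks, ~ !is.null(.x$predictor_rfp)))
  if (mode == "auto") mode <- if (have_rfp) "three_channel" else "two_channel"
  if (mode == "three_channel" && !have_rfp) {
    saibr_abort("three-channel mode requires an RFP predictor in every stack",
                class = "config")
  }
  mode
}
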