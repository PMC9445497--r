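#' Bundle co-registered channel images for one sample
#'
#' A `channel_stack` holds the 2-D images of one sample: the primary
#' fluorophore channel (typically GFP), the red-shifted autofluorescence
#' predictor channel, an optional red-fluorophore predictor channel, and a
#' logical region-of-interest mask. All arrays must share one shape and all
#' intensities must be finite. Intensities are stored in double precision in
#' raw detector units; no rescaling is applied, so intercepts fitted on one
#' sample remain comparable across samples.
#'
#' @param primary Numeric matrix, primary (fluorophore) channel.
#' @param predictor_af Numeric matrix, autofluorescence predictor channel,
#'   same shape as `primary`.
#' @param predictor_rfp Optional numeric matrix, red-fluorophore predictor
#'   channel, same shape.
#' @param roi Optional logical matrix marking pixels of interest. Defaults to
#'   all-`TRUE`. Numeric masks are interpreted as nonzero = inside.
#' @param sample_id Character label for the sample.
#' @param meta Named list of free-form acquisition metadata (e.g.
#'   `bit_depth`, source paths).
#'
#' @return An object of class `channel_stack`.
#' @examples
#' s <- channel_stack(matrix(10, 4, 4), matrix(5, 4, 4), sample_id = "ex")
#' dim(s$roi)
#' @export
channel_stack <- function(primary, predictor_af, predictor_rfp = NULL,
                          roi = NULL, sample_id = "sample", meta = list()) {
  primary <- as_channel_matrix(primary, "primary")
  predictor_af <- as_channel_matrix(predictor_af, "predictor_af")
  if (!is.null(predictor_rfp)) {
    predictor_rfp <- as_channel_matrix(predictor_rfp, "predictor_rfp")
  }

  shp <- dim(primary)
  for (nm in c("predictor_af", "predictor_rfp")) {
    ch <- get(nm)
    if (!is.null(ch) && !identical(dim(ch), shp)) {
      saibr_abort(
        sprintf("channel `%s` has shape %dx%d but `primary` is %dx%d",
                nm, nrow(ch), ncol(ch), shp[1], shp[2]),
        class = "geometry")
    }
  }

  if (is.null(roi)) {
    roi <- matrix(TRUE, shp[1], shp[2])
  } else {
    if (is.numeric(roi)) roi <- roi != 0
    if (!is.logical(roi) || !identical(dim(roi), shp)) {
      saibr_abort("`roi` must be a logical matrix with the channel shape",
                  class = "geometry")
    }
  }
  if (!any(roi)) {
    saibr_abort("`roi` contains no pixels", class = "geometry")
  }

  structure(
    list(primary = primary, predictor_af = predictor_af,
         predictor_rfp = predictor_rfp, roi = roi,
         sample_id = as.character(sample_id), meta = meta),
    class = "channel_stack")
}

as_channel_matrix <- function(x, name) {
  if (!is.matrix(x) || !is.numeric(x)) {
    saibr_abort(sprintf("`%s` must be a numeric matrix", name),
                class = "geometry")
  }
  storage.mode(x) <- "double"
  if (!all(is.finite(x))) {
    saibr_abort(sprintf("`%s` contains non-finite pixel values", name),
                class = "data")
  }
  x
}

#' @export
print.channel_stack <- function(x, ...) {
  cat(sprintf("<channel_stack> %s: %dx%d px, channels: %s; ROI %d px\n",
              x$sample_id, nrow(x$primary), ncol(x$primary),
              paste(c("primary", "predictor_af",
                      if (!is.null(x$predictor_rfp)) "predictor_rfp"),
                    collapse = ", "),
              sum(x$roi)))
  invisible(x)
}

stack_channels <- function(stack) {
  chans <- list(primary = stack$primary, predictor_af = stack$predictor_af)
  if (!is.null(stack$predictor_rfp)) chans$predictor_rfp <- stack$predictor_rfp
  chans
}

#' Read a 2-D intensity image from TIFF
#'
#' Integer TIFFs are read in raw detector units (no rescaling: a 16-bit pixel
#' at full scale loads as 65535). Images written by [write_image()] with a
#' scaling sidecar are restored to their original signed values.
#'
#' @param path Path to a TIFF file.
#' @param page Page index for multi-page files (default 1).
#' @return A numeric (double) matrix.
#' @export
read_image <- function(path, page = 1L) {
  if (!file.exists(path)) {
    saibr_abort(sprintf("cannot read image: `%s` does not exist", path),
                class = "io")
  }
  sidecar <- paste0(path, ".scale.json")
  scaled <- file.exists(sidecar)
  # sidecar images are stored as normalized [0,1] samples; native integer
  # images are read in raw detector units
  img <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = !scaled),
                  error = function(e) {
                    saibr_abort(sprintf("failed to decode `%s`: %s",
                                        path, conditionMessage(e)),
                                class = "io")
                  })
  if (page > length(img)) {
    saibr_abort(sprintf("`%s` has %d page(s); page %d requested",
                        path, length(img), page), class = "io")
  }
  m <- img[[page]]
  if (length(dim(m)) == 3L) m <- m[, , 1L]  # collapse greyscale-with-alpha
  storage.mode(m) <- "double"

  if (scaled) {
    sc <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    m <- m * sc$scale + sc$offset
  }
  if (!all(is.finite(m))) {
    saibr_abort(sprintf("`%s` contains non-finite pixel values", path),
                class = "data")
  }
  m
}

#' Write a 2-D intensity image to TIFF
#'
#' Nonnegative integer-valued images are written natively at the requested
#' bit depth. Signed or non-integer images (e.g. corrected fluorophore
#' images, which legitimately contain negative values) are stored as 32-bit
#' samples of affinely rescaled values, with the offset/scale recorded in a
#' `<path>.scale.json` sidecar so that [read_image()] restores them. The
#' quantization step is (max - min) / (2^32 - 1); a second save of a loaded
#' image is bit-identical.
#'
#' @param image Numeric matrix.
#' @param path Output path.
#' @param bits Bits per sample for native integer output (8, 16 or 32).
#' @param clip Clip negative values to zero before writing (display exports
#'   only; never the default, since negative values are diagnostic).
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path, bits = 16L, clip = FALSE) {
  stopifnot(is.matrix(image), is.numeric(image))
  if (clip) image[image < 0] <- 0
  maxv <- 2^bits - 1
  is_native <- all(image >= 0) && all(image == round(image)) && all(image <= maxv)
  sidecar <- paste0(path, ".scale.json")
  if (is_native) {
    tiff::writeTIFF(image / maxv, path, bits.per.sample = as.integer(bits))
    if (file.exists(sidecar)) file.remove(sidecar)
  } else {
    rng <- range(image)
    scale <- if (rng[2] > rng[1]) rng[2] - rng[1] else 1
    u <- (image - rng[1]) / scale
    tiff::writeTIFF(u, path, bits.per.sample = 32L)
    jsonlite::write_json(list(offset = rng[1], scale = scale),
                         sidecar, auto_unbox = TRUE, digits = I(17))
  }
  invisible(path)
}

#' Load a channel stack from image files
#'
#' @param primary,predictor_af,predictor_rfp Paths to per-channel TIFFs
#'   (`predictor_rfp` optional), or `primary` may be a multi-page TIFF with
#'   channel pages given by `pages` (user-declared order; page metadata is
#'   never guessed).
#' @param roi_path Optional mask TIFF (nonzero = inside). Defaults to an
#'   all-true ROI.
#' @param pages Integer vector of page indices (primary, af\[, rfp\]) when
#'   `primary` is a multi-page stack and the other paths are `NULL`.
#' @param sample_id Sample label; defaults to the primary file name.
#' @return A [channel_stack()].
#' @export
load_channel_stack <- function(primary, predictor_af = NULL,
                               predictor_rfp = NULL, roi_path = NULL,
                               pages = NULL, sample_id = NULL) {
  if (is.null(sample_id)) {
    sample_id <- sub("\\.[^.]+$", "", basename(primary))
  }
  if (!is.null(pages)) {
    g <- read_image(primary, pages[1])
    a <- read_image(primary, pages[2])
    r <- if (length(pages) >= 3) read_image(primary, pages[3]) else NULL
  } else {
    if (is.null(predictor_af)) {
      saibr_abort("`predictor_af` path required when `pages` is not given",
                  class = "config")
    }
    g <- read_image(primary)
    a <- read_image(predictor_af)
    r <- if (!is.null(predictor_rfp)) read_image(predictor_rfp) else NULL
  }
  roi <- if (!is.null(roi_path)) read_image(roi_path) != 0 else NULL
  channel_stack(g, a, r, roi = roi, sample_id = sample_id,
                meta = list(source = primary))
}

#' Subtract per-channel background frames
#'
#' Subtracts a background image (a field of view with no sample) from each
#' channel pixel-wise. Negative results are retained — clipping would destroy
#' the over-subtraction diagnostics downstream. Subtraction is linear:
#' subtracting B1 then B2 equals subtracting B1 + B2.
#'
#' @param stack A [channel_stack()].
#' @param backgrounds Named list of background matrices; names among
#'   `primary`, `predictor_af`, `predictor_rfp`. Every present channel with a
#'   named background has it subtracted; a background named for an absent
#'   channel is an error.
#' @return The corrected `channel_stack`, with the operation recorded in
#'   `meta$background_subtracted`.
#' @export
subtract_background <- function(stack, backgrounds) {
  stopifnot(inherits(stack, "channel_stack"))
  if (!is.list(backgrounds) || is.null(names(backgrounds))) {
    saibr_abort("`backgrounds` must be a named list of matrices",
                class = "config")
  }
  for (nm in names(backgrounds)) {
    if (!nm %in% c("primary", "predictor_af", "predictor_rfp")) {
      saibr_abort(sprintf("unknown channel `%s` in backgrounds", nm),
                  class = "config")
    }
    ch <- stack[[nm]]
    if (is.null(ch)) {
      saibr_abort(sprintf("background given for absent channel `%s`", nm),
                  class = "config")
    }
    bg <- backgrounds[[nm]]
    if (!identical(dim(bg), dim(ch))) {
      saibr_abort(sprintf("background for `%s` has mismatched shape", nm),
                  class = "geometry")
    }
    stack[[nm]] <- ch - bg
  }
  stack$meta$background_subtracted <-
    c(stack$meta$background_subtracted, list(names(backgrounds)))
  stack
}
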