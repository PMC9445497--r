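#' Parameters for a synthetic multi-channel scene
#'
#' The generator renders an elliptical "embryo" whose channels obey the
#' additive linear model the correction assumes: the primary channel is the
#' sum of a true-fluorophore component and an autofluorescence component
#' proportional to the AF-channel field (`G = G_gfp + m_true*A_af + c_true`),
#' the AF channel may carry fluorophore spillover (`s_true * G_gfp`) and
#' red-fluorophore bleedthrough (`rfp_bleed * R_rfp`), and the RFP channel
#' carries only the red fluorophore. All latent components are stored
#' exactly, so recovery can be checked against ground truth.
#'
#' Defaults emulate a 16-bit camera imaging a *C. elegans*-like embryo:
#' detector-unit AF around `af_base_level` in the AF channel, a ~2-fold
#' spread of per-sample AF magnitude (`af_sample_range = 2` draws each
#' sample's level uniformly over a 2:1 range), smooth AF texture with ~6 px
#' correlation length, and additive Gaussian read noise with an optional
#' signal-proportional (shot-noise-like) variance term.
#'
#' @param shape `c(rows, cols)` image size.
#' @param m_true,c_true AF mapping from the AF channel into the primary
#'   channel (slope, intercept in detector units).
#' @param rfp_bleed Slope of red-fluorophore bleedthrough into the AF
#'   channel (`A_rfp = rfp_bleed * R_rfp`). The three-channel fit then
#'   recovers `m1 = m_true` and `m2 = -m_true * rfp_bleed`.
#' @param s_true Fluorophore spillover slope into the AF channel
#'   (`A_gfp = s_true * G_gfp`); requires `s_true * m_true < 1`.
#' @param af_base_level Mean AF magnitude in AF-channel units.
#' @param af_sample_range Max:min ratio of the per-sample AF level
#'   distribution (uniform draw; 2 reproduces the observed ~2-fold
#'   inter-sample variation).
#' @param af_texture_cv Relative spatial variation of the AF field,
#'   calibrated at the default 6 px correlation length; longer correlation
#'   lengths give proportionally flatter fields.
#' @param af_texture_scale Correlation length (Gaussian smoothing sigma, px)
#'   of the AF texture.
#' @param af_void Add an interior void mimicking local AF exclusion
#'   (e.g. pronuclear regions).
#' @param gfp_layout One of `"none"`, `"uniform_cytoplasm"`,
#'   `"membrane_band"`, `"nuclear_void"`.
#' @param gfp_amplitude Peak true-fluorophore intensity (primary-channel
#'   units).
#' @param rfp_amplitude Red-fluorophore intensity (RFP-channel units);
#'   uniform in the cytoplasm when positive.
#' @param include_rfp Render an RFP channel even when `rfp_amplitude = 0`.
#' @param band_width Gaussian cross-section sigma of the membrane band, px.
#' @param noise_sd Additive Gaussian noise sigma (detector units).
#' @param noise_gain Signal-proportional variance coefficient
#'   (`var = noise_sd^2 + noise_gain * signal`).
#' @param quantize Round rendered channels to integer detector counts, as a
#'   camera does (default `TRUE`). Disable to inspect the exact latent
#'   model identities pre-noise.
#' @param af_extra_amplitude Amplitude of an optional second, independently
#'   varying AF component with a different inter-channel slope
#'   (`af_extra_slope`); exercises the known multi-source failure mode and
#'   is off by default.
#' @param af_extra_slope Primary-channel slope of the second AF component.
#' @param seed Integer seed; all randomness flows from it, never from the
#'   global RNG state.
#' @return A `scene_params` list.
#' @export
scene_params <- function(shape = c(64L, 96L),
                         m_true = 1.8, c_true = 100,
                         rfp_bleed = 0, s_true = 0,
                         af_base_level = 400, af_sample_range = 2,
                         af_texture_cv = 0.25, af_texture_scale = 6,
                         af_void = FALSE,
                         gfp_layout = c("none", "uniform_cytoplasm",
                                        "membrane_band", "nuclear_void"),
                         gfp_amplitude = 0, rfp_amplitude = 0,
                         include_rfp = FALSE, band_width = 1.5,
                         noise_sd = 10, noise_gain = 0, quantize = TRUE,
                         af_extra_amplitude = 0, af_extra_slope = 0.5,
                         seed = 1L) {
  gfp_layout <- match.arg(gfp_layout)
  if (any(c(gfp_amplitude, rfp_amplitude, af_base_level, noise_sd,
            noise_gain, af_extra_amplitude) < 0)) {
    saibr_abort("amplitudes and noise parameters must be >= 0",
                class = "parameter")
  }
  if (s_true * m_true >= 1) {
    saibr_abort("s_true * m_true must be < 1", class = "parameter")
  }
  if (gfp_layout == "membrane_band" && band_width <= 0) {
    saibr_abort("membrane_band layout requires band_width > 0",
                class = "parameter")
  }
  structure(as.list(environment()), class = "scene_params")
}

# embryo geometry shared by all layouts: fixed ellipse, ROI adds a margin
scene_geometry <- function(shape) {
  nr <- shape[1]; nc <- shape[2]
  cx <- (nc + 1) / 2; cy <- (nr + 1) / 2
  a <- 0.38 * nc; b <- 0.33 * nr
  xs <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  ys <- matrix(rep(seq_len(nr), nc), nr, nc)
  rr <- sqrt(((xs - cx) / a)^2 + ((ys - cy) / b)^2)
  list(center = c(cx, cy), semi_axes = c(a, b), rr = rr,
       embryo = rr <= 1, roi = rr <= 1.25, xs = xs, ys = ys)
}

#' Generate a latent autofluorescence field
#'
#' Smoothed white noise, rescaled so its embryo mean equals a per-sample AF
#' level drawn uniformly over the configured range, restricted to the
#' embryo ellipse. As the texture scale grows the field approaches a
#' spatially constant level.
#'
#' @param params A [scene_params()].
#' @return List: `field` (matrix, AF-channel units), `level` (the drawn
#'   per-sample mean level). Deterministic given `params$seed`.
#' @export
make_af_field <- function(params) {
  withr::with_seed(params$seed, make_af_field_impl(params))
}

make_af_field_impl <- function(params) {
  geo <- scene_geometry(params$shape)
  r <- params$af_sample_range
  level <- params$af_base_level * runif(1, 2 / (1 + r), 2 * r / (1 + r))
  noise <- matrix(rnorm(prod(params$shape)), params$shape[1], params$shape[2])
  sm <- gaussian_filter(noise, params$af_texture_scale)
  # amplitude referenced to the theoretical sd of unit white noise smoothed
  # at the default 6 px correlation length, so af_texture_cv sets the field
  # cv at that scale and longer correlation lengths flatten the field
  # (constant in the large-scale limit) instead of being re-amplified
  sd_ref <- sum(gaussian_kernel(6)^2)
  z <- (sm - mean(sm)) / sd_ref
  tex <- pmax(1 + params$af_texture_cv * z, 0.05)
  field <- matrix(0, params$shape[1], params$shape[2])
  field[geo$embryo] <- tex[geo$embryo]
  if (params$af_void) {
    void <- exp(-((geo$xs - geo$center[1] - 0.3 * geo$semi_axes[1])^2 +
                  (geo$ys - geo$center[2])^2) / (2 * (0.18 * geo$semi_axes[1])^2))
    field <- field * (1 - 0.8 * void)
  }
  inb <- mean(field[geo$embryo])
  field <- field * (level / max(inb, 1e-12))
  list(field = field, level = level)
}

gfp_layout_image <- function(params, geo) {
  switch(params$gfp_layout,
    none = matrix(0, params$shape[1], params$shape[2]),
    uniform_cytoplasm = geo$embryo * 1,
    membrane_band = {
      # annular band along the ellipse boundary, Gaussian cross-section;
      # ground-truth peak sits on the ellipse contour (distance 0)
      sr <- params$band_width / mean(geo$semi_axes)
      exp(-(geo$rr - 1)^2 / (2 * sr^2))
    },
    nuclear_void = {
      blob <- exp(-((geo$xs - geo$center[1])^2 + (geo$ys - geo$center[2])^2) /
                    (2 * (0.2 * geo$semi_axes[1])^2))
      (geo$embryo * 1) * (1 - 0.9 * blob)
    })
}

#' Render a synthetic multi-channel scene
#'
#' Assembles the channels from the latent components and additive noise:
#' `G = G_gfp + m_true*A_af(+ extra AF) + c_true + eps`,
#' `A = A_af + s_true*G_gfp + rfp_bleed*R_rfp + eps`,
#' `R = R_rfp + eps`. The pre-noise identities hold exactly in the stored
#' truth. Bit-reproducible for a fixed seed.
#'
#' @param params A [scene_params()].
#' @param sample_id Label for the rendered stack.
#' @return A `synthetic_scene`: list with `stack` (a [channel_stack()] whose
#'   ROI is the embryo ellipse plus a background margin), `truth` (latent
#'   images `G_gfp`, `G_af`, `A_af`, `A_gfp`, `A_rfp`, `R_rfp`), `af_level`
#'   and `params`.
#' @export
make_scene <- function(params, sample_id = sprintf("scene_%05d", params$seed)) {
  stopifnot(inherits(params, "scene_params"))
  withr::with_seed(params$seed, {
    geo <- scene_geometry(params$shape)
    af <- make_af_field_impl(params)

    G_gfp <- params$gfp_amplitude * gfp_layout_image(params, geo)
    R_rfp <- if (params$rfp_amplitude > 0) {
      params$rfp_amplitude * (geo$embryo * 1)
    } else matrix(0, params$shape[1], params$shape[2])
    A_af <- af$field
    G_af <- params$m_true * A_af + params$c_true
    A_gfp <- params$s_true * G_gfp
    A_rfp <- params$rfp_bleed * R_rfp

    extra <- NULL
    G_extra <- 0
    if (params$af_extra_amplitude > 0) {
      # second, independently drawn AF source with its own channel slope:
      # punctate (short-scale) texture so it is distinguishable from the
      # primary smooth component
      p2 <- params
      p2$af_base_level <- params$af_extra_amplitude
      p2$af_texture_scale <- 1.5
      p2$af_texture_cv <- 0.8
      extra <- make_af_field_impl(p2)
      A_af <- A_af + extra$field
      G_extra <- params$af_extra_slope * extra$field
      G_af <- params$m_true * af$field + G_extra + params$c_true
    }

    addnoise <- function(img) {
      sdm <- sqrt(params$noise_sd^2 + params$noise_gain * pmax(img, 0))
      out <- img + matrix(rnorm(length(img)), nrow(img)) * sdm
      if (isTRUE(params$quantize)) out <- round(out)
      out
    }
    G <- addnoise(G_gfp + G_af)
    A <- addnoise(A_af + A_gfp + A_rfp)
    has_rfp <- params$include_rfp || params$rfp_amplitude > 0 ||
      params$rfp_bleed > 0
    R <- if (has_rfp) addnoise(R_rfp) else NULL

    stack <- channel_stack(G, A, R, roi = geo$roi, sample_id = sample_id,
                           meta = list(synthetic = TRUE, seed = params$seed))
    structure(
      list(stack = stack,
           truth = list(G_gfp = G_gfp, G_af = G_af, A_af = A_af,
                        A_gfp = A_gfp, A_rfp = A_rfp, R_rfp = R_rfp),
           af_level = af$level, embryo = geo$embryo, params = params),
      class = "synthetic_scene")
  })
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf(
    "<synthetic_scene> %s: %dx%d, layout %s, AF level %.1f, seed %d\n",
    x$stack$sample_id, nrow(x$stack$primary), ncol(x$stack$primary),
    x$params$gfp_layout, x$af_level, x$params$seed))
  invisible(x)
}

#' Generate a cohort of independent scenes
#'
#' Scenes share the inter-channel truth (`m_true`, `c_true`, ...) but each
#' draws its own AF level and texture. Scene `i` is generated with seed
#' `params$seed + i`, so any scene is reproducible in isolation.
#'
#' @param params Base [scene_params()].
#' @param n_samples Number of scenes.
#' @param overrides Named list of per-scene parameter vectors, each recycled
#'   to length `n_samples` (e.g. `list(gfp_amplitude = c(300, 150))` for
#'   alternating full/half dose).
#' @return List of `synthetic_scene`s.
#' @export
make_cohort <- function(params, n_samples, overrides = NULL) {
  stopifnot(inherits(params, "scene_params"), n_samples >= 1)
  purrr::map(seq_len(n_samples), function(i) {
    p <- params
    if (!is.null(overrides)) {
      for (nm in names(overrides)) {
        v <- rep_len(overrides[[nm]], n_samples)
        p[[nm]] <- v[i]
      }
    }
    p$seed <- params$seed + i
    make_scene(p, sample_id = sprintf("scene_%03d", i))
  })
}

#' Embryo mask of a synthetic scene
#'
#' The embryo ellipse at an optional shrink factor: `fraction = 1` is the
#' full embryo, smaller values erode towards the center. Useful as a
#' quantification ROI (the stack's own ROI additionally includes a
#' background margin for calibration) and, eroded, as the interior mask
#' recommended for [estimate_spillover()].
#'
#' @param scene A `synthetic_scene`.
#' @param fraction Relative ellipse radius in (0, 1].
#' @return Logical matrix.
#' @export
embryo_mask <- function(scene, fraction = 1) {
  stopifnot(inherits(scene, "synthetic_scene"), fraction > 0, fraction <= 1)
  geo <- scene_geometry(scene$params$shape)
  geo$rr <= fraction
}

#' Membrane contour of a synthetic scene
#'
#' The ellipse along which the `membrane_band` layout peaks, as a contour
#' usable with [cross_membrane_profiles()].
#'
#' @param scene A `synthetic_scene`.
#' @param n Number of vertices.
#' @return 2-column `(x, y)` vertex matrix.
#' @export
scene_membrane_contour <- function(scene, n = 360L) {
  stopifnot(inherits(scene, "synthetic_scene"))
  geo <- scene_geometry(scene$params$shape)
  ellipse_contour(geo$center, geo$semi_axes, n = n)
}

#' Extract the rendered stacks from a list of scenes
#'
#' @param scenes List of `synthetic_scene`s.
#' @return List of `channel_stack`s.
#' @export
scene_stacks <- function(scenes) {
  purrr::map(scenes, "stack")
}

#' Write a synthetic scene to disk
#'
#' Writes the rendered channels, ROI mask, latent truth images and a
#' parameter JSON into `dir`, named by the scene's sample id.
#'
#' @param scene A `synthetic_scene`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_scene <- function(scene, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  base <- file.path(dir, scene$stack$sample_id)
  write_image(scene$stack$primary, paste0(base, "_primary.tif"))
  write_image(scene$stack$predictor_af, paste0(base, "_af.tif"))
  if (!is.null(scene$stack$predictor_rfp)) {
    write_image(scene$stack$predictor_rfp, paste0(base, "_rfp.tif"))
  }
  write_image(scene$stack$roi * 1, paste0(base, "_roi.tif"), bits = 8L)
  for (nm in names(scene$truth)) {
    write_image(scene$truth[[nm]], paste0(base, "_truth_", nm, ".tif"))
  }
  pj <- scene$params
  pj$gfp_layout <- as.character(pj$gfp_layout)
  jsonlite::write_json(unclass(pj), paste0(base, "_params.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
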