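#' Mean intensity over a region of interest
#'
#' @param image Numeric matrix.
#' @param mask Logical (or nonzero-numeric) matrix of the same shape.
#' @return Arithmetic mean over masked pixels.
#' @export
roi_mean <- function(image, mask) {
  stopifnot(is.matrix(image))
  if (is.numeric(mask)) mask <- mask != 0
  if (!identical(dim(mask), dim(image))) {
    saibr_abort("mask shape does not match image", class = "geometry")
  }
  if (!any(mask)) {
    saibr_abort("mask selects no pixels", class = "parameter")
  }
  mean(image[mask])
}

#' Coefficient of variation
#'
#' Sample standard deviation (n - 1 denominator) divided by the mean; the
#' standard summary of inter-sample measurement spread.
#'
#' @param values Numeric vector, length >= 2, nonzero mean.
#' @return Scalar c.o.v.
#' @examples
#' coefficient_of_variation(c(2, 4))  # sqrt(2)/3
#' @export
coefficient_of_variation <- function(values) {
  if (length(values) < 2) {
    saibr_abort("c.o.v. needs at least 2 values", class = "parameter")
  }
  m <- mean(values)
  if (m == 0) {
    saibr_abort("c.o.v. undefined: mean is zero", class = "cov_undefined")
  }
  sd(values) / m
}

#' Closed elliptical contour
#'
#' Convenience constructor for a membrane contour along an ellipse, in the
#' package's pixel coordinate frame (pixel centers at integer coordinates,
#' `x` = column rightwards, `y` = row downwards). Vertices are ordered
#' counter-clockwise in the standard mathematical sense.
#'
#' @param center `c(x, y)` center.
#' @param semi_axes `c(a, b)` semi-axis lengths in pixels.
#' @param n Number of vertices.
#' @return A 2-column matrix of `(x, y)` vertices, class `contour`.
#' @export
ellipse_contour <- function(center, semi_axes, n = 360L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cbind(x = center[1] + semi_axes[1] * cos(th),
        y = center[2] + semi_axes[2] * sin(th))
}

# Keys bicubic convolution interpolation (a = -0.5), mirror boundary.
# Reproduces linear images exactly; standard smooth image interpolant.
interp_bicubic <- function(image, x, y) {
  stopifnot(length(x) == length(y))
  nr <- nrow(image); nc <- ncol(image)
  kern <- function(t) {
    at <- abs(t)
    ifelse(at <= 1, 1.5 * at^3 - 2.5 * at^2 + 1,
           ifelse(at < 2, -0.5 * at^3 + 2.5 * at^2 - 4 * at + 2, 0))
  }
  mirror <- function(i, n) {
    # reflect 1-based indices into [1, n]
    i <- abs(i - 1L) %% (2L * (n - 1L))
    ifelse(i >= n, 2L * (n - 1L) - i, i) + 1L
  }
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  out <- numeric(length(x))
  for (dy in -1:2) {
    wy <- kern(fy - dy)
    ri <- mirror(as.integer(y0) + dy, nr)
    for (dx in -1:2) {
      wx <- kern(fx - dx)
      ci <- mirror(as.integer(x0) + dx, nc)
      out <- out + wy * wx * image[cbind(ri, ci)]
    }
  }
  out
}

#' Extract cross-membrane intensity linescans
#'
#' Walks the contour at fixed arc-length steps and, at each step, samples
#' the image along the local normal at `n_samples` equally spaced positions
#' spanning `[-half_length, +half_length]` pixels, using bicubic
#' interpolation. The distance axis is centered on the membrane: negative
#' distances lie outside the contour, positive inside (orientation is fixed
#' by the contour winding, resolved via its signed area, so either winding
#' gives the same outside/inside convention).
#'
#' Linescans with any sample falling outside the image are dropped; the
#' dropped count is kept in the `n_dropped` attribute.
#'
#' @param image Numeric matrix.
#' @param contour 2-column matrix of `(x, y)` vertices tracing the membrane
#'   (closed implicitly).
#' @param half_length Half-extent of each linescan in pixels (default 25,
#'   i.e. 50-pixel profiles).
#' @param spacing Arc-length step between linescans, pixels (default 1).
#' @param n_samples Samples per linescan (default `2 * half_length`, i.e.
#'   one per pixel).
#' @return Tidy tibble: `line_id`, `arc_length` (position of the linescan
#'   along the contour), `distance` (signed, membrane at 0), `intensity`.
#'   Attributes: `n_dropped`, `total_arc`.
#' @export
cross_membrane_profiles <- function(image, contour, half_length = 25,
                                    spacing = 1,
                                    n_samples = 2 * half_length) {
  stopifnot(is.matrix(image))
  contour <- as.matrix(contour)
  if (ncol(contour) != 2 || nrow(contour) < 3) {
    saibr_abort("contour must be a 2-column matrix with >= 3 vertices",
                class = "geometry")
  }
  nr <- nrow(image); nc <- ncol(image)
  if (all(contour[, 1] < 1 | contour[, 1] > nc |
          contour[, 2] < 1 | contour[, 2] > nr)) {
    saibr_abort("contour lies entirely outside the image", class = "geometry")
  }

  # closed polygon: segment vectors and cumulative arc length
  nxt <- c(seq_len(nrow(contour))[-1], 1L)
  seg <- contour[nxt, , drop = FALSE] - contour
  seg_len <- sqrt(rowSums(seg^2))
  total <- sum(seg_len)
  cum0 <- c(0, cumsum(seg_len))

  # outward normal sign from the signed area (shoelace)
  area2 <- sum(contour[, 1] * contour[nxt, 2] - contour[nxt, 1] * contour[, 2])
  # for positive (math-CCW) winding the outward normal of tangent (tx,ty)
  # in a y-down frame is (ty,-tx) flipped; resolve by testing the centroid
  offsets <- seq(-half_length, half_length, length.out = n_samples)
  steps <- seq(0, total - 1e-9, by = spacing)

  centroid <- colMeans(contour)
  lines <- purrr::map(seq_along(steps), function(i) {
    s <- steps[i]
    j <- findInterval(s, cum0, rightmost.closed = TRUE)
    j <- min(j, length(seg_len))
    f <- if (seg_len[j] > 0) (s - cum0[j]) / seg_len[j] else 0
    pt <- contour[j, ] + f * seg[j, ]
    tg <- seg[j, ] / max(seg_len[j], 1e-12)
    nrm <- c(tg[2], -tg[1])
    # orient nrm outward: away from centroid
    if (sum(nrm * (pt - centroid)) < 0) nrm <- -nrm
    inward <- -nrm
    px <- pt[1] + offsets * inward[1]
    py <- pt[2] + offsets * inward[2]
    if (any(px < 1 | px > nc | py < 1 | py > nr)) return(NULL)
    out <- tibble(line_id = i, arc_length = s, distance = offsets,
                  intensity = interp_bicubic(image, px, py))
    attr(out, "pos") <- c(pt, s)
    out
  })
  dropped <- sum(purrr::map_lgl(lines, is.null))
  kept <- purrr::compact(lines)
  out <- dplyr::bind_rows(kept)
  if (!nrow(out)) {
    saibr_abort("every linescan exited the image frame", class = "geometry")
  }
  pos <- do.call(rbind, purrr::map(kept, ~ attr(.x, "pos")))
  positions <- tibble(line_id = purrr::map_int(kept, ~ .x$line_id[1]),
                      x = pos[, 1], y = pos[, 2], arc_length = pos[, 3])
  structure(out, n_dropped = dropped, total_arc = total,
            line_positions = positions)
}

#' Average linescans over an arc of the contour
#'
#' Selects the linescans lying on a contiguous fraction of the contour's
#' arc length centered on an anchor point, and averages them pointwise.
#'
#' @param linescans Tibble from [cross_membrane_profiles()].
#' @param fraction Fraction of the total circumference to average over
#'   (default 1, the full contour).
#' @param anchor Optional `c(x, y)` anchor; the arc window is centered on
#'   the linescan nearest this point. With `NULL` the window starts at the
#'   contour's first vertex. Anchors are user-supplied coordinates (e.g. a
#'   posterior pole); no axis detection is attempted.
#' @param anchor_arc Alternative to `anchor`: arc-length position directly.
#' @return A `membrane_profile`: tibble with `distance`, `mean`, `sd`, `n`,
#'   plus attributes `n_lines` and `arc_fraction`.
#' @export
average_profiles <- function(linescans, fraction = 1, anchor = NULL,
                             anchor_arc = NULL) {
  if (!nrow(linescans)) {
    saibr_abort("no linescans to average", class = "parameter")
  }
  if (fraction <= 0 || fraction > 1) {
    saibr_abort("`fraction` must be in (0, 1]", class = "parameter")
  }
  total <- attr(linescans, "total_arc") %||% max(linescans$arc_length)
  per_line <- dplyr::distinct(linescans, .data$line_id, .data$arc_length)

  if (fraction < 1) {
    center <- if (!is.null(anchor_arc)) {
      anchor_arc
    } else if (!is.null(anchor)) {
      pos <- attr(linescans, "line_positions")
      if (is.null(pos)) {
        saibr_abort("linescans carry no positions; pass `anchor_arc` instead",
                    class = "parameter")
      }
      pos$arc_length[which.min((pos$x - anchor[1])^2 + (pos$y - anchor[2])^2)]
    } else 0
    half <- fraction * total / 2
    d <- (per_line$arc_length - center) %% total
    d <- pmin(d, total - d)          # circular distance
    keep_ids <- per_line$line_id[d <= half + 1e-9]
  } else {
    keep_ids <- per_line$line_id
  }
  if (!length(keep_ids)) {
    saibr_abort("arc selection is empty", class = "parameter")
  }
  sel <- dplyr::filter(linescans, .data$line_id %in% keep_ids)
  prof <- sel |>
    dplyr::group_by(.data$distance) |>
    dplyr::summarise(mean = mean(.data$intensity),
                     sd = if (dplyr::n() > 1) stats::sd(.data$intensity) else 0,
                     n = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(.data$distance)
  structure(prof, n_lines = length(keep_ids), arc_fraction = fraction,
            class = c("membrane_profile", class(prof)))
}

#' Plot an averaged cross-membrane profile
#'
#' @param object A `membrane_profile`.
#' @param ... Unused.
#' @return A ggplot: mean intensity vs signed distance with a +/- 1 sd
#'   ribbon; membrane at distance 0 (negative = outside).
#' @method autoplot membrane_profile
#' @export
autoplot.membrane_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$distance, y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd),
                         alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "distance from membrane (px; negative = outside)",
                  y = "mean intensity") +
    ggplot2::theme_minimal()
}
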