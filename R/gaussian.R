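#' Gaussian prefilter for channel images
#'
#' Smooths an image with a normalized, separable Gaussian kernel to suppress
#' salt-and-pepper pixel noise before regression or correction. The kernel
#' standard deviation equals `radius` (pixels) and is truncated at three
#' standard deviations; image borders are handled by symmetric reflection so
#' pooled border pixels are not darkened. `radius = 0` returns the input
#' unchanged. Constant images are preserved exactly.
#'
#' @param image Numeric matrix.
#' @param radius Gaussian sigma in pixels; must be >= 0.
#' @return Smoothed matrix of the same shape.
#' @examples
#' gaussian_filter(matrix(7, 5, 5), radius = 2)[1, 1]  # still 7
#' @export
gaussian_filter <- function(image, radius) {
  stopifnot(is.matrix(image), is.numeric(image))
  if (!is.numeric(radius) || length(radius) != 1 || is.na(radius) ||
      radius < 0) {
    saibr_abort("`radius` must be a single number >= 0", class = "parameter")
  }
  if (radius == 0) return(image)
  k <- gaussian_kernel(radius)
  out <- convolve_sep(image, k)      # along columns (within each column)
  t(convolve_sep(t(out), k))         # along rows
}

gaussian_kernel <- function(radius) {
  h <- max(1L, as.integer(ceiling(3 * radius)))
  k <- exp(-((-h:h)^2) / (2 * radius^2))
  k / sum(k)
}

# 1-D convolution down each column with symmetric boundary reflection.
convolve_sep <- function(m, k) {
  h <- (length(k) - 1L) %/% 2L
  n <- nrow(m)
  hh <- min(h, n)  # reflection indices must stay in range
  if (hh < h) {    # kernel wider than the image: renormalize the clipped part
    k <- k[(h - hh + 1L):(h + hh + 1L)]
    k <- k / sum(k)
    h <- hh
  }
  # symmetric padding: rows h..1, 1..n, n..n-h+1
  idx <- c(h:1, seq_len(n), n:(n - h + 1L))
  p <- m[idx, , drop = FALSE]
  out <- matrix(0, n, ncol(m))
  for (i in seq_along(k)) {
    out <- out + k[i] * p[(i - 1L) + seq_len(n), , drop = FALSE]
  }
  out
}
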