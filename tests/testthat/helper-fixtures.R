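# Shared fixtures: all synthetic, generated in code at test time.

# Independent OLS oracle: explicit normal equations, never the package path.
ols_oracle <- function(y, X) {
  X <- cbind(1, X)
  unname(solve(t(X) %*% X, t(X) %*% y)[, 1])
}

# quick unlabeled calibration cohort + fitted two-channel model
fit_unlabeled_model <- function(seed = 11, n = 5, ...) {
  scenes <- make_cohort(scene_params(seed = seed, ...), n)
  suppressWarnings(saibr_calibrate(scene_stacks(scenes)))
}

# tiny constant-channel stack for arithmetic contracts
const_stack <- function(g, a, r = NULL, nr = 4, nc = 4, roi = NULL) {
  channel_stack(matrix(g, nr, nc), matrix(a, nr, nc),
                if (!is.null(r)) matrix(r, nr, nc), roi = roi)
}

# model with hand-set coefficients (bypasses fitting)
manual_model <- function(mode = "two_channel", m = NULL, m1 = NULL,
                         m2 = NULL, c = 0, s = NULL, radius = 0) {
  saibr:::new_saibr_model(mode, m = m, m1 = m1, m2 = m2, c = c, s = s,
                          gaussian_radius = radius, n_pixels = 10L,
                          r_squared = 1)
}

# embryo-interior stacks for spillover estimation
interior_stacks <- function(scenes, fraction = 0.9) {
  lapply(scenes, function(sc) {
    st <- sc$stack
    st$roi <- embryo_mask(sc, fraction)
    st
  })
}
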