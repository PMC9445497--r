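test_that("pixel pools concatenate ROI pixels with provenance", {
  scenes <- make_cohort(scene_params(seed = 3), 3)
  stacks <- scene_stacks(scenes)
  pool <- build_pixel_pool(stacks, radius = 2)
  expect_identical(nrow(pool), sum(vapply(stacks, function(s) sum(s$roi), 1L)))
  expect_identical(dplyr::n_distinct(pool$sample_id), 3L)

  # pool length is independent of the filter radius, values are not
  pool0 <- build_pixel_pool(stacks, radius = 0)
  expect_identical(nrow(pool0), nrow(pool))
  expect_false(isTRUE(all.equal(pool0$g, pool$g)))

  # single-pixel ROI: pool of length 1, rejected downstream
  one <- const_stack(5, 3, roi = {
    r <- matrix(FALSE, 4, 4); r[2, 2] <- TRUE; r
  })
  p1 <- suppressWarnings(build_pixel_pool(one, radius = 0))
  expect_identical(nrow(p1), 1L)
  expect_error(suppressWarnings(fit_two_channel(p1)),
               class = "saibr_error_insufficient")
})

test_that("saturated pixels are excluded from pools with a count", {
  g <- matrix(100, 4, 4); g[1, 1] <- 255
  st <- channel_stack(g, matrix(50, 4, 4), meta = list(bit_depth = 8))
  expect_message(pool <- build_pixel_pool(st, radius = 0), "saturated")
  expect_identical(nrow(pool), 15L)
  expect_identical(attr(pool, "n_saturated"), 1L)
})

test_that("two-channel fit reproduces exact and hand-solved regressions", {
  # exactly collinear points
  p <- tibble::tibble(sample_id = "s", a = c(0, 1, 2), g = c(1, 3, 5))
  m <- suppressWarnings(fit_two_channel(p))
  expect_equal(m$m, 2)
  expect_equal(m$c, 1)
  expect_equal(m$r_squared, 1)

  # hand-computed normal equations: m = 4/20, c = 0.2
  p2 <- tibble::tibble(sample_id = "s", a = 0:3, g = c(0, 1, 0, 1))
  m2 <- suppressWarnings(fit_two_channel(p2))
  expect_equal(m2$m, 0.2, tolerance = 1e-12)
  expect_equal(m2$c, 0.2, tolerance = 1e-12)

  expect_error(suppressWarnings(
    fit_two_channel(tibble::tibble(sample_id = "s", a = c(1, 1, 1),
                                   g = c(1, 2, 3)))),
    class = "saibr_error_degenerate")
})

test_that("OLS matches the explicit normal-equations oracle on small pools", {
  set.seed(7)
  for (i in 1:20) {
    n <- sample(3:10, 1)
    a <- rnorm(n); g <- rnorm(n)
    if (var(a) == 0) next
    fit <- suppressWarnings(
      fit_two_channel(tibble::tibble(sample_id = "s", a = a, g = g)))
    oracle <- ols_oracle(g, cbind(a))
    expect_equal(fit$c, oracle[1], tolerance = 1e-10)
    expect_equal(fit$m, oracle[2], tolerance = 1e-10)
  }
  for (i in 1:20) {
    n <- sample(4:10, 1)
    a <- rnorm(n); r <- rnorm(n); g <- rnorm(n)
    fit <- suppressWarnings(
      fit_three_channel(tibble::tibble(sample_id = "s", a = a, r = r, g = g)))
    oracle <- ols_oracle(g, cbind(a, r))
    expect_equal(fit$c, oracle[1], tolerance = 1e-10)
    expect_equal(fit$m1, oracle[2], tolerance = 1e-10)
    expect_equal(fit$m2, oracle[3], tolerance = 1e-10)
  }
})

test_that("fits are scale- and shift-covariant", {
  set.seed(8)
  pool <- tibble::tibble(sample_id = "s", a = runif(50, 0, 100),
                         g = runif(50, 0, 100))
  base <- suppressWarnings(fit_two_channel(pool))
  k <- 3.7; b <- 11.1
  scaled <- suppressWarnings(
    fit_two_channel(dplyr::mutate(pool, a = a * k)))
  expect_equal(scaled$m, base$m / k, tolerance = 1e-10)
  expect_equal(scaled$c, base$c, tolerance = 1e-8)
  shifted <- suppressWarnings(
    fit_two_channel(dplyr::mutate(pool, g = g + b)))
  expect_equal(shifted$m, base$m, tolerance = 1e-10)
  expect_equal(shifted$c, base$c + b, tolerance = 1e-8)
})

test_that("three-channel fit recovers exact planes and flags collinearity", {
  p <- tibble::tibble(sample_id = "s", a = c(0, 1, 0, 1), r = c(0, 0, 1, 1))
  p$g <- 1 * p$a + 2 * p$r + 3
  fit <- suppressWarnings(fit_three_channel(p))
  expect_equal(fit$m1, 1)
  expect_equal(fit$m2, 2)
  expect_equal(fit$c, 3)
  expect_equal(fit$r_squared, 1)

  pc <- tibble::tibble(sample_id = "s", a = c(0, 1, 2, 3), r = rep(5, 4),
                       g = 1:4 * 1.0)
  expect_error(suppressWarnings(fit_three_channel(pc)),
               class = "saibr_error_collinear")
  expect_error(suppressWarnings(fit_three_channel(
    tibble::tibble(sample_id = "s", a = c(0, 1, 2, 3), r = c(0, 2, 4, 6),
                   g = 1:4 * 1.0))),
    class = "saibr_error_collinear")
})

test_that("calibration recovers generator truth within tolerance", {
  mod <- fit_unlabeled_model(seed = 101)
  expect_lt(abs(mod$m - 1.8) / 1.8, 0.02)
  expect_lt(abs(mod$c - 100), 5)
  expect_gt(mod$r_squared, 0.99)

  # three-channel: m1 = m_true, m2 = -m_true * bleed slope
  scenes3 <- make_cohort(scene_params(rfp_bleed = 0.3, rfp_amplitude = 800,
                                      include_rfp = TRUE, seed = 102), 5)
  mod3 <- saibr_calibrate(scene_stacks(scenes3))
  expect_lt(abs(mod3$m1 - 1.8) / 1.8, 0.05)
  expect_lt(abs(mod3$m2 - (-1.8 * 0.3)) / (1.8 * 0.3), 0.05)
})

test_that("slope error shrinks as pooled pixels grow", {
  pool <- build_pixel_pool(
    scene_stacks(make_cohort(scene_params(seed = 103, noise_sd = 20), 8)),
    radius = 1)
  errs <- vapply(c(100, 1000, 10000), function(n) {
    reps <- vapply(1:20, function(r) {
      idx <- withr::with_seed(1000 + r, sample.int(nrow(pool), n))
      abs(suppressWarnings(fit_two_channel(pool[idx, ]))$m - 1.8)
    }, 1.0)
    mean(reps)
  }, 1.0)
  expect_true(all(diff(errs) < 0))
})

test_that("fit R^2 on noisy pools is non-decreasing in filter radius", {
  stacks <- scene_stacks(make_cohort(scene_params(seed = 104, noise_sd = 25), 4))
  r2 <- vapply(c(0, 1, 2), function(rad) {
    suppressWarnings(fit_two_channel(build_pixel_pool(stacks, radius = rad)))$r_squared
  }, 1.0)
  expect_true(all(diff(r2) >= 0))
})

test_that("whole-sample fit matches exact lines and needs enough samples", {
  mk <- function(g, a) const_stack(g, a)
  stacks <- list(mk(21, 10), mk(41, 20), mk(61, 30))
  # perfect fit: summary.lm warns that R^2 is unreliable, which is fine here
  fit <- suppressWarnings(fit_whole_sample(stacks, "two_channel"))
  expect_equal(fit$m, 2)
  expect_equal(fit$c, 1)
  expect_identical(fit$method, "whole_sample")

  expect_error(fit_whole_sample(stacks[1:2], "two_channel"),
               class = "saibr_error_insufficient")
})

test_that("whole-sample and pixel fits agree on homogeneous cohorts", {
  scenes <- make_cohort(scene_params(seed = 105, af_texture_cv = 0.05), 12)
  stacks <- scene_stacks(scenes)
  mp <- saibr_calibrate(stacks)
  mw <- fit_whole_sample(stacks, "two_channel")
  expect_lt(abs(mp$m - mw$m) / mp$m, 0.05)
  expect_lt(abs(mp$c - mw$c), 25)
})

test_that("a two-channel fit on RFP-contaminated data is biased, growing with RFP level", {
  slope_at <- function(amp) {
    scenes <- make_cohort(scene_params(rfp_bleed = 0.3, rfp_amplitude = amp,
                                       include_rfp = TRUE, seed = 106), 4)
    suppressWarnings(
      fit_two_channel(build_pixel_pool(scene_stacks(scenes), radius = 1)))$m
  }
  s0 <- slope_at(0); s1 <- slope_at(400); s2 <- slope_at(1200)
  # RFP inflates the AF channel without adding primary-channel AF, so the
  # apparent slope drops below the AF-only truth, increasingly with RFP
  expect_lt(s1, s0)
  expect_lt(s2, s1)
  expect_lt(abs(s0 - 1.8) / 1.8, 0.05)
})

test_that("spillover is recovered from bright samples and null on clean ones", {
  base <- fit_unlabeled_model(seed = 41, m_true = 0.5, c_true = 0, s_true = 0.1)
  bright <- make_cohort(scene_params(m_true = 0.5, c_true = 0, s_true = 0.1,
                                     gfp_layout = "nuclear_void",
                                     gfp_amplitude = 3000, seed = 51), 5)
  ms <- estimate_spillover(interior_stacks(bright), base)
  expect_lt(abs(ms$s - 0.1) / 0.1, 0.1)

  # s = 0 scenes: estimate statistically indistinguishable from 0
  null_sc <- make_cohort(scene_params(m_true = 0.5, c_true = 0, s_true = 0,
                                      gfp_layout = "nuclear_void",
                                      gfp_amplitude = 3000, seed = 61), 5)
  m0 <- suppressWarnings(estimate_spillover(interior_stacks(null_sc), base))
  expect_lt(abs(m0$s), 0.01)

  # pure-AF scenes: no usable fluorophore variation biases s towards 0 too
  af_only <- make_cohort(scene_params(m_true = 0.5, c_true = 0, seed = 71), 5)
  m_af <- suppressWarnings(estimate_spillover(interior_stacks(af_only), base))
  expect_lt(abs(m_af$s), 0.02)
})

test_that("tidy, glance and diagnostics describe the fit", {
  mod <- fit_unlabeled_model(seed = 107)
  td <- tidy(mod)
  expect_identical(td$term, c("(Intercept)", "a"))
  expect_true(all(is.finite(td$std.error)))
  gl <- glance(mod)
  expect_identical(gl$mode, "two_channel")
  expect_true(gl$r.squared > 0 && gl$r.squared <= 1)
  expect_identical(nrow(mod$per_sample), 5L)
  expect_true(all(mod$per_sample$r_squared > 0.9, na.rm = TRUE))
})
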