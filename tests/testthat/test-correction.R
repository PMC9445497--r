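test_that("inferred AF follows the fitted linear mapping pixel-wise", {
  st <- const_stack(0, 5)
  expect_equal(infer_af(st, manual_model(m = 2, c = 1)),
               matrix(11, 4, 4))
  st3 <- const_stack(0, 4, r = 1)
  expect_equal(infer_af(st3, manual_model("three_channel", m1 = 1, m2 = 2, c = 3)),
               matrix(9, 4, 4))
  # three-channel model on a stack without RFP predictor
  expect_error(infer_af(st, manual_model("three_channel", m1 = 1, m2 = 2, c = 3)),
               class = "saibr_error_config")
})

test_that("inferred AF tracks the latent AF field on synthetic scenes", {
  mod <- fit_unlabeled_model(seed = 11)
  sc <- make_scene(scene_params(seed = 90))
  interior <- embryo_mask(sc, 0.8)  # away from the embryo edge
  err_f <- (infer_af(sc$stack, mod) - sc$truth$G_af)[interior]
  err_r <- (infer_af(sc$stack, mod, filter_predictors = FALSE) -
              sc$truth$G_af)[interior]
  # raw predictors pass the AF-channel noise through at slope m;
  # filtering suppresses it
  expect_lt(sqrt(mean(err_f^2)), mod$m * 10)
  expect_lt(mean(abs(err_f)), mean(abs(err_r)))
})

test_that("correction subtracts inferred AF and rescales for spillover", {
  expect_equal(saibr_correct(const_stack(15, 5), manual_model(m = 2, c = 1))$corrected,
               matrix(4, 4, 4))
  # a calibration-consistent pure-AF pixel corrects to zero
  expect_equal(saibr_correct(const_stack(11, 5), manual_model(m = 2, c = 1))$corrected,
               matrix(0, 4, 4))
  # constructed spillover pixel: G_gfp=100, A_af=40, m=0.5, c=0, s=0.1
  # => A_obs = 50, G_obs = 120; uncompensated = 95, compensated = 100
  st <- const_stack(120, 50)
  expect_equal(saibr_correct(st, manual_model(m = 0.5, c = 0))$corrected[1, 1], 95)
  expect_equal(saibr_correct(st, manual_model(m = 0.5, c = 0, s = 0.1))$corrected[1, 1],
               100)
  # impossible spillover
  expect_error(saibr_correct(st, manual_model(m = 2, c = 0, s = 0.6)),
               class = "saibr_error_spillover")
})

test_that("corrected plus inferred AF reproduces the primary channel bit-for-bit", {
  mod <- fit_unlabeled_model(seed = 11)
  for (seed in c(90, 91)) {
    sc <- make_scene(scene_params(gfp_layout = "uniform_cytoplasm",
                                  gfp_amplitude = 300, seed = seed))
    res <- saibr_correct(sc$stack, mod)
    expect_identical(res$corrected + res$inferred_af, sc$stack$primary)
  }
})

test_that("correction is linear in the fluorophore component", {
  mod <- fit_unlabeled_model(seed = 11)
  p <- scene_params(gfp_layout = "uniform_cytoplasm", gfp_amplitude = 200,
                    seed = 95, quantize = FALSE, noise_sd = 0)
  sc1 <- make_scene(p)
  # add a second fluorophore component on top of the rendered primary channel
  p2 <- p; p2$gfp_amplitude <- 130
  sc2 <- make_scene(p2)
  extra <- sc2$truth$G_gfp
  st_sum <- sc1$stack
  st_sum$primary <- st_sum$primary + extra
  r1 <- saibr_correct(sc1$stack, mod)
  r12 <- saibr_correct(st_sum, mod)
  expect_equal(r12$roi_mean_corrected - r1$roi_mean_corrected,
               mean(extra[st_sum$roi]), tolerance = 1e-6)
})

test_that("batch correction preserves order and isolates failures", {
  mod3 <- manual_model("three_channel", m1 = 1, m2 = 0.5, c = 0)
  ok1 <- const_stack(10, 5, r = 2)
  ok2 <- const_stack(20, 5, r = 2)
  bad <- const_stack(10, 5)            # lacks the RFP predictor
  ok1$sample_id <- "s1"; ok2$sample_id <- "s2"; bad$sample_id <- "s3"

  out <- correct_batch(list(ok1, bad, ok2), mod3)
  expect_identical(out$sample_id, c("s1", "s3", "s2"))
  expect_identical(out$status[c(1, 3)], c("ok", "ok"))
  expect_match(out$status[2], "failed")
  expect_true(is.null(out$result[[2]]))
  expect_s3_class(out$result[[1]], "saibr_correction")

  empty <- correct_batch(list(), mod3)
  expect_identical(nrow(empty), 0L)
})

test_that("over-subtraction is reported and flagged by negative fraction", {
  allpos <- saibr_correct(const_stack(100, 10), manual_model(m = 2, c = 1))
  rep1 <- overcorrection_report(allpos)
  expect_identical(rep1$negative_fraction, 0)
  expect_false(rep1$flagged)

  allneg <- saibr_correct(const_stack(20, 10), manual_model(m = 2, c = 1))
  expect_identical(allneg$negative_fraction, 1)
  expect_true(overcorrection_report(allneg)$flagged)
  expect_equal(overcorrection_report(allneg)$mean_negative, -1)
})

test_that("RFP-expressing scenes flag under two-channel but not three-channel correction", {
  mod2 <- fit_unlabeled_model(seed = 31)
  scenes3 <- make_cohort(scene_params(rfp_bleed = 0.3, rfp_amplitude = 800,
                                      include_rfp = TRUE, seed = 21), 5)
  mod3 <- saibr_calibrate(scene_stacks(scenes3))

  sc <- make_scene(scene_params(rfp_bleed = 0.3, rfp_amplitude = 800,
                                include_rfp = TRUE,
                                gfp_layout = "uniform_cytoplasm",
                                gfp_amplitude = 300, seed = 77))
  st <- sc$stack
  st$roi <- embryo_mask(sc)  # quantification ROI encompasses the embryo
  r2 <- saibr_correct(st, mod2)
  r3 <- saibr_correct(st, mod3)
  expect_true(overcorrection_report(r2)$flagged)
  expect_false(overcorrection_report(r3)$flagged)
})

test_that("unlabeled scenes correct to zero mean within Monte Carlo error", {
  mod <- fit_unlabeled_model(seed = 11)
  scenes <- make_cohort(scene_params(seed = 301), 8)
  means <- vapply(scenes, function(sc) {
    saibr_correct(sc$stack, mod)$roi_mean_corrected
  }, 1.0)
  a_bar <- mean(vapply(scenes, function(sc) {
    mean(sc$stack$predictor_af[sc$stack$roi])
  }, 1.0))
  # total SE: between-scene spread plus calibration error shared by all scenes
  se <- sqrt(var(means) / length(means) + prediction_se(mod, a_bar)^2)
  expect_lt(abs(mean(means)), 3 * se)
})

test_that("predictor filtering at correction time is optional and suppresses noise", {
  # smooth AF at the filter scale: the regime predictor filtering targets
  mod <- fit_unlabeled_model(seed = 301, af_texture_cv = 0.05)
  sc <- make_scene(scene_params(af_texture_cv = 0.05, seed = 311))
  interior <- embryo_mask(sc, 0.8)
  r_filt <- saibr_correct(sc$stack, mod, filter_predictors = TRUE)
  r_raw <- saibr_correct(sc$stack, mod, filter_predictors = FALSE)
  expect_false(identical(r_filt$corrected, r_raw$corrected))
  expect_lt(sd(r_filt$corrected[interior]), sd(r_raw$corrected[interior]))
})

test_that("correction results round-trip to disk", {
  mod <- fit_unlabeled_model(seed = 11)
  sc <- make_scene(scene_params(seed = 90))
  res <- saibr_correct(sc$stack, mod)
  dir <- withr::local_tempdir()
  write_correction(res, dir, clip_display = TRUE)
  corr <- read_image(file.path(dir, paste0(sc$stack$sample_id, "_corrected.tif")))
  expect_equal(corr, res$corrected, tolerance = 1e-7)
  disp <- read_image(file.path(dir, paste0(sc$stack$sample_id,
                                           "_corrected_display.tif")))
  expect_gte(min(disp), 0)
})
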