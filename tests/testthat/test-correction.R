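make_fake_tuples <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(meas_x = stats::runif(n, -5, 5), meas_y = stats::runif(n, -5, 5),
             meas_z = stats::runif(n, 25, 45),
             meas_gx = stats::runif(n, -0.6, 0.6),
             meas_gy = stats::runif(n, -0.6, 0.6),
             meas_radius = stats::runif(n, 0.5, 4.5),
             circularity = stats::runif(n, 0.35, 1))
}

test_that("an identity-map training set is reproduced exactly", {
  tu <- make_fake_tuples(900)
  tu$true_x <- tu$meas_x; tu$true_y <- tu$meas_y; tu$true_z <- tu$meas_z
  tu$true_gx <- tu$meas_gx; tu$true_gy <- tu$meas_gy
  tu$true_radius <- tu$meas_radius
  mod <- fit_correction(tu, degree = 2)
  out <- apply_correction(tu, mod)
  expect_equal(out$x, tu$true_x, tolerance = 1e-6)
  expect_equal(out$z, tu$true_z, tolerance = 1e-6)
  expect_equal(out$radius_corrected_mm, tu$true_radius, tolerance = 1e-6)
  expect_false(any(out$outside_hull))
})

test_that("a known quadratic distortion is inverted to numerical precision", {
  tu <- make_fake_tuples(2000, seed = 4)
  # truth generated by a degree-2 map of the standardized measured variables
  zs <- (tu$meas_z - 35) / 6
  rs <- (tu$meas_radius - 2.5) / 1.2
  tu$true_x <- tu$meas_x + 0.3 * zs * rs
  tu$true_y <- tu$meas_y - 0.2 * rs^2
  tu$true_z <- tu$meas_z + 1.5 * rs + 0.4 * zs^2
  tu$true_gx <- tu$meas_gx + 0.05 * zs
  tu$true_gy <- tu$meas_gy - 0.04 * rs
  tu$true_radius <- tu$meas_radius * (1.1 + 0.05 * zs + 0.02 * rs^2)
  mod <- fit_correction(tu, degree = 3)
  out <- apply_correction(tu, mod)
  expect_equal(out$z, tu$true_z, tolerance = 1e-6)
  expect_equal(out$radius_corrected_mm, tu$true_radius, tolerance = 1e-6)
})

test_that("training-set size and rank requirements are enforced", {
  tu <- make_fake_tuples(50)
  tu$true_x <- tu$meas_x; tu$true_y <- tu$meas_y; tu$true_z <- tu$meas_z
  tu$true_gx <- tu$meas_gx; tu$true_gy <- tu$meas_gy
  tu$true_radius <- tu$meas_radius
  expect_error(fit_correction(tu, degree = 3), "tuples")
  # collapsing an input to a constant makes its monomials rank-deficient
  tu2 <- make_fake_tuples(900)
  tu2$true_x <- tu2$meas_x; tu2$true_y <- tu2$meas_y; tu2$true_z <- tu2$meas_z
  tu2$true_gx <- tu2$meas_gx; tu2$true_gy <- tu2$meas_gy
  tu2$true_radius <- tu2$meas_radius
  tu2$meas_gy <- 0.2
  expect_error(fit_correction(tu2, degree = 2), "rank-deficient")
})

test_that("corrected gaze is unit length and radii are never negative", {
  tu <- make_fake_tuples(900, seed = 9)
  tu$true_x <- tu$meas_x; tu$true_y <- tu$meas_y; tu$true_z <- tu$meas_z
  tu$true_gx <- pmin(0.99, tu$meas_gx * 1.5)   # push towards the unit bound
  tu$true_gy <- tu$meas_gy
  tu$true_radius <- pmax(0, tu$meas_radius - 2)  # drives small radii to 0
  mod <- fit_correction(tu, degree = 2)
  ev <- make_fake_tuples(300, seed = 10)
  out <- apply_correction(ev, mod)
  nrm <- sqrt(out$gaze_x^2 + out$gaze_y^2 + out$gaze_z^2)
  expect_equal(nrm, rep(1, nrow(out)), tolerance = 1e-12)
  expect_true(all(out$radius_corrected_mm >= 0))
  expect_error(apply_correction(ev, list()), "untrained")
})

test_that("the model serializes to JSON and restores bit-exactly", {
  tu <- make_fake_tuples(900, seed = 12)
  tu$true_x <- tu$meas_x + 0.1; tu$true_y <- tu$meas_y; tu$true_z <- tu$meas_z
  tu$true_gx <- tu$meas_gx; tu$true_gy <- tu$meas_gy
  tu$true_radius <- 1.05 * tu$meas_radius
  mod <- fit_correction(tu, degree = 2)
  path <- tempfile(fileext = ".json")
  write_correction_model(mod, path)
  back <- read_correction_model(path)
  expect_identical(mod, back)
  unlink(path)
})

test_that("raytraced tuples behave as the optics dictates", {
  # refraction OFF (tangent scenes): measured matches truth to about a percent
  cfg <- pfe_config(resolution = 200, n_frames = 30,
                    pupil_radius_range = c(1.5, 4))
  tu0 <- build_training_set(cfg, n_runs = 4, seed = 31, min_tuples = 60,
                            scene = "tangent")
  expect_lt(stats::median(abs(tu0$meas_radius - tu0$true_radius) /
                            tu0$true_radius), 0.01)
  # refraction ON: a single-scene config yields at most one tuple per frame
  cfg1 <- pfe_config(resolution = 100, n_frames = 12,
                     pupil_radius_range = c(2.5, 2.5),
                     position_box = list(x = c(0, 0), y = c(0, 0), z = c(35, 35)))
  tu1 <- build_training_set(cfg1, n_runs = 1, seed = 3, min_tuples = 1)
  expect_lte(nrow(tu1), 12)
  expect_true(all(tu1$true_x == 0 & tu1$true_z == 35))
})

test_that("correction strictly improves held-out radius RMSE and depth bias", {
  cfg <- pfe_config(resolution = 150, n_frames = 40,
                    pupil_radius_range = c(1, 4))
  tu <- build_training_set(cfg, n_runs = 40, seed = 51, min_tuples = 700)
  mod <- fit_correction(tu, degree = 2)
  held <- build_training_set(cfg, n_runs = 8, seed = 5151, min_tuples = 120)
  out <- apply_correction(held, mod)
  rmse_unc <- sqrt(mean((held$meas_radius - held$true_radius)^2))
  rmse_cor <- sqrt(mean((out$radius_corrected_mm - held$true_radius)^2))
  expect_lt(rmse_cor, rmse_unc)
  expect_lt(abs(mean(out$z - held$true_z)), abs(mean(held$meas_z - held$true_z)))
  # refraction magnification: correction increases the measured radius overall
  expect_gt(mean(out$radius_corrected_mm > held$meas_radius), 0.5)
})
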