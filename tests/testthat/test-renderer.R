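test_that("physiological parameter sampling matches the configured distributions", {
  cfg <- pfe_config()
  set.seed(11)
  n <- 20000
  draws <- replicate(n, unlist(sample_eye_parameters(cfg)[
    c("eyeball_radius", "cornea_radius", "iris_radius")]))
  m <- rowMeans(draws); s <- apply(draws, 1, sd)
  # sample means within 3 standard errors of the configured means
  expect_lt(abs(m[1] - 12.0), 3 * 1.0 / sqrt(n))
  expect_lt(abs(m[2] - 7.81), 3 * 0.24 / sqrt(n))
  expect_lt(abs(m[3] - 5.57), 3 * 0.28 / sqrt(n))
  expect_equal(unname(s[1]), 1.0, tolerance = 0.02)
  # zero-spread configuration degenerates to the means
  cfg0 <- cfg
  cfg0$eye_distributions[c("eyeball_sd", "cornea_sd", "iris_sd")] <- 0
  e0 <- sample_eye_parameters(cfg0)
  expect_equal(e0$eyeball_radius, 12.0)
  expect_equal(e0$cornea_radius, 7.81)
  expect_equal(e0$iris_radius, 5.57)
})

test_that("eye geometry places pupil and cornea on the optical axis", {
  eye <- legrand_eye()
  pose <- eye_pose(c(0, 0, 30), c(0, 0, -1))
  scn <- build_eye_geometry(eye, pose, 2)
  expect_equal(scn$pupil$center[1:2], c(0, 0))
  expect_equal(scn$pupil$normal, pose$gaze_direction)
  # iris rim lies on the eyeball sphere; corneal apex 3.6 mm in front of it
  d_iris <- sqrt(12^2 - 5.57^2)
  expect_equal(scn$iris$center[3], 30 - d_iris)
  apex_z <- scn$cornea$center[3] - eye$cornea_radius
  expect_equal(scn$iris$center[3] - apex_z, 3.6)
  # rigid rotation: distance from pupil centre to eyeball centre is invariant
  pose2 <- eye_pose(c(0, 0, 30), gaze_from_angles(35, 1.1))
  scn2 <- build_eye_geometry(eye, pose2, 2)
  expect_equal(sqrt(sum((scn2$pupil$center - c(0, 0, 30))^2)), d_iris)
  expect_equal(scn2$pupil$normal, pose2$gaze_direction)
  expect_error(build_eye_geometry(eye, pose, 6), "anatomy")
})

test_that("rendered labels are four-valued and conserve pixel counts", {
  cfg <- pfe_config(resolution = 100)
  scn <- build_eye_geometry(legrand_eye(), eye_pose(c(0, 0, 35), c(0, 0, -1)), 2)
  img <- render_eye_image(scn, cfg$camera)
  tab <- table(factor(unclass(img), levels = 0:3))
  expect_equal(sum(tab), 100 * 100)
  expect_true(all(tab > 0))
  expect_error(render_eye_image(scn, pinhole_camera(20, c(16, 16))), "32")
})

test_that("a frontal on-axis eye renders a near-circular pupil", {
  cfg <- pfe_config(resolution = 200)
  scn <- build_eye_geometry(legrand_eye(), eye_pose(c(0, 0, 35), c(0, 0, -1)), 2)
  d <- detect_pupil(render_eye_image(scn, cfg$camera))
  expect_gte(d$circularity, 0.99)
})

test_that("pupil pixel area decreases as gaze angle grows", {
  cfg <- pfe_config(resolution = 200)
  eye <- legrand_eye()
  areas <- vapply(seq(0, 60, by = 10), function(a) {
    scn <- build_eye_geometry(eye, eye_pose(c(0, 0, 45), gaze_from_angles(a, 0)), 2)
    sum(unclass(render_eye_image(scn, cfg$camera)) == pfe_labels[["pupil"]])
  }, 0)
  expect_true(all(diff(areas) < 0))
})

test_that("refraction-off rendering matches the exact projection oracle", {
  cfg <- pfe_config(resolution = 400)
  scn <- build_eye_geometry(legrand_eye(n_ref = 1),
                            eye_pose(c(2, -1, 33), gaze_from_angles(25, 0.8)), 2)
  d <- detect_pupil(render_eye_image(scn, cfg$camera))
  oracle <- project_circle(scn$pupil, cfg$camera)
  expect_lt(abs(d$ellipse$major_axis - oracle$major_axis), 0.5)
  expect_lt(abs(d$ellipse$minor_axis - oracle$minor_axis), 0.5)
  expect_lt(max(abs(d$ellipse$center - oracle$center)), 0.5)
})

test_that("corneal refraction magnifies the apparent pupil", {
  cfg <- pfe_config(resolution = 200)
  pose <- eye_pose(c(2, -1, 33), gaze_from_angles(25, 0.8))
  on <- detect_pupil(render_eye_image(
    build_eye_geometry(legrand_eye(), pose, 2), cfg$camera))
  off <- detect_pupil(render_eye_image(
    build_eye_geometry(legrand_eye(n_ref = 1), pose, 2), cfg$camera))
  expect_gt(on$ellipse$major_axis, off$ellipse$major_axis)
})

test_that("partial-visibility screening flags border pupils and empty frames", {
  cfg <- pfe_config(resolution = 100)
  eye <- legrand_eye()
  ok <- render_eye_image(build_eye_geometry(
    eye, eye_pose(c(0, 0, 35), c(0, 0, -1)), 2), cfg$camera)
  expect_true(pupil_fully_visible(ok))
  clipped <- render_eye_image(build_eye_geometry(
    eye, eye_pose(c(14, 0, 26), gaze_from_angles(45, 0)), 3), cfg$camera)
  expect_false(pupil_fully_visible(clipped))
  empty <- structure(matrix(pfe_labels[["sclera"]], 50, 50),
                     class = "label_image")
  expect_false(pupil_fully_visible(empty))
})

test_that("noiseless runs have constant per-frame radius; noisy runs fluctuate as configured", {
  cfg <- pfe_config(resolution = 100, n_frames = 30, pupil_radius_range = c(2, 4))
  sim <- simulate_run(cfg, seed = 8)
  expect_equal(sd(sim$frames$true_radius_mm), 0)
  expect_equal(sim$sigma_run, 0)
  cfgn <- pfe_config(resolution = 100, n_frames = 400,
                     pupil_radius_range = c(3, 3),
                     noise_sigma = list(mean = 0.05, sd = 0, lo = 0, hi = 0.1))
  simn <- simulate_run(cfgn, seed = 8, noise = TRUE)
  expect_equal(simn$sigma_run, 0.05)
  factors <- simn$frames$true_radius_mm / simn$base_radius
  # sample sd of the multiplicative factors within 3 SE of 0.05
  n <- length(factors)
  expect_lt(abs(sd(factors) - 0.05), 3 * 0.05 / sqrt(2 * (n - 1)))
})

test_that("runs are bit-identical under the same seed and share poses across noise settings", {
  cfg <- pfe_config(resolution = 100, n_frames = 15, pupil_radius_range = c(2, 4))
  a <- simulate_run(cfg, seed = 123)
  b <- simulate_run(cfg, seed = 123)
  expect_identical(a$frames, b$frames)
  nz <- simulate_run(cfg, seed = 123, noise = TRUE)
  shared <- intersect(a$frames$frame, nz$frames$frame)
  expect_gt(length(shared), 0)
  expect_equal(a$frames$gaze_angle_deg[match(shared, a$frames$frame)],
               nz$frames$gaze_angle_deg[match(shared, nz$frames$frame)])
})

test_that("label images round-trip through PNG with the fixed gray map", {
  cfg <- pfe_config(resolution = 100)
  scn <- build_eye_geometry(legrand_eye(), eye_pose(c(0, 0, 35), c(0, 0, -1)), 2)
  img <- render_eye_image(scn, cfg$camera)
  path <- tempfile(fileext = ".png")
  write_label_png(img, path)
  back <- png::readPNG(path)
  expect_equal(round(back * 3), unclass(img), ignore_attr = TRUE)
  unlink(path)
})
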