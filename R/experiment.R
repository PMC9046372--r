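# Orchestration of the canned end-to-end experiments: the population-level
# simulation study (render -> detect -> sphere fit -> three measures ->
# correction -> aggregation) and the apparent-pupil-area demonstration.

#' Train the refraction-correction model used by an experiment
#'
#' Convenience wrapper: raytraces an independent training set on the
#' mean-parameter eye and fits the polynomial correction.
#'
#' @param config See [pfe_config()].
#' @param n_runs Training recordings.
#' @param seed Master seed for the training set.
#' @param degree Polynomial degree.
#' @return A `correction_model`.
#' @export
train_correction_model <- function(config = pfe_config(), n_runs = 30,
                                   seed = 90001, degree = 3) {
  tuples <- build_training_set(config, n_runs = n_runs, seed = seed,
                               min_tuples = 10 *
                                 nrow(monomial_exponents(7, degree)))
  fit_correction(tuples, degree = degree)
}

# Measure one simulated run with all three methods; returns the long
# measurements data frame (one row per frame and method) or NULL on failure.
measure_run_all_methods <- function(sim, config, model, run_id) {
  frames <- sim$frames
  if (is.null(frames) || nrow(frames) < 10) return(NULL)
  sp <- tryCatch(estimate_sphere(frames, config$camera, config$sphere_radius),
                 error = function(e) NULL)
  if (is.null(sp)) return(NULL)
  mm <- measure_run_3d1p(frames, sp, config$camera)
  if (mean(is.na(mm$radius_uncorrected_mm)) > 0.5) return(NULL)
  meas <- data.frame(meas_x = sp$center[1], meas_y = sp$center[2],
                     meas_z = sp$center[3],
                     meas_gx = mm$est_gaze_x, meas_gy = mm$est_gaze_y,
                     meas_radius = mm$radius_uncorrected_mm,
                     circularity = mm$circularity)
  corrected <- rep(NA_real_, nrow(mm))
  ok <- stats::complete.cases(meas)
  if (!is.null(model) && any(ok))
    corrected[ok] <- apply_correction(meas[ok, , drop = FALSE],
                                      model)$radius_corrected_mm
  base <- data.frame(run_id = run_id, frame = mm$frame,
                     major_px = mm$major_px, circularity = mm$circularity,
                     confidence = mm$confidence,
                     true_radius_mm = mm$true_radius_mm,
                     gaze_angle_deg = mm$gaze_angle_deg)
  rbind(
    cbind(base, method = "2D-0p", value = mm$major_px),
    cbind(base, method = "3D-1p", value = mm$radius_uncorrected_mm),
    if (!is.null(model)) cbind(base, method = "3D-4p", value = corrected))
}

#' Run the population-level PFE simulation experiment
#'
#' Simulates `n_runs` synthetic recordings (each a random eye, eyeball
#' position, and constant base pupil radius, with per-frame random gaze),
#' measures every frame with the three methods, and aggregates to
#' subject-level profiles and population statistics.
#'
#' @param config See [pfe_config()].
#' @param n_runs Number of simulated recordings.
#' @param seed Master seed; per-run seeds derive from it.
#' @param noise Enable per-frame multiplicative pupil-size noise.
#' @param model A `correction_model` for the 3D-4p method, or `NULL` to train
#'   one on the fly (`train_runs` recordings, independent seed stream).
#' @param train_runs Training recordings when `model` is `NULL`.
#' @return List with `measurements`, `profiles`, `population` (per method),
#'   and a `manifest` (seeds, scale, per-run status, discard counts).
#' @export
run_pfe_experiment <- function(config = pfe_config(), n_runs = 60, seed = 1,
                               noise = FALSE, model = NULL, train_runs = 30) {
  if (is.null(model))
    model <- train_correction_model(config, n_runs = train_runs,
                                    seed = derive_seed(seed, 777001))
  meas <- vector("list", n_runs)
  status <- data.frame(run = seq_len(n_runs), seed = NA_integer_,
                       n_frames = 0L, n_partial = 0L, n_detect_fail = 0L,
                       ok = FALSE)
  for (k in seq_len(n_runs)) {
    run_seed <- derive_seed(seed, k)
    status$seed[k] <- run_seed
    sim <- simulate_run(config, seed = run_seed, noise = noise)
    status$n_frames[k] <- if (is.null(sim$frames)) 0L else nrow(sim$frames)
    status$n_partial[k] <- sim$n_partial
    status$n_detect_fail[k] <- sim$n_detect_fail
    m <- measure_run_all_methods(sim, config, model, run_id = k)
    if (!is.null(m)) { meas[[k]] <- m; status$ok[k] <- TRUE }
  }
  measurements <- do.call(rbind, meas[!vapply(meas, is.null, TRUE)])
  if (is.null(measurements)) stop("all runs failed")
  agg <- aggregate_measurements(measurements,
                                confidence_threshold = config$confidence_threshold,
                                outlier_tolerance = config$outlier_tolerance)
  list(measurements = measurements, profiles = agg$profiles,
       population = agg$population, model = model,
       manifest = list(master_seed = seed, n_runs = n_runs, noise = noise,
                       resolution = config$camera$image_size,
                       n_frames = config$n_frames, runs = status,
                       failed_profiles = agg$failed))
}

#' Apparent 2D pupil area as a function of gaze angle
#'
#' Raytraces a mean-parameter eye over a grid of gaze angles for several 3D
#' pupil radii and counts pupil-labeled pixels: the classic demonstration of
#' pupil foreshortening of the apparent area.
#'
#' @param config See [pfe_config()].
#' @param radii 3D pupil radii in mm.
#' @param angles Gaze angles in degrees.
#' @param eyeball_center Fixed eyeball position (mm).
#' @return Data frame `gaze_angle_deg`, `pupil_radius_mm`, `area_px`.
#' @export
pupil_area_vs_gaze <- function(config = pfe_config(),
                               radii = c(1, 2, 3, 4),
                               angles = seq(0, 60, by = 2),
                               eyeball_center = c(0, 0, 45)) {
  eye <- legrand_eye(config$eye_distributions$eyeball_mean,
                     config$eye_distributions$cornea_mean,
                     config$eye_distributions$iris_mean,
                     config$eye_distributions$n_ref)
  out <- expand.grid(gaze_angle_deg = angles, pupil_radius_mm = radii)
  out$area_px <- NA_real_
  for (i in seq_len(nrow(out))) {
    pose <- eye_pose(eyeball_center, gaze_from_angles(out$gaze_angle_deg[i], 0))
    if (out$pupil_radius_mm[i] <= 0) { out$area_px[i] <- 0; next }
    scn <- build_eye_geometry(eye, pose, out$pupil_radius_mm[i])
    img <- render_eye_image(scn, config$camera)
    out$area_px[i] <- sum(unclass(img) == pfe_labels[["pupil"]])
  }
  out
}

#' Gaze angle at which pupil circularity crosses a given value
#'
#' Renders a mean-parameter eye at a fixed position over a fine grid of gaze
#' angles and linearly interpolates the angle at which the fitted 2D pupil
#' circularity crosses `target` (the paper-style proxy mapping between
#' circularity and gaze angle).
#'
#' @param config See [pfe_config()].
#' @param target Circularity value to cross.
#' @param eyeball_center Eye position; on the camera axis, deep enough that
#'   extreme-angle pupils stay fully in frame.
#' @param pupil_radius Pupil radius in mm.
#' @param angles Grid of gaze angles (degrees).
#' @return List with `angle_deg` (interpolated crossing) and the `curve`.
#' @export
circularity_gaze_crossing <- function(config = pfe_config(), target = 0.4,
                                      eyeball_center = c(0, 0, 45),
                                      pupil_radius = 2,
                                      angles = seq(0, 70, by = 1)) {
  eye <- legrand_eye(config$eye_distributions$eyeball_mean,
                     config$eye_distributions$cornea_mean,
                     config$eye_distributions$iris_mean,
                     config$eye_distributions$n_ref)
  C <- rep(NA_real_, length(angles))
  for (i in seq_along(angles)) {
    pose <- eye_pose(eyeball_center, gaze_from_angles(angles[i], 0))
    img <- render_eye_image(build_eye_geometry(eye, pose, pupil_radius),
                            config$camera)
    if (!pupil_fully_visible(img)) next
    d <- detect_pupil(img)
    if (d$ok) C[i] <- d$circularity
  }
  ok <- !is.na(C)
  cross <- stats::approx(C[ok], angles[ok], xout = target, ties = mean)$y
  list(angle_deg = cross, curve = data.frame(gaze_angle_deg = angles,
                                             circularity = C))
}

#' Uncorrected radius error across a refraction-on gaze sweep
#'
#' Renders a mean-parameter LeGrand eye at a fixed position over a gaze sweep
#' (angles crossed with azimuths, so the sweep constrains the sphere fit in
#' both image directions), estimates the eye sphere from the sweep, and
#' reports the refraction-unaware (3D-1p) radius at each gaze angle next to
#' ground truth. The deviation at large angles quantifies the corneal
#' refraction error the 3D-4p method corrects.
#'
#' @param config See [pfe_config()].
#' @param angles Gaze angles in degrees.
#' @param azimuths Azimuths in radians, cycled across angles.
#' @param eyeball_center Eye position; deep enough on the camera axis that
#'   the largest angle stays fully visible.
#' @param pupil_radius True pupil radius in mm.
#' @return Data frame with per-angle mean measured radius and relative
#'   deviation (`rel_dev_pct`), plus the sphere estimate as attribute.
#' @export
gaze_sweep_error <- function(config = pfe_config(),
                             angles = seq(0, 60, by = 2),
                             azimuths = c(0, pi / 2, pi, 3 * pi / 2),
                             eyeball_center = c(0, 0, 45),
                             pupil_radius = 2) {
  eye <- legrand_eye(config$eye_distributions$eyeball_mean,
                     config$eye_distributions$cornea_mean,
                     config$eye_distributions$iris_mean,
                     config$eye_distributions$n_ref)
  grid <- expand.grid(azimuth = azimuths, angle = angles)
  rows <- list()
  for (i in seq_len(nrow(grid))) {
    pose <- eye_pose(eyeball_center,
                     gaze_from_angles(grid$angle[i], grid$azimuth[i]))
    img <- render_eye_image(build_eye_geometry(eye, pose, pupil_radius),
                            config$camera)
    if (!pupil_fully_visible(img)) next
    det <- detect_pupil(img, min_pixels = config$min_pupil_pixels)
    if (!det$ok) next
    el <- correct_principal_point(det$ellipse, config$camera)
    rows[[length(rows) + 1]] <- data.frame(
      frame = i, gaze_deg = grid$angle[i],
      cx = el$center[1], cy = el$center[2],
      major_px = el$major_axis, minor_px = el$minor_axis,
      angle_rad = el$angle, circularity = det$circularity, confidence = 1)
  }
  det <- do.call(rbind, rows)
  sp <- estimate_sphere(det, config$camera, config$sphere_radius)
  mm <- measure_run_3d1p(det, sp, config$camera)
  agg <- stats::aggregate(cbind(radius = radius_uncorrected_mm,
                                circularity = circularity) ~ gaze_deg,
                          data = mm, FUN = mean)
  agg$rel_dev_pct <- (agg$radius - pupil_radius) / pupil_radius * 100
  attr(agg, "sphere") <- sp
  attr(agg, "true_center") <- eyeball_center
  agg
}

#' Write experiment outputs as tidy CSVs
#'
#' @param experiment Output of [run_pfe_experiment()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_experiment_csvs <- function(experiment, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(profiles = file.path(dir, "profiles.csv"),
             population = file.path(dir, "population.csv"),
             measurements = file.path(dir, "measurements.csv"))
  utils::write.csv(experiment$profiles, paths["profiles"], row.names = FALSE)
  pop <- do.call(rbind, lapply(names(experiment$population), function(m)
    cbind(method = m, experiment$population[[m]])))
  utils::write.csv(pop, paths["population"], row.names = FALSE)
  utils::write.csv(experiment$measurements, paths["measurements"],
                   row.names = FALSE)
  invisible(paths)
}
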