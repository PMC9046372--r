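# The refraction-aware 3D-4p method: multivariate polynomial correction
# functions learned from raytraced (measured, truth) tuples and applied to
# 3D-1p outputs. Inputs are the measured sphere position (mm), the measured
# gaze (transverse components g_x, g_y), the measured radius (mm), and the
# pupil-ellipse circularity, all standardised to the training set; outputs
# are the corrected position, gaze, and radius. Position and gaze are fitted
# as absolute polynomial outputs; the radius is fitted multiplicatively
# (polynomial for the ratio truth/measured), matching the multiplicative
# nature of refraction magnification.

# Exponent table for all monomials of total degree <= degree in nvar
# variables, one row per monomial.
monomial_exponents <- function(nvar, degree) {
  grid <- do.call(expand.grid, rep(list(0:degree), nvar))
  grid <- grid[rowSums(grid) <= degree, , drop = FALSE]
  out <- as.matrix(grid[order(rowSums(grid)), , drop = FALSE])
  dimnames(out) <- NULL
  out
}

# Design matrix of monomials for standardized inputs X (n x nvar).
monomial_design <- function(X, expo) {
  n <- nrow(X)
  D <- matrix(1, n, nrow(expo))
  for (j in seq_len(nrow(expo))) for (v in seq_len(ncol(expo)))
    if (expo[j, v] > 0) D[, j] <- D[, j] * X[, v]^expo[j, v]
  D
}

measured_inputs <- function(tuples) {
  as.matrix(tuples[, c("meas_x", "meas_y", "meas_z",
                       "meas_gx", "meas_gy", "meas_radius", "circularity")])
}

#' Build a raytraced training set for the refraction correction
#'
#' Renders refraction-on recordings of the mean-parameter LeGrand eye
#' (positions, gaze angles, and pupil radii varied over the configured
#' physiological ranges), runs detection and the refraction-unaware 3D-1p fit
#' on them, and emits one (measured, truth) tuple per usable frame.
#'
#' @param config See [pfe_config()]. Pupil radius is drawn per recording
#'   (constant within a run, uniform over `pupil_radius_range`), matching the
#'   conditions under which the eye-sphere estimate is later produced.
#' @param n_runs Number of simulated recordings.
#' @param seed Master seed; per-run seeds are derived from it.
#' @param min_tuples Error if fewer usable tuples result.
#' @param scene `"legrand"` (refraction on, the default) or `"tangent"`
#'   (model-consistent cornea-free scenes, for oracle tests).
#' @return Data frame of tuples with measured and ground-truth position,
#'   gaze, and radius, plus `circularity` and `run`.
#' @export
build_training_set <- function(config = pfe_config(), n_runs = 30, seed = 1,
                               min_tuples = 50, scene = c("legrand", "tangent")) {
  scene <- match.arg(scene)
  cfg <- config
  eye <- legrand_eye(cfg$eye_distributions$eyeball_mean,
                     cfg$eye_distributions$cornea_mean,
                     cfg$eye_distributions$iris_mean,
                     cfg$eye_distributions$n_ref)
  out <- vector("list", n_runs)
  n_failed_runs <- 0L
  for (k in seq_len(n_runs)) {
    run_seed <- derive_seed(seed, k)
    sim <- if (scene == "legrand") {
      simulate_run(cfg, seed = run_seed, eye = eye)
    } else {
      simulate_tangent_run(cfg, seed = run_seed)
    }
    if (is.null(sim$frames) || nrow(sim$frames) < 10) {
      n_failed_runs <- n_failed_runs + 1L
      next
    }
    sp <- tryCatch(estimate_sphere(sim$frames, cfg$camera, cfg$sphere_radius),
                   error = function(e) NULL)
    if (is.null(sp)) { n_failed_runs <- n_failed_runs + 1L; next }
    mm <- measure_run_3d1p(sim$frames, sp, cfg$camera)
    mm <- mm[!is.na(mm$radius_uncorrected_mm), , drop = FALSE]
    if (nrow(mm) == 0) { n_failed_runs <- n_failed_runs + 1L; next }
    out[[k]] <- data.frame(
      run = k,
      meas_x = sp$center[1], meas_y = sp$center[2], meas_z = sp$center[3],
      meas_gx = mm$est_gaze_x, meas_gy = mm$est_gaze_y,
      meas_radius = mm$radius_uncorrected_mm,
      true_x = sim$eyeball_center[1], true_y = sim$eyeball_center[2],
      true_z = sim$eyeball_center[3],
      true_gx = mm$gaze_x, true_gy = mm$gaze_y,
      true_radius = mm$true_radius_mm,
      circularity = mm$circularity)
  }
  tuples <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(tuples) || nrow(tuples) < min_tuples)
    stop("insufficient training tuples (", if (is.null(tuples)) 0 else nrow(tuples),
         " < ", min_tuples, ")")
  attr(tuples, "n_failed_runs") <- n_failed_runs
  tuples
}

# Tangent-scene analogue of simulate_run (used for oracle tests of the
# correction machinery: measured should match truth up to discretisation).
simulate_tangent_run <- function(config, seed) {
  set.seed(sane_seed(seed))
  camera <- config$camera
  pos <- c(stats::runif(1, config$position_box$x[1], config$position_box$x[2]),
           stats::runif(1, config$position_box$y[1], config$position_box$y[2]),
           stats::runif(1, config$position_box$z[1], config$position_box$z[2]))
  nfr <- config$n_frames
  polar <- stats::runif(nfr, config$gaze_polar_range[1], config$gaze_polar_range[2])
  azim <- stats::runif(nfr, 0, 2 * pi)
  radii <- stats::runif(nfr, config$pupil_radius_range[1],
                        config$pupil_radius_range[2])
  rows <- vector("list", nfr)
  for (k in seq_len(nfr)) {
    pose <- eye_pose(pos, gaze_from_angles(polar[k], azim[k]))
    scn <- build_tangent_eye_geometry(pose, radii[k], config$sphere_radius)
    img <- render_eye_image(scn, camera)
    if (!pupil_fully_visible(img)) next
    det <- detect_pupil(img, min_pixels = config$min_pupil_pixels)
    if (!det$ok) next
    el <- correct_principal_point(det$ellipse, camera)
    rows[[k]] <- data.frame(
      frame = k, gaze_angle_deg = pose$gaze_angle_deg,
      gaze_x = pose$gaze_direction[1], gaze_y = pose$gaze_direction[2],
      gaze_z = pose$gaze_direction[3], true_radius_mm = radii[k],
      cx = el$center[1], cy = el$center[2],
      major_px = el$major_axis, minor_px = el$minor_axis,
      angle_rad = el$angle, circularity = det$circularity,
      confidence = det$confidence, n_pupil_px = det$n_pixels)
  }
  frames <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  list(frames = frames, eyeball_center = pos, camera = camera, seed = seed)
}

#' Fit the polynomial correction model
#'
#' Per-component least-squares polynomial regression in the standardized
#' measured variables (position, transverse gaze, radius, circularity).
#' Position and gaze components regress the ground truth directly; the radius
#' component regresses the ratio ground truth / measured, so the corrected
#' radius is a multiplicative rescaling of the measured one.
#'
#' @param tuples From [build_training_set()], or any data frame with the same
#'   measured/truth columns.
#' @param degree Total polynomial degree (>= 1).
#' @return An object of class `correction_model`: degree, standardization
#'   constants, exponent table, per-component coefficients, training summary
#'   (n, residual RMS per component), and the training-input hull (ranges).
#' @export
fit_correction <- function(tuples, degree = 3) {
  stopifnot(degree >= 1)
  X <- measured_inputs(tuples)
  outputs <- c("true_x", "true_y", "true_z", "true_gx", "true_gy",
               "radius_ratio")
  expo <- monomial_exponents(ncol(X), degree)
  if (nrow(tuples) < 10 * nrow(expo))
    stop("need at least ", 10 * nrow(expo), " tuples for degree ", degree,
         " (", nrow(expo), " monomials); got ", nrow(tuples))
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  sdv[sdv < 1e-12] <- 1
  Xs <- sweep(sweep(X, 2, mu), 2, sdv, "/")
  D <- monomial_design(Xs, expo)
  qrD <- qr(D)
  if (qrD$rank < ncol(D)) {
    bad <- setdiff(seq_len(ncol(D)), qrD$pivot[seq_len(qrD$rank)])
    stop("rank-deficient polynomial design; deficient monomials (exponent rows): ",
         paste(bad, collapse = ", "))
  }
  Y <- cbind(as.matrix(tuples[, c("true_x", "true_y", "true_z",
                                  "true_gx", "true_gy")]),
             radius_ratio = tuples$true_radius / tuples$meas_radius)
  coefs <- qr.coef(qrD, Y)
  resid <- Y - D %*% coefs
  structure(list(degree = degree,
                 input_names = colnames(X),
                 output_names = outputs,
                 standardization = list(mean = mu, sd = sdv),
                 exponents = expo,
                 coefficients = coefs,
                 hull = apply(X, 2, range),
                 training = list(n = nrow(tuples),
                                 rms = sqrt(colMeans(resid^2)))),
            class = "correction_model")
}

#' Apply the refraction correction to 3D-1p measurements
#'
#' @param measurements Data frame with columns `meas_x`, `meas_y`, `meas_z`,
#'   `meas_gx`, `meas_gy`, `meas_radius`, `circularity` (as produced by
#'   [build_training_set()] or assembled from [measure_run_3d1p()] output plus
#'   the sphere estimate).
#' @param model A `correction_model`.
#' @return Data frame with corrected position (`x`, `y`, `z`), unit gaze
#'   (`gaze_x/y/z`, renormalized, camera-facing), `radius_corrected_mm`
#'   (clamped at 0), and `outside_hull` flag for inputs outside the training
#'   ranges.
#' @export
apply_correction <- function(measurements, model) {
  if (!inherits(model, "correction_model")) stop("untrained or invalid model")
  X <- as.matrix(measurements[, model$input_names])
  if (any(!is.finite(X))) stop("non-finite inputs to correction")
  Xs <- sweep(sweep(X, 2, model$standardization$mean), 2,
              model$standardization$sd, "/")
  D <- monomial_design(Xs, model$exponents)
  Y <- D %*% model$coefficients
  colnames(Y) <- model$output_names
  radius <- X[, "meas_radius"] * Y[, "radius_ratio"]
  gx <- Y[, "true_gx"]; gy <- Y[, "true_gy"]
  t2 <- gx^2 + gy^2
  scl <- ifelse(t2 > 1, 1 / sqrt(t2 + 1e-12), 1)
  gx <- gx * scl; gy <- gy * scl
  gz <- -sqrt(pmax(0, 1 - gx^2 - gy^2))
  nrm <- sqrt(gx^2 + gy^2 + gz^2)
  outside <- rowSums(X < matrix(model$hull[1, ], nrow(X), ncol(X), byrow = TRUE) |
                     X > matrix(model$hull[2, ], nrow(X), ncol(X), byrow = TRUE)) > 0
  data.frame(x = Y[, "true_x"], y = Y[, "true_y"], z = Y[, "true_z"],
             gaze_x = gx / nrm, gaze_y = gy / nrm, gaze_z = gz / nrm,
             radius_corrected_mm = pmax(0, radius),
             outside_hull = outside)
}

#' Serialise / restore a correction model as JSON
#'
#' Round-trips bit-exactly (coefficients stored at full precision).
#' @param model A `correction_model`.
#' @param path File path.
#' @export
write_correction_model <- function(model, path) {
  obj <- list(degree = model$degree, input_names = model$input_names,
              output_names = model$output_names,
              standardization = model$standardization,
              exponents = model$exponents,
              coefficients = model$coefficients,
              hull = model$hull,
              training = model$training)
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_correction_model
#' @export
read_correction_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  co <- as.matrix(obj$coefficients)
  dimnames(co) <- list(NULL, obj$output_names)
  expo <- as.matrix(obj$exponents)
  dimnames(expo) <- NULL
  hull <- as.matrix(obj$hull)
  dimnames(hull) <- list(NULL, obj$input_names)
  storage.mode(expo) <- "integer"
  structure(list(degree = as.numeric(obj$degree), input_names = obj$input_names,
                 output_names = obj$output_names,
                 standardization = list(mean = stats::setNames(obj$standardization$mean, obj$input_names),
                                        sd = stats::setNames(obj$standardization$sd, obj$input_names)),
                 exponents = expo,
                 coefficients = co,
                 hull = hull,
                 training = list(n = as.integer(obj$training$n),
                                 rms = stats::setNames(obj$training$rms,
                                                       obj$output_names))),
            class = "correction_model")
}

# Counter-based per-run seed splitter: reproducible independent run seeds
# below 2^31.
derive_seed <- function(master, k) {
  as.integer((as.numeric(master) * 48271 + k * 30269) %% 2147483587)
}
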