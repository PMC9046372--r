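# Synthetic-data stage: raytraced label images of LeGrand-model eyes and
# complete simulation runs with ground truth, including the pupil-size-noise
# variant. Labels: 0 background, 1 sclera, 2 iris, 3 pupil.

#' Pixel label codes of rendered eye images
#' @export
pfe_labels <- c(background = 0L, sclera = 1L, iris = 2L, pupil = 3L)

#' LeGrand eye parameters
#'
#' Schematic eye with a spherical eyeball, a protruding spherical corneal
#' cap, and a flat iris/pupil plane whose rim lies on the eyeball sphere.
#' Cornea and aqueous humour form a continuous medium of refractive index
#' `n_ref`. The corneal apex sits `anterior_depth` mm in front of the
#' iris/pupil plane (3.6 mm in the LeGrand schematic eye: anterior chamber
#' plus corneal thickness).
#'
#' @param eyeball_radius,cornea_radius,iris_radius Radii in mm.
#' @param n_ref Refractive index of the cornea + aqueous humour medium; set
#'   `n_ref = 1` to disable refraction.
#' @param anterior_depth Corneal apex to pupil-plane distance in mm.
#' @return An object of class `legrand_eye`.
#' @export
legrand_eye <- function(eyeball_radius = 12.0, cornea_radius = 7.81,
                        iris_radius = 5.57, n_ref = 1.3375,
                        anterior_depth = 3.6) {
  stopifnot(eyeball_radius > 0, cornea_radius > 0, iris_radius > 0, n_ref >= 1,
            anterior_depth > 0)
  if (iris_radius >= eyeball_radius)
    stop("invalid anatomy: iris radius must be smaller than eyeball radius")
  if (anterior_depth >= cornea_radius)
    stop("invalid anatomy: corneal apex depth exceeds the corneal radius")
  # corneal radial extent at the iris plane must cover the iris
  if (anterior_depth * (2 * cornea_radius - anterior_depth) <= iris_radius^2)
    stop("invalid anatomy: corneal cap cannot cover the iris")
  structure(list(eyeball_radius = eyeball_radius,
                 cornea_radius = cornea_radius,
                 iris_radius = iris_radius, n_ref = n_ref,
                 anterior_depth = anterior_depth),
            class = "legrand_eye")
}

#' Eye pose in camera coordinates
#'
#' @param eyeball_center 3-vector, mm.
#' @param gaze_direction Unit 3-vector: optical axis of the eye, pointing out
#'   of the eye (towards the camera side, i.e. typically with negative z).
#' @return An object of class `eye_pose` with derived `gaze_angle_deg`, the
#'   angle between the optical axes of eye and camera.
#' @export
eye_pose <- function(eyeball_center, gaze_direction) {
  g <- unit3(gaze_direction)
  theta <- acos(pmin(1, pmax(-1, sum(g * c(0, 0, -1))))) * 180 / pi
  structure(list(eyeball_center = as.numeric(eyeball_center),
                 gaze_direction = g, gaze_angle_deg = theta),
            class = "eye_pose")
}

#' Gaze direction from polar angle and azimuth
#'
#' @param polar_deg Angle in degrees away from the camera-facing `-z` axis.
#' @param azimuth Azimuth in radians about that axis.
#' @return Unit 3-vector.
#' @export
gaze_from_angles <- function(polar_deg, azimuth) {
  th <- polar_deg * pi / 180
  c(sin(th) * cos(azimuth), sin(th) * sin(azimuth), -cos(th))
}

#' Sample physiological eye parameters
#'
#' Draws eyeball, cornea, and iris radii from normal distributions with the
#' configured means and standard deviations, truncated to anatomically valid
#' combinations (all positive, iris < eyeball, iris < cornea).
#'
#' @param config See [pfe_config()]; uses `$eye_distributions`.
#' @return A [legrand_eye()].
#' @export
sample_eye_parameters <- function(config = pfe_config()) {
  d <- config$eye_distributions
  ad <- if (is.null(d$anterior_depth)) 3.6 else d$anterior_depth
  repeat {
    eb <- stats::rnorm(1, d$eyeball_mean, d$eyeball_sd)
    co <- stats::rnorm(1, d$cornea_mean, d$cornea_sd)
    ir <- stats::rnorm(1, d$iris_mean, d$iris_sd)
    if (eb > 0 && co > ad && ir > 0 && ir < eb &&
        ad * (2 * co - ad) > ir^2) break
  }
  legrand_eye(eb, co, ir, d$n_ref, anterior_depth = ad)
}

#' Build the 3D scene for one eye state
#'
#' Places the iris/pupil plane so that the iris rim lies on the eyeball
#' sphere, and the corneal sphere so that its apex sits `anterior_depth` mm
#' in front of that plane (the cap protrudes from the eyeball and covers the
#' iris).
#'
#' @param eye A [legrand_eye()].
#' @param pose An [eye_pose()].
#' @param pupil_radius Pupil radius in mm (< iris radius).
#' @return A scene list with eyeball/cornea spheres and iris/pupil circles.
#' @export
build_eye_geometry <- function(eye, pose, pupil_radius) {
  if (pupil_radius >= eye$iris_radius)
    stop("invalid anatomy: pupil radius must be smaller than iris radius")
  g <- pose$gaze_direction
  d_iris <- sqrt(eye$eyeball_radius^2 - eye$iris_radius^2)
  iris_center <- pose$eyeball_center + d_iris * g
  d_cornea <- d_iris + eye$anterior_depth - eye$cornea_radius
  cornea_center <- pose$eyeball_center + d_cornea * g
  list(eye = eye, pose = pose,
       eyeball = sphere3d(pose$eyeball_center, eye$eyeball_radius),
       cornea = sphere3d(cornea_center, eye$cornea_radius),
       iris = circle3d(iris_center, g, eye$iris_radius),
       pupil = circle3d(iris_center, g, pupil_radius),
       d_iris = d_iris)
}

#' Build a model-consistent (tangent-pupil) scene
#'
#' Cornea-free scene in which the pupil circle is tangent to the eye sphere
#' exactly as the refraction-unaware 3D eye-model fit assumes: pupil and iris
#' lie in the tangent plane at the point where the optical axis exits the
#' sphere. Used as the forward model for end-to-end oracle tests of the
#' fitting pipeline, where measured quantities must reproduce ground truth up
#' to discretisation.
#'
#' @param pose An [eye_pose()].
#' @param pupil_radius Pupil radius in mm.
#' @param sphere_radius Eye-sphere radius in mm.
#' @param iris_radius Iris disk radius in mm (label cosmetics only).
#' @return A scene list renderable by [render_eye_image()].
#' @export
build_tangent_eye_geometry <- function(pose, pupil_radius, sphere_radius = 12,
                                       iris_radius = 5.57) {
  if (pupil_radius >= iris_radius)
    stop("invalid anatomy: pupil radius must be smaller than iris radius")
  g <- pose$gaze_direction
  center <- pose$eyeball_center + sphere_radius * g
  list(eye = NULL, pose = pose,
       eyeball = sphere3d(pose$eyeball_center, sphere_radius),
       cornea = NULL,
       iris = circle3d(center, g, iris_radius),
       pupil = circle3d(center, g, pupil_radius),
       d_iris = sphere_radius)
}

# Cached pixel-ray direction grid per (camera, resolution); directions are
# unit vectors through pixel centres, one row per pixel in column-major image
# order (y fastest).
pixel_directions <- function(camera) {
  w <- camera$image_size[1]; h <- camera$image_size[2]
  u <- (seq_len(w) - 0.5) - camera$principal_point[1]
  v <- (seq_len(h) - 0.5) - camera$principal_point[2]
  X <- rep(u, each = h)
  Y <- rep(v, times = w)
  d <- cbind(X, Y, camera$focal_length)
  d / sqrt(rowSums(d^2))
}

#' Raytrace a labeled eye image
#'
#' Casts one ray per pixel from the pinhole and labels it by four cases:
#' misses the eye (background), hits the eyeball (sclera), or hits the corneal
#' cap, in which case it is refracted once (air to `n_ref`) and followed to
#' the iris plane, yielding iris or pupil. Refracted rays that miss both are
#' labeled sclera.
#'
#' @param scene From [build_eye_geometry()].
#' @param camera A [pinhole_camera()]; its `image_size` is the resolution.
#' @return Integer label matrix of dimension `c(height, width)` with class
#'   `label_image` (see [pfe_labels]).
#' @export
render_eye_image <- function(scene, camera) {
  w <- camera$image_size[1]; h <- camera$image_size[2]
  if (w < 32 || h < 32) stop("resolution must be at least 32 x 32")
  dirs <- pixel_directions(camera)
  n <- nrow(dirs)
  g <- scene$pose$gaze_direction
  E0 <- scene$eyeball$center
  lab <- rep(pfe_labels[["background"]], n)

  te <- ray_sphere_t0(dirs, E0, scene$eyeball$radius)
  lab[!is.na(te)] <- pfe_labels[["sclera"]]

  if (is.null(scene$cornea)) {
    # cornea-free scene: rays meet the iris/pupil plane directly
    ic <- scene$iris$center
    denom <- drop(dirs %*% g)
    tp <- sum(ic * g) / denom
    q <- dirs * tp
    s2 <- rowSums((q - matrix(ic, n, 3, byrow = TRUE))^2)
    hit_p <- !is.na(tp) & tp > 0 & s2 <= scene$iris$radius^2 &
      (is.na(te) | tp <= te + 1e-9)
    lab[hit_p] <- ifelse(s2[hit_p] <= scene$pupil$radius^2,
                         pfe_labels[["pupil"]], pfe_labels[["iris"]])
    return(structure(matrix(lab, nrow = h, ncol = w), class = "label_image"))
  }

  tc <- ray_sphere_t0(dirs, scene$cornea$center, scene$cornea$radius)
  hit_c <- !is.na(tc)
  if (any(hit_c)) {
    pc <- dirs[hit_c, , drop = FALSE] * tc[hit_c]
    # corneal cap: in front of the iris plane
    on_cap <- drop((pc - matrix(E0, sum(hit_c), 3, byrow = TRUE)) %*% g) >=
      scene$d_iris - 1e-9
    nearer <- is.na(te[hit_c]) | tc[hit_c] <= te[hit_c] + 1e-9
    use <- on_cap & nearer
    if (any(use)) {
      idx <- which(hit_c)[use]
      p0 <- pc[use, , drop = FALSE]
      nrm <- (p0 - matrix(scene$cornea$center, length(idx), 3, byrow = TRUE)) /
        scene$cornea$radius
      d2 <- refract_many(dirs[idx, , drop = FALSE], nrm, 1, scene$eye$n_ref)
      ic <- scene$iris$center
      denom <- drop(d2 %*% g)
      tnum <- drop((matrix(ic, length(idx), 3, byrow = TRUE) - p0) %*% g)
      t2 <- tnum / denom
      lab[idx] <- pfe_labels[["sclera"]]
      fwd <- !is.na(t2) & t2 > 0
      if (any(fwd)) {
        q <- p0[fwd, , drop = FALSE] + d2[fwd, , drop = FALSE] * t2[fwd]
        dq <- q - matrix(ic, sum(fwd), 3, byrow = TRUE)
        s2 <- rowSums(dq^2)
        li <- rep(pfe_labels[["sclera"]], sum(fwd))
        li[s2 <= scene$iris$radius^2] <- pfe_labels[["iris"]]
        li[s2 <= scene$pupil$radius^2] <- pfe_labels[["pupil"]]
        lab[idx[fwd]] <- li
      }
    }
  }
  structure(matrix(lab, nrow = h, ncol = w), class = "label_image")
}

#' Is the 2D pupil fully visible?
#'
#' `FALSE` if any pupil-labeled pixel touches the image border, or if there are
#' no pupil pixels at all (degenerate frames count as unusable).
#'
#' @param image A `label_image`.
#' @return Logical scalar.
#' @export
pupil_fully_visible <- function(image) {
  pp <- unclass(image) == pfe_labels[["pupil"]]
  if (!any(pp)) return(FALSE)
  !(any(pp[1, ]) || any(pp[nrow(pp), ]) || any(pp[, 1]) || any(pp[, ncol(pp)]))
}

#' Write a label image as an 8-bit PNG
#'
#' Uses the fixed label-to-gray map background 0, sclera 85, iris 170,
#' pupil 255.
#'
#' @param image A `label_image`.
#' @param path Output file path.
#' @export
write_label_png <- function(image, path) {
  png::writePNG(unclass(image) / 3, path)
  invisible(path)
}

#' Simulate one synthetic eye recording
#'
#' Draws one eye (Table-of-distributions parameters), one eyeball position,
#' and one base pupil radius; renders `n_frames` gaze samples; runs the 2D
#' pupil detector on each frame. Frames with a partially visible (or absent)
#' 2D pupil, or where detection fails, are discarded and counted. With
#' `noise = TRUE`, the per-frame true radius is the base radius times a factor
#' drawn from Normal(1, sigma_run), where sigma_run is drawn once per run from
#' the configured fluctuation distribution. The pose stream and the noise
#' stream are seeded separately so matched-seed noiseless/noisy runs share
#' identical poses.
#'
#' @param config See [pfe_config()].
#' @param seed Integer seed for this run.
#' @param noise Logical: enable per-frame multiplicative pupil-size noise.
#' @param eye Optionally a fixed [legrand_eye()] (e.g. the mean-parameter eye
#'   used for correction training) instead of a random draw.
#' @return A `simulation_run` list with `frames` (data frame of ground truth
#'   and detections), `eye`, `camera`, `base_radius`, `sigma_run`, `seed`, and
#'   discard counters.
#' @export
simulate_run <- function(config = pfe_config(), seed = 1, noise = FALSE,
                         eye = NULL) {
  if (config$n_frames < 1) stop("configuration error: n_frames must be >= 1")
  rngkeep <- sane_seed(seed)
  set.seed(rngkeep)
  camera <- config$camera
  if (is.null(eye)) eye <- sample_eye_parameters(config)
  base_radius <- stats::runif(1, config$pupil_radius_range[1],
                              config$pupil_radius_range[2])
  pos <- c(stats::runif(1, config$position_box$x[1], config$position_box$x[2]),
           stats::runif(1, config$position_box$y[1], config$position_box$y[2]),
           stats::runif(1, config$position_box$z[1], config$position_box$z[2]))
  nfr <- config$n_frames
  polar <- stats::runif(nfr, config$gaze_polar_range[1], config$gaze_polar_range[2])
  azim <- stats::runif(nfr, 0, 2 * pi)
  radius_draw <- if (config$vary_radius_per_frame)
    stats::runif(nfr, config$pupil_radius_range[1], config$pupil_radius_range[2])
  else rep(base_radius, nfr)

  sigma_run <- 0
  factors <- rep(1, nfr)
  if (noise) {
    set.seed(sane_seed(rngkeep + 500000003))
    sigma_run <- sample_sigma_run(config)
    factors <- pmax(0.05, stats::rnorm(nfr, 1, sigma_run))
  }
  radii <- radius_draw * factors

  rows <- vector("list", nfr)
  n_partial <- 0L; n_detect_fail <- 0L
  for (k in seq_len(nfr)) {
    pose <- eye_pose(pos, gaze_from_angles(polar[k], azim[k]))
    if (radii[k] >= eye$iris_radius) radii[k] <- 0.98 * eye$iris_radius
    scene <- build_eye_geometry(eye, pose, radii[k])
    img <- render_eye_image(scene, camera)
    if (!pupil_fully_visible(img)) { n_partial <- n_partial + 1L; next }
    det <- detect_pupil(img, min_pixels = config$min_pupil_pixels)
    if (!det$ok) { n_detect_fail <- n_detect_fail + 1L; next }
    el <- correct_principal_point(det$ellipse, camera)
    rows[[k]] <- data.frame(
      frame = k, gaze_angle_deg = pose$gaze_angle_deg,
      gaze_x = pose$gaze_direction[1], gaze_y = pose$gaze_direction[2],
      gaze_z = pose$gaze_direction[3],
      true_radius_mm = radii[k],
      cx = el$center[1], cy = el$center[2],
      major_px = el$major_axis, minor_px = el$minor_axis,
      angle_rad = el$angle, circularity = det$circularity,
      confidence = det$confidence, n_pupil_px = det$n_pixels)
  }
  frames <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  structure(list(frames = frames, eye = eye, camera = camera,
                 eyeball_center = pos, base_radius = base_radius,
                 sigma_run = sigma_run, noise = noise, seed = seed,
                 n_attempted = nfr, n_partial = n_partial,
                 n_detect_fail = n_detect_fail),
            class = "simulation_run")
}

# Per-run pupil-fluctuation scale: truncated normal on [lo, hi] with the
# configured mean (default mean 0.05, range [0, 0.10]).
sample_sigma_run <- function(config) {
  d <- config$noise_sigma
  repeat {
    s <- stats::rnorm(1, d$mean, d$sd)
    if (s >= d$lo && s <= d$hi) return(s)
  }
}

# Keep derived seeds valid 32-bit integers.
sane_seed <- function(seed) as.integer(abs(seed) %% .Machine$integer.max)
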