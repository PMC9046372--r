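# Shared fixtures built in code: cameras, random circles, and small rendered
# sweeps used across test files.

test_camera <- function(res = 200) pfe_config(resolution = res)$camera

random_front_circle <- function(camera, rng_z = c(20, 50)) {
  cen <- c(stats::runif(1, -8, 8), stats::runif(1, -8, 8),
           stats::runif(1, rng_z[1], rng_z[2]))
  n <- c(stats::rnorm(3))
  n <- n / sqrt(sum(n^2))
  r <- stats::runif(1, 0.5, 4)
  if (cen[3] - r * sqrt(1 - n[3]^2) <= 2) return(NULL)
  circle3d(cen, n, r)
}

# Exact-projection detections of tangent-model pupils: the forward model of
# the refraction-unaware fit (no rendering, no noise).
tangent_forward_detections <- function(camera, center, n_frames = 50,
                                       sphere_radius = 12, radius_range = c(1, 4),
                                       polar_range = c(0, 50)) {
  rows <- vector("list", n_frames)
  truth <- vector("list", n_frames)
  for (k in seq_len(n_frames)) {
    th <- stats::runif(1, polar_range[1], polar_range[2]) * pi / 180
    az <- stats::runif(1, 0, 2 * pi)
    g <- c(sin(th) * cos(az), sin(th) * sin(az), -cos(th))
    r <- stats::runif(1, radius_range[1], radius_range[2])
    el <- project_circle(circle3d(center + sphere_radius * g, g, r), camera)
    rows[[k]] <- data.frame(frame = k, cx = el$center[1], cy = el$center[2],
                            major_px = el$major_axis, minor_px = el$minor_axis,
                            angle_rad = el$angle, confidence = 1)
    truth[[k]] <- list(gaze = g, radius = r)
  }
  list(detections = do.call(rbind, rows), truth = truth)
}

# Points on an exact ellipse (full axes, radians).
ellipse_points <- function(center, major, minor, angle, n = 100) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  ca <- cos(angle); sa <- sin(angle)
  cbind(center[1] + major / 2 * cos(th) * ca - minor / 2 * sin(th) * sa,
        center[2] + major / 2 * cos(th) * sa + minor / 2 * sin(th) * ca)
}
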