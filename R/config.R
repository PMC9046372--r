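# Experiment configuration: camera, sampling ranges, scale parameters.

#' Default simulation configuration
#'
#' Study conditions for the synthetic recordings. Defaults: camera with a 60
#' degree field of view (f = sqrt(3)/2 x resolution, about 346 px at
#' 400 x 400), typical of near-eye cameras and wide enough that oblique-gaze
#' pupils stay in frame (partial visibility remains a rare event, and the
#' observed circularity range extends below 0.4); eyeball positions in a
#' near-eye box x, y in [-8, 8] mm, z in [25, 45] mm; per-frame gaze with
#' polar angle uniform in [0, 50] degrees off the camera axis, azimuth
#' uniform; constant per-run pupil radius uniform in [0.5, 4.5] mm; per-run
#' pupil-fluctuation scale from a truncated normal with mean 0.05 on
#' [0, 0.10].
#'
#' @param resolution Image size in px (square).
#' @param n_frames Attempted frames (gaze samples) per run.
#' @param ... Overrides for any listed component.
#' @return Configuration list.
#' @export
pfe_config <- function(resolution = 200, n_frames = 100, ...) {
  f <- sqrt(3) / 2 * resolution        # 60 degree field of view
  cfg <- list(
    camera = pinhole_camera(f, c(resolution, resolution)),
    n_frames = n_frames,
    position_box = list(x = c(-8, 8), y = c(-8, 8), z = c(25, 45)),
    gaze_polar_range = c(0, 50),
    pupil_radius_range = c(0.5, 4.5),
    vary_radius_per_frame = FALSE,
    min_pupil_pixels = 20,
    eye_distributions = list(eyeball_mean = 12.0, eyeball_sd = 1.0,
                             cornea_mean = 7.81, cornea_sd = 0.24,
                             iris_mean = 5.57, iris_sd = 0.28,
                             n_ref = 1.3375),
    noise_sigma = list(mean = 0.05, sd = 0.025, lo = 0, hi = 0.10),
    sphere_radius = 12,
    confidence_threshold = 0.6,
    outlier_tolerance = 0.2,
    high_confidence_fraction = 1.0)
  ov <- list(...)
  for (nm in names(ov)) {
    if (!nm %in% names(cfg)) stop("unknown configuration field: ", nm)
    cfg[[nm]] <- ov[[nm]]
  }
  for (rg in c("gaze_polar_range", "pupil_radius_range"))
    if (diff(cfg[[rg]]) < 0) stop("configuration error: empty range ", rg)
  cfg
}

#' Read/write a configuration as YAML
#'
#' Camera objects are flattened to plain lists for serialisation.
#' @param config Configuration list.
#' @param path File path.
#' @export
write_config_yaml <- function(config, path) {
  config$camera <- unclass(config$camera)
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_config_yaml
#' @export
read_config_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$camera <- pinhole_camera(cfg$camera$focal_length,
                               unlist(cfg$camera$image_size),
                               unlist(cfg$camera$principal_point))
  cfg
}
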