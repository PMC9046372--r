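# The refraction-unaware 3D eye-model fit (3D-1p): eye-sphere position from a
# sweep of pupil ellipses via least-squares intersection of projected gaze
# lines plus a 1D depth search, then per-frame pupil radius and gaze by conic
# unprojection and tangency scaling. Works entirely in the camera frame; the
# eye sphere radius (default 12 mm) is the method's sole physiological
# parameter.

#' Select the highest-confidence detections
#'
#' @param detections Data frame with columns `frame` and `confidence`.
#' @param fraction Fraction in (0, 1] to keep; `ceiling(fraction * n)` rows.
#'   Ties are broken in favour of earlier frames.
#' @return The selected subset, in frame order.
#' @export
select_high_confidence <- function(detections, fraction = 0.1) {
  if (nrow(detections) == 0) stop("no detections to select from")
  stopifnot(fraction > 0, fraction <= 1)
  k <- ceiling(fraction * nrow(detections))
  ord <- order(-detections$confidence, detections$frame)
  sel <- sort(ord[seq_len(k)])
  detections[sel, , drop = FALSE]
}

# Unproject one detection row (relative-to-principal-point centred ellipse in
# absolute px) into its two r = 1 mm circle candidates.
detection_candidates <- function(row, camera) {
  el <- ellipse2d(c(row$cx, row$cy), row$major_px, row$minor_px, row$angle_rad)
  unproject_ellipse(el, camera, r_fixed = 1)
}

# Project a 3D point to (x, y) px.
project_point <- function(p, camera) {
  camera$focal_length * p[1:2] / p[3] + camera$principal_point
}

# 2D line through the projections of the candidate circle centre and of a
# point shifted along the (camera-facing) normal: the image of the 3D line on
# which the eye-sphere centre must lie. Returns list(p = point, d = unit dir).
candidate_gaze_line <- function(cand, camera) {
  p1 <- project_point(cand$center, camera)
  q <- cand$center - 0.5 * cand$normal      # into the eye
  if (q[3] <= 1e-6) q <- cand$center + 0.5 * cand$normal
  p2 <- project_point(q, camera)
  d <- p2 - p1
  nd <- sqrt(sum(d^2))
  if (nd < 1e-12) return(NULL)              # frontal view: direction undefined
  list(p = p1, d = d / nd)
}

# Least-squares intersection point of lines (any dimension): minimises the
# sum of squared point-line distances. lines: list of list(p = point,
# d = unit direction).
intersect_lines <- function(lines) {
  k <- length(lines[[1]]$p)
  A <- matrix(0, k, k); b <- numeric(k)
  for (ln in lines) {
    P <- diag(k) - outer(ln$d, ln$d)
    A <- A + P
    b <- b + P %*% ln$p
  }
  if (abs(det(A)) < 1e-10)
    stop("degenerate sweep: gaze lines are parallel (single gaze direction)")
  drop(solve(A, b))
}

#' Estimate the eye-sphere position from a sweep of pupil ellipses
#'
#' Least-squares intersection of lines, in two stages. Stage 1 (candidate
#' disambiguation): both unprojection candidates of a detection project to
#' the same image line through the projected pupil centre, so the projected
#' eye centre is first located as the least-squares 2D intersection of one
#' such line per detection; the kept candidate is then the one whose
#' projected outward normal points away from that centre. Stage 2 (3D):
#' the tangent eye model requires E = s_i c_i - R m_i with unknown per-frame
#' scales s_i (c_i, m_i: centre and camera-facing normal of the kept
#' unit-radius circle, R: the model sphere radius). Each frame therefore
#' constrains E to the 3D line through -R m_i with direction c_i, and E is
#' their closed-form least-squares intersection -- exact for noise-free
#' tangent-model observations of any per-frame pupil radii.
#'
#' @param detections Data frame with columns `frame`, `cx`, `cy`, `major_px`,
#'   `minor_px`, `angle_rad`, `confidence`.
#' @param camera A [pinhole_camera()].
#' @param sphere_radius Model eye-sphere radius in mm.
#' @return List with `center` (mm), `sphere_radius`, `n_observations_used`,
#'   `residual` (RMS point-line distance of the unit-scene intersection, mm),
#'   and `projected_center` (px).
#' @export
estimate_sphere <- function(detections, camera, sphere_radius = 12) {
  if (nrow(detections) < 2)
    stop("degenerate sweep: need at least 2 detections under varying gaze")
  cands <- lapply(seq_len(nrow(detections)), function(i)
    detection_candidates(detections[i, ], camera))
  lines2 <- list()
  for (i in seq_along(cands)) {
    ln <- candidate_gaze_line(cands[[i]][[1]], camera)
    if (!is.null(ln)) lines2[[length(lines2) + 1]] <- ln
  }
  if (length(lines2) < 2)
    stop("degenerate sweep: gaze lines are parallel (single gaze direction)")
  c0 <- intersect_lines(lines2)
  # keep, per detection, the candidate whose projected outward normal points
  # away from the projected eye centre
  keep <- list()
  for (i in seq_along(cands)) {
    best <- NULL; bestdot <- -Inf
    for (j in 1:2) {
      cc <- cands[[i]][[j]]
      p1 <- project_point(cc$center, camera)
      q <- cc$center + 0.5 * cc$normal        # outward (camera-facing) normal
      if (q[3] <= 1e-6) next
      d2 <- project_point(q, camera) - p1
      dt <- sum(d2 * (p1 - c0))
      if (dt > bestdot) { bestdot <- dt; best <- cc }
    }
    if (!is.null(best)) keep[[length(keep) + 1]] <- best
  }
  lines3 <- lapply(keep, function(cc)
    list(p = -sphere_radius * cc$normal, d = unit3(cc$center)))
  E <- intersect_lines(lines3)
  resid <- sqrt(mean(vapply(lines3, function(ln) {
    v <- E - ln$p
    max(0, sum(v^2) - sum(v * ln$d)^2)
  }, 0)))
  pc <- camera$focal_length * E[1:2] / E[3] + camera$principal_point
  list(center = E, sphere_radius = sphere_radius,
       n_observations_used = nrow(detections),
       residual = resid, projected_center = pc)
}

#' Per-frame pupil circle, radius, and gaze from the fitted sphere
#'
#' Unprojects the pupil ellipse at r = 1 mm, picks the candidate most
#' consistent with tangency to the estimated sphere, and scales it along the
#' unprojection cone to tangency (closed form, linear in the scale). The
#' scaling factor is the pupil radius in mm; the gaze vector is the direction
#' from the sphere centre through the scaled circle centre.
#'
#' @param detection One-row data frame (see [estimate_sphere()]).
#' @param sphere Output of [estimate_sphere()].
#' @param camera A [pinhole_camera()].
#' @return List with `circle` ([circle3d()]), `radius_mm`, `gaze_vector`,
#'   `residual` (mm), or `NULL` when no positive scaling achieves tangency.
#' @export
estimate_pupil_circle <- function(detection, sphere, camera) {
  cands <- tryCatch(detection_candidates(detection, camera),
                    error = function(e) NULL)
  if (is.null(cands)) return(NULL)
  E <- sphere$center; R <- sphere$sphere_radius
  best <- NULL
  for (cd in cands) {
    cc <- cd$center; nn <- cd$normal
    # camera-facing candidate normal is the outward gaze of the tangent model
    s <- sum(cc * (E + R * nn)) / sum(cc^2)
    if (s <= 0) next
    res <- sqrt(sum((s * cc - R * nn - E)^2))
    if (is.null(best) || res < best$residual)
      best <- list(circle = circle3d(s * cc, nn, s), radius_mm = s,
                   gaze_vector = unit3(s * cc - E), residual = res)
  }
  best
}

#' Apply the 3D-1p method to every frame of a run
#'
#' @param frames Detection data frame (as in `simulation_run$frames`).
#' @param sphere Output of [estimate_sphere()].
#' @param camera A [pinhole_camera()].
#' @return `frames` with columns `radius_uncorrected_mm`, `est_gaze_x/y/z`,
#'   `tangency_residual` appended (NA on per-frame failure).
#' @export
measure_run_3d1p <- function(frames, sphere, camera) {
  n <- nrow(frames)
  out <- data.frame(radius_uncorrected_mm = rep(NA_real_, n),
                    est_gaze_x = NA_real_, est_gaze_y = NA_real_,
                    est_gaze_z = NA_real_, tangency_residual = NA_real_)
  for (i in seq_len(n)) {
    m <- estimate_pupil_circle(frames[i, ], sphere, camera)
    if (is.null(m)) next
    out$radius_uncorrected_mm[i] <- m$radius_mm
    out$est_gaze_x[i] <- m$gaze_vector[1]
    out$est_gaze_y[i] <- m$gaze_vector[2]
    out$est_gaze_z[i] <- m$gaze_vector[3]
    out$tangency_residual[i] <- m$residual
  }
  cbind(frames, out)
}
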