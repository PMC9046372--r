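# 2D pupil extraction: sub-pixel boundary of the pupil-labeled region,
# direct least-squares ellipse fitting, circularity, principal-point
# correction.

#' Extract the sub-pixel pupil boundary from a label image
#'
#' Contours the pupil indicator at iso-level 0.5 (marching squares with linear
#' interpolation). If several closed contours exist (disjoint blobs), the one
#' enclosing the largest area is used and a warning is raised.
#'
#' @param image A `label_image` (or a binary matrix where TRUE/1 marks pupil).
#' @param min_pixels Minimum number of pupil-labeled pixels to attempt
#'   extraction.
#' @return A two-column matrix of ordered boundary points (x, y) in px, or
#'   `NULL` when detection fails (too few pixels).
#' @export
extract_pupil_boundary <- function(image, min_pixels = 20) {
  m <- unclass(image)
  ind <- if (is.logical(m)) m else m == pfe_labels[["pupil"]]
  if (sum(ind) < min_pixels) return(NULL)
  h <- nrow(ind); w <- ncol(ind)
  # pad so that contours at the image border still close
  z <- matrix(0, h + 2, w + 2)
  z[2:(h + 1), 2:(w + 1)] <- ind
  # contourLines x runs over rows of z; rows of the image are y
  cl <- grDevices::contourLines(x = (0:(h + 1)) - 0.5, y = (0:(w + 1)) - 0.5,
                                z = z, levels = 0.5)
  if (length(cl) == 0) return(NULL)
  if (length(cl) > 1) {
    warning("multiple pupil components; using the largest")
    areas <- vapply(cl, function(cc) {
      x <- cc$x; y <- cc$y
      abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
    }, 0)
    cl <- cl[which.max(areas)]
  }
  cbind(x = cl[[1]]$y, y = cl[[1]]$x)   # swap back to image (x, y)
}

#' Direct least-squares ellipse fit
#'
#' Fits the conic constrained to an ellipse (Fitzgibbon's direct method in the
#' numerically stable Halir-Flusser formulation), with data centred for
#' conditioning.
#'
#' @param points Two-column matrix of (x, y) points; at least 5, not
#'   collinear.
#' @return An [ellipse2d()] with attribute `rms` (residual RMS of the
#'   normalised algebraic distance).
#' @export
fit_ellipse <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 5) stop("ellipse fit requires at least 5 points")
  mu <- colMeans(points)
  x <- points[, 1] - mu[1]; y <- points[, 2] - mu[2]
  D1 <- cbind(x^2, x * y, y^2)
  D2 <- cbind(x, y, 1)
  S1 <- crossprod(D1); S2 <- crossprod(D1, D2); S3 <- crossprod(D2)
  T1 <- tryCatch(-solve(S3, t(S2)), error = function(e)
    stop("ellipse fit failed: collinear or degenerate points"))
  M <- S1 + S2 %*% T1
  C1inv <- matrix(c(0, 0, 0.5, 0, -1, 0, 0.5, 0, 0), 3, 3)
  ev <- eigen(C1inv %*% M)
  evec <- Re(ev$vectors)
  cond <- 4 * evec[1, ] * evec[3, ] - evec[2, ]^2
  ok <- which(cond > 0)
  if (length(ok) == 0) stop("ellipse fit failed: no elliptical solution")
  a1 <- evec[, ok[1]]
  a2 <- T1 %*% a1
  co <- c(a = a1[1], b = a1[2], c = a1[3], d = a2[1], e = a2[2], g = a2[3])
  el <- conic_to_ellipse(co, shift = mu)
  alg <- cbind(D1, D2) %*% c(a1, a2)
  attr(el, "rms") <- sqrt(mean(alg^2)) / sqrt(sum(a1^2))
  el
}

#' Circularity of an ellipse
#'
#' Ratio of minor to major axis, in `[0, 1]`; 1 for a circular pupil image,
#' decreasing with the angle between the eye's optical axis and the viewing
#' direction.
#'
#' @param ellipse An [ellipse2d()].
#' @return Numeric scalar in `[0, 1]`.
#' @export
circularity <- function(ellipse) {
  if (ellipse$major_axis <= 0) stop("zero major axis")
  ellipse$minor_axis / ellipse$major_axis
}

#' Re-express an ellipse relative to the calibrated principal point
#'
#' Translates the ellipse centre by the offset of the principal point from the
#' image centre; axes and angle are unchanged.
#'
#' @param ellipse An [ellipse2d()].
#' @param camera A [pinhole_camera()].
#' @return An [ellipse2d()].
#' @export
correct_principal_point <- function(ellipse, camera) {
  off <- camera$principal_point - camera$image_size / 2
  ellipse2d(ellipse$center - off, ellipse$major_axis, ellipse$minor_axis,
            ellipse$angle)
}

#' Detect the pupil ellipse in a label image
#'
#' Boundary extraction plus direct ellipse fit. Synthetic detections carry
#' confidence 1.0 (segmentation from pixel labels is always equally
#' confident).
#'
#' @param image A `label_image`.
#' @param min_pixels Minimum pupil pixel count to attempt a fit.
#' @return List with `ok`; when `ok`, also `ellipse`, `circularity`,
#'   `confidence`, `n_pixels`.
#' @export
detect_pupil <- function(image, min_pixels = 20) {
  npx <- sum(unclass(image) == pfe_labels[["pupil"]])
  pts <- extract_pupil_boundary(image, min_pixels)
  if (is.null(pts)) return(list(ok = FALSE, reason = "too few pupil pixels"))
  el <- tryCatch(fit_ellipse(pts), error = function(e) NULL)
  if (is.null(el)) return(list(ok = FALSE, reason = "ellipse fit failed"))
  list(ok = TRUE, ellipse = el, circularity = circularity(el),
       confidence = 1.0, n_pixels = npx)
}
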