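# Core 3D geometry and optics: pinhole camera, exact circle projection and
# conic unprojection, vector Snell refraction, and ray-sphere intersections.
# All 3D quantities are in mm in the camera frame (right-handed, +z into the
# scene, origin at the pinhole); image quantities are in px with the origin at
# the top-left corner, x right, y down.

#' Pinhole camera model
#'
#' @param focal_length Focal length in px (> 0).
#' @param image_size Image size `c(width, height)` in px.
#' @param principal_point Principal point `c(x, y)` in px; defaults to the
#'   image centre.
#' @return An object of class `pinhole_camera`.
#' @export
pinhole_camera <- function(focal_length, image_size = c(400, 400),
                           principal_point = image_size / 2) {
  stopifnot(focal_length > 0, length(image_size) == 2, all(image_size > 0),
            length(principal_point) == 2)
  if (any(principal_point < 0) || any(principal_point > image_size))
    stop("principal point must lie inside the image bounds")
  structure(list(focal_length = focal_length,
                 image_size = as.numeric(image_size),
                 principal_point = as.numeric(principal_point)),
            class = "pinhole_camera")
}

#' 3D circle
#'
#' @param center 3-vector, mm.
#' @param normal 3-vector; normalised internally.
#' @param radius Radius in mm (>= 0).
#' @return An object of class `circle3d`.
#' @export
circle3d <- function(center, normal, radius) {
  stopifnot(length(center) == 3, length(normal) == 3, radius >= 0)
  n <- sqrt(sum(normal^2))
  if (n == 0) stop("circle normal must be non-zero")
  structure(list(center = as.numeric(center), normal = as.numeric(normal) / n,
                 radius = as.numeric(radius)), class = "circle3d")
}

#' Sphere
#' @param center 3-vector, mm.
#' @param radius Radius in mm (> 0).
#' @return An object of class `sphere3d`.
#' @export
sphere3d <- function(center, radius) {
  stopifnot(length(center) == 3, radius > 0)
  structure(list(center = as.numeric(center), radius = as.numeric(radius)),
            class = "sphere3d")
}

#' 2D ellipse (full axis lengths)
#'
#' @param center `c(x, y)` in px.
#' @param major_axis Full major-axis length in px.
#' @param minor_axis Full minor-axis length in px (`<= major_axis`).
#' @param angle Major-axis angle in radians, normalised to (-pi/2, pi/2].
#' @return An object of class `ellipse2d`.
#' @export
ellipse2d <- function(center, major_axis, minor_axis, angle = 0) {
  stopifnot(length(center) == 2, minor_axis >= 0, major_axis >= minor_axis)
  structure(list(center = as.numeric(center),
                 major_axis = as.numeric(major_axis),
                 minor_axis = as.numeric(minor_axis),
                 angle = wrap_half_pi(angle)), class = "ellipse2d")
}

#' Ray with unit direction
#' @param origin 3-vector, mm.
#' @param direction 3-vector; normalised internally.
#' @return An object of class `ray3d`.
#' @export
ray3d <- function(origin, direction) {
  stopifnot(length(origin) == 3, length(direction) == 3)
  n <- sqrt(sum(direction^2))
  if (n == 0) stop("ray direction must be non-zero")
  structure(list(origin = as.numeric(origin),
                 direction = as.numeric(direction) / n), class = "ray3d")
}

unit3 <- function(v) v / sqrt(sum(v^2))

wrap_half_pi <- function(a) {
  a <- (a + pi / 2) %% pi - pi / 2
  if (a <= -pi / 2 + 1e-15) a <- a + pi
  a
}

# --- conic helpers -----------------------------------------------------------

# Geometric ellipse -> implicit conic a x^2 + b xy + c y^2 + d x + e y + g = 0,
# coordinates relative to the given origin shift.
ellipse_to_conic <- function(ellipse, shift = c(0, 0)) {
  sa <- ellipse$major_axis / 2
  sb <- ellipse$minor_axis / 2
  if (sb <= 0) stop("degenerate ellipse (zero minor axis)")
  ca <- cos(ellipse$angle); saa <- sin(ellipse$angle)
  R <- matrix(c(ca, saa, -saa, ca), 2, 2)
  A <- R %*% diag(c(1 / sa^2, 1 / sb^2)) %*% t(R)
  cen <- ellipse$center - shift
  L <- -2 * A %*% cen
  g <- drop(t(cen) %*% A %*% cen) - 1
  c(a = A[1, 1], b = 2 * A[1, 2], c = A[2, 2], d = L[1], e = L[2], g = g)
}

# Implicit conic -> geometric ellipse; error unless the conic is a real ellipse.
conic_to_ellipse <- function(co, shift = c(0, 0)) {
  A <- matrix(c(co["a"], co["b"] / 2, co["b"] / 2, co["c"]), 2, 2)
  if (det(A) <= 0) stop("conic is not an ellipse")
  cen <- drop(solve(A, -c(co["d"], co["e"]) / 2))
  f0 <- drop(co["g"] + (co["d"] * cen[1] + co["e"] * cen[2]) / 2)
  ev <- eigen(A, symmetric = TRUE)
  if (ev$values[1] < 0) {
    # normalise sign so that the quadratic part is positive definite and f0 < 0
    ev$values <- rev(-ev$values)
    ev$vectors <- ev$vectors[, 2:1]
    f0 <- -f0
  }
  if (any(ev$values <= 0) || f0 >= 0) stop("conic is not a real ellipse")
  semi <- sqrt(-f0 / ev$values)             # values sorted decreasing -> semi increasing
  major_vec <- ev$vectors[, which.max(semi)]
  ellipse2d(center = cen + shift,
            major_axis = 2 * max(semi), minor_axis = 2 * min(semi),
            angle = atan2(major_vec[2], major_vec[1]))
}

# --- projection --------------------------------------------------------------

#' Project a 3D circle through a pinhole camera
#'
#' Computes the exact conic image of a circle under the pinhole map and returns
#' it in geometric ellipse parameters. Serves as the refraction-free oracle for
#' the raytracer.
#'
#' @param circle A [circle3d()].
#' @param camera A [pinhole_camera()].
#' @return An [ellipse2d()].
#' @export
project_circle <- function(circle, camera) {
  cen <- circle$center; n <- circle$normal; r <- circle$radius
  f <- camera$focal_length
  # circle must be entirely in front of the camera
  zmin <- cen[3] - r * sqrt(max(0, 1 - n[3]^2))
  if (zmin <= 0) stop("degenerate projection: circle reaches the z = 0 plane")
  d <- sum(n * cen)
  if (abs(d) < 1e-9 * sqrt(sum(cen^2)))
    stop("degenerate projection: circle plane contains the camera centre")
  # cone of rays through the circle: w' M w = 0 for direction w
  M <- d^2 * diag(3) - d * (outer(n, cen) + outer(cen, n)) +
    (sum(cen^2) - r^2) * outer(n, n)
  co <- c(a = M[1, 1], b = 2 * M[1, 2], c = M[2, 2],
          d = 2 * f * M[1, 3], e = 2 * f * M[2, 3], g = f^2 * M[3, 3])
  conic_to_ellipse(co, shift = camera$principal_point)
}

# --- unprojection ------------------------------------------------------------

#' Unproject an image ellipse to the two 3D circles of fixed radius
#'
#' Recovers the two 3D circles of radius `r_fixed` whose pinhole projection is
#' the given ellipse (the classical cone-slicing two-fold ambiguity). Circles
#' are returned in front of the camera with normals oriented towards the camera
#' (`normal . center < 0`), ordered by the z-component of the normal
#' (most camera-facing first), ties broken on normal x then y.
#'
#' @param ellipse An [ellipse2d()].
#' @param camera A [pinhole_camera()].
#' @param r_fixed Circle radius in mm.
#' @return List of two [circle3d()] candidates.
#' @export
unproject_ellipse <- function(ellipse, camera, r_fixed = 1) {
  if (ellipse$minor_axis <= 0) stop("degenerate ellipse: zero minor axis")
  f <- camera$focal_length
  co <- ellipse_to_conic(ellipse, shift = camera$principal_point)
  Q <- matrix(c(co["a"], co["b"] / 2, co["d"] / (2 * f),
                co["b"] / 2, co["c"], co["e"] / (2 * f),
                co["d"] / (2 * f), co["e"] / (2 * f), co["g"] / f^2), 3, 3)
  ev <- eigen(Q, symmetric = TRUE)
  lam <- ev$values                       # decreasing
  if (sum(lam > 0) == 1) {               # normalise sign: two positive, one negative
    lam <- -rev(lam)
    ev$vectors <- ev$vectors[, 3:1]
  }
  if (!(lam[1] >= lam[2] && lam[2] > 0 && lam[3] < 0))
    stop("degenerate conic: unrecoverable geometry")
  V <- ev$vectors
  mx <- sqrt(max(0, (lam[1] - lam[2]) / (lam[1] - lam[3])))
  mz <- sqrt(max(0, (lam[2] - lam[3]) / (lam[1] - lam[3])))
  cands <- list()
  for (sx in c(1, -1)) for (sz in c(1, -1)) {
    m <- c(sx * mx, 0, sz * mz)
    b <- c(-m[3], 0, m[1])               # in-plane basis vector (m x e2)
    qb <- -(lam[1] - lam[3]) * m[1] * m[3]
    qm <- lam[1] * m[1]^2 + lam[3] * m[3]^2
    k2 <- (qb^2 - lam[2] * qm) / lam[2]^2
    if (k2 <= 0) next
    h <- r_fixed / sqrt(k2)
    cen_e <- h * m + (-h * qb / lam[2]) * b
    cen <- drop(V %*% cen_e)
    nrm <- drop(V %*% m)
    if (cen[3] < 0) cen <- -cen          # other cone sheet: reflect into z > 0
    if (sum(nrm * cen) > 0) nrm <- -nrm  # orient facing the camera
    cands[[length(cands) + 1]] <- circle3d(cen, nrm, r_fixed)
  }
  if (length(cands) == 0) stop("degenerate conic: no circular sections found")
  keys <- vapply(cands, function(cc)
    paste(signif(c(cc$center, cc$normal), 8), collapse = "|"), "")
  cands <- cands[!duplicated(keys)]
  if (length(cands) == 1) cands <- list(cands[[1]], cands[[1]])
  ord <- order(vapply(cands, function(cc) cc$normal[3], 0),
               vapply(cands, function(cc) cc$normal[1], 0),
               vapply(cands, function(cc) cc$normal[2], 0))
  cands[ord][1:2]
}

# --- refraction --------------------------------------------------------------

#' Refract a direction at an interface (vector Snell's law)
#'
#' @param incident Unit 3-vector, pointing towards the surface.
#' @param surface_normal Unit 3-vector (either orientation accepted).
#' @param n1,n2 Refractive indices of the incident and transmitting media.
#' @return Unit 3-vector of the transmitted direction, or `NULL` on total
#'   internal reflection.
#' @export
refract_direction <- function(incident, surface_normal, n1, n2) {
  stopifnot(n1 > 0, n2 > 0)
  i <- unit3(incident)
  n <- unit3(surface_normal)
  if (sum(n * i) > 0) n <- -n           # make normal oppose the incident ray
  eta <- n1 / n2
  c1 <- -sum(n * i)
  k <- 1 - eta^2 * (1 - c1^2)
  if (k < 0) return(NULL)               # total internal reflection
  unit3(eta * i + (eta * c1 - sqrt(k)) * n)
}

# Vectorised refraction for the renderer: dirs and normals are n x 3 matrices,
# normals oriented to oppose the rays by the caller. Returns n x 3.
refract_many <- function(dirs, normals, n1, n2) {
  eta <- n1 / n2
  c1 <- -rowSums(normals * dirs)
  flip <- c1 < 0
  if (any(flip)) {
    normals[flip, ] <- -normals[flip, , drop = FALSE]
    c1[flip] <- -c1[flip]
  }
  k <- 1 - eta^2 * (1 - c1^2)
  k[k < 0] <- NA_real_
  out <- eta * dirs + (eta * c1 - sqrt(k)) * normals
  out / sqrt(rowSums(out^2))
}

# --- ray-sphere --------------------------------------------------------------

#' Intersect a ray with a sphere
#'
#' @param ray A [ray3d()].
#' @param sphere A [sphere3d()].
#' @return `NULL` if there is no intersection at positive ray parameter,
#'   otherwise a list with `point`, outward `normal` and ray parameter `t`
#'   of the nearest positive intersection.
#' @export
intersect_ray_sphere <- function(ray, sphere) {
  oc <- ray$origin - sphere$center
  b <- sum(ray$direction * oc)
  cc <- sum(oc^2) - sphere$radius^2
  disc <- b^2 - cc
  if (disc < 0) return(NULL)
  s <- sqrt(disc)
  t <- -b - s
  if (t <= 0) t <- -b + s
  if (t <= 0) return(NULL)
  p <- ray$origin + t * ray$direction
  list(point = p, normal = (p - sphere$center) / sphere$radius, t = t)
}

# Vectorised nearest positive intersection parameter for origin-at-camera rays.
# dirs: n x 3 unit directions; returns n-vector of t (NA if no hit).
ray_sphere_t0 <- function(dirs, center, radius) {
  b <- dirs %*% center                  # = -(d . (0 - C))
  cc <- sum(center^2) - radius^2
  disc <- drop(b)^2 - cc
  ok <- disc >= 0
  t <- rep(NA_real_, nrow(dirs))
  s <- sqrt(disc[ok])
  b1 <- drop(b)[ok]
  tt <- b1 - s
  tt[tt <= 0] <- (b1 + s)[tt <= 0]
  tt[tt <= 0] <- NA_real_
  t[ok] <- tt
  t
}
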