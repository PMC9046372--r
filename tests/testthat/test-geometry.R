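test_that("a frontal circle projects to a circle through the pinhole map", {
  cam <- pinhole_camera(600, c(400, 400))
  el <- project_circle(circle3d(c(0, 0, 30), c(0, 0, -1), 2), cam)
  expect_equal(el$minor_axis / el$major_axis, 1, tolerance = 1e-9)
  # thin-pinhole size prediction: full major axis = 2 f r / z
  expect_equal(el$major_axis, 2 * 600 * 2 / 30, tolerance = 1e-9)
})

test_that("projected axis ratio approaches cos(tilt) in the orthographic limit", {
  cam <- pinhole_camera(6e5, c(400, 400))
  for (th in c(0.2, 0.5, 1.0)) {
    el <- project_circle(circle3d(c(0, 0, 3e4), c(sin(th), 0, -cos(th)), 2), cam)
    expect_equal(el$minor_axis / el$major_axis, cos(th), tolerance = 1e-4)
  }
})

test_that("axis ratio decreases monotonically with tilt for on-axis geometry", {
  cam <- test_camera()
  tilts <- seq(0, 60, by = 5) * pi / 180
  ratios <- vapply(tilts, function(th) {
    el <- project_circle(circle3d(c(0, 0, 35), c(sin(th), 0, -cos(th)), 2), cam)
    el$minor_axis / el$major_axis
  }, 0)
  expect_true(all(diff(ratios) < 0))
})

test_that("projection/unprojection round trip recovers the source circle", {
  cam <- pinhole_camera(600, c(400, 400))
  set.seed(101)
  n_ok <- 0
  while (n_ok < 300) {
    circ <- random_front_circle(cam)
    if (is.null(circ)) next
    n_ok <- n_ok + 1
    el <- project_circle(circ, cam)
    cands <- unproject_ellipse(el, cam, r_fixed = circ$radius)
    err <- vapply(cands, function(cc) {
      sqrt(sum((cc$center - circ$center)^2)) +
        min(sqrt(sum((cc$normal - circ$normal)^2)),
            sqrt(sum((cc$normal + circ$normal)^2)))
    }, 0)
    expect_lt(min(err), 1e-6)
  }
})

test_that("unprojection of a centred circular ellipse yields coincident candidates", {
  cam <- pinhole_camera(600, c(400, 400), principal_point = c(200, 200))
  el <- ellipse2d(c(200, 200), 80, 80, 0)
  cands <- unproject_ellipse(el, cam, r_fixed = 2)
  expect_equal(cands[[1]]$center, cands[[2]]$center, tolerance = 1e-9)
  expect_equal(abs(cands[[1]]$normal[3]), 1, tolerance = 1e-9)
})

test_that("unprojection scales linearly with the fixed radius", {
  cam <- pinhole_camera(600, c(400, 400))
  el <- ellipse2d(c(230, 180), 60, 40, 0.4)
  c1 <- unproject_ellipse(el, cam, r_fixed = 1)
  c3 <- unproject_ellipse(el, cam, r_fixed = 3)
  expect_equal(c3[[1]]$center, 3 * c1[[1]]$center, tolerance = 1e-9)
  expect_equal(c3[[1]]$normal, c1[[1]]$normal, tolerance = 1e-9)
})

test_that("degenerate projections and conics are rejected", {
  cam <- pinhole_camera(600, c(400, 400))
  # circle plane contains the camera centre
  expect_error(project_circle(circle3d(c(0, 0, 30), c(1, 0, 0), 2), cam),
               "degenerate")
  # circle reaching z = 0
  expect_error(project_circle(circle3d(c(0, 0, 1), c(1, 0, 0.01), 2), cam),
               "degenerate")
  expect_error(unproject_ellipse(ellipse2d(c(200, 200), 50, 0), cam),
               "degenerate")
})

test_that("vector Snell's law matches the scalar law and preserves the plane of incidence", {
  # normal incidence and matched media leave the direction unchanged
  expect_equal(refract_direction(c(0, 0, 1), c(0, 0, -1), 1, 1.3375),
               c(0, 0, 1), tolerance = 1e-12)
  d <- c(0.3, -0.2, 0.93); d <- d / sqrt(sum(d^2))
  expect_equal(refract_direction(d, c(0, 0, -1), 1.2, 1.2), d, tolerance = 1e-12)
  # 30 degrees into n = 1.3375: transmission angle asin(sin(30)/1.3375)
  i <- c(sin(pi / 6), 0, cos(pi / 6))
  t <- refract_direction(i, c(0, 0, -1), 1, 1.3375)
  expect_equal(asin(sqrt(t[1]^2 + t[2]^2)), asin(sin(pi / 6) / 1.3375),
               tolerance = 1e-12)
  # plane of incidence: t stays in span(i, n)
  expect_equal(t[2], 0, tolerance = 1e-12)
  set.seed(7)
  for (k in 1:50) {
    i <- stats::rnorm(3); i <- i / sqrt(sum(i^2))
    n <- stats::rnorm(3); n <- n / sqrt(sum(n^2))
    n1 <- stats::runif(1, 1, 1.6); n2 <- stats::runif(1, 1, 1.6)
    t <- refract_direction(i, n, n1, n2)
    if (is.null(t)) next
    # scalar Snell: n1 sin(theta_i) = n2 sin(theta_t)
    si <- sqrt(1 - sum(i * n)^2); st <- sqrt(1 - sum(t * n)^2)
    expect_equal(n1 * si, n2 * st, tolerance = 1e-12)
    # coplanarity of i, n, t
    expect_equal(abs(sum(t * c(i[2] * n[3] - i[3] * n[2],
                               i[3] * n[1] - i[1] * n[3],
                               i[1] * n[2] - i[2] * n[1]))), 0,
                 tolerance = 1e-12)
    # reversing the refracted ray with swapped indices recovers the incident one
    back <- refract_direction(-t, n, n2, n1)
    expect_equal(back, -i, tolerance = 1e-10)
  }
})

test_that("total internal reflection is reported as an explicit error value", {
  i <- c(sin(1.2), 0, cos(1.2))  # ~69 degrees, beyond the critical angle
  expect_null(refract_direction(i, c(0, 0, -1), 1.5, 1.0))
})

test_that("ray-sphere intersection returns the nearest hit with outward normal", {
  hit <- intersect_ray_sphere(ray3d(c(0, 0, 0), c(0, 0, 1)),
                              sphere3d(c(0, 0, 30), 12))
  expect_equal(hit$point, c(0, 0, 18))
  expect_equal(hit$normal, c(0, 0, -1))
  expect_null(intersect_ray_sphere(ray3d(c(0, 0, 0), c(1, 0, 0)),
                                   sphere3d(c(0, 0, 30), 12)))
  # tangent ray: single root returned as the hit
  hit2 <- intersect_ray_sphere(ray3d(c(12, 0, 0), c(0, 0, 1)),
                               sphere3d(c(0, 0, 30), 12))
  expect_equal(hit2$point, c(12, 0, 30), tolerance = 1e-6)
})
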