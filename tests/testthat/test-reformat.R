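test_that("axis-aligned landmarks give the identity plane", {
  lm <- data.frame(x_mm = c(0, 10, 0), y_mm = c(0, 0, 10), z_mm = 5)
  pl <- fit_endplate_plane(lm)
  expect_equal(pl$normal, c(0, 0, 1), tolerance = 1e-12)
  expect_equal(pl$in_plane_reference, c(0, 1, 0), tolerance = 1e-12)
  expect_equal(pl$origin[3], 5)
})

test_that("noise-free tilted landmarks are fitted exactly", {
  th <- 15 * pi / 180
  nrm <- c(sin(th), 0, cos(th))
  e2 <- c(0, 1, 0)
  e1 <- c(cos(th), 0, -sin(th))
  ab <- cbind(c(3, -4, 1, 2), c(0, 5, -6, 2))
  pts <- ab[, 1] %o% e1 + ab[, 2] %o% e2
  pl <- fit_endplate_plane(as.data.frame(pts) |>
                             stats::setNames(c("x", "y", "z")))
  expect_lt(max(abs(abs(sum(pl$normal * nrm)) - 1)), 1e-6)
  expect_lt(abs(sum(pl$normal * pl$in_plane_reference)), 1e-9)
  expect_equal(sqrt(sum(pl$normal^2)), 1, tolerance = 1e-12)
})

test_that("the fitted plane is a least-squares optimum", {
  set.seed(5)
  for (i in 1:5) {
    pts <- matrix(rnorm(18), ncol = 3)
    pts[, 3] <- 0.3 * pts[, 1] - 0.2 * pts[, 2] + rnorm(6, 0, 0.1)
    pl <- fit_endplate_plane(pts)
    sse <- function(nrm, org) {
      nrm <- nrm / sqrt(sum(nrm^2))
      sum((sweep(pts, 2, org) %*% nrm)^2)
    }
    best <- sse(pl$normal, pl$origin)
    for (j in 1:20) {
      expect_gte(sse(pl$normal + rnorm(3, 0, 0.02), pl$origin), best - 1e-12)
    }
  }
})

test_that("degenerate landmark configurations are rejected", {
  line <- data.frame(x = 1:5, y = 2 * (1:5), z = 3 * (1:5))
  expect_error(fit_endplate_plane(line),
               class = "vertrot_degenerate_geometry_error")
  expect_error(fit_endplate_plane(line[1:2, ]),
               class = "vertrot_degenerate_geometry_error")
  # plane containing no projection of the AP axis: normal along y
  vertical <- data.frame(x = c(0, 1, 0, 1), y = 0, z = c(0, 0, 1, 1))
  expect_error(fit_endplate_plane(vertical),
               class = "vertrot_reference_undefined_error")
})

test_that("identity reformat reproduces the stored axial section", {
  vol <- generate_tilted_volume(shape_params(), true_angle = 123,
                                tilt = c(0, 0), voxel_size = 0.75)
  sl <- extract_true_axial(vol, vol$plane, field_of_view = 70,
                          pixel_spacing = 0.5)
  m_vol <- measure_endplate_rotation(sl, angle_step = 0.1)
  m_2d <- measure_endplate_rotation(
    generate_endplate_outline(shape_params(), 123), 0.5, 0.1)
  expect_equal(m_vol$quality, "ok")
  expect_lt(circ_dist(m_vol$phi, m_2d$phi), 0.6)
})

test_that("tilted phantoms measured end-to-end recover the in-plane angle", {
  vol <- generate_tilted_volume(shape_params(), true_angle = 30,
                                tilt = c(15, 0), voxel_size = 0.75)
  pl <- fit_endplate_plane(vol$landmarks)
  sl <- extract_true_axial(vol, pl, field_of_view = 70, pixel_spacing = 0.5)
  m <- measure_endplate_rotation(sl, angle_step = 0.1)
  expect_equal(m$quality, "ok")
  expect_lt(circ_dist(m$phi, 30), 0.6)
})

test_that("measured angle is invariant to field of view and pixel spacing", {
  vol <- generate_tilted_volume(shape_params(), true_angle = 140,
                                tilt = c(10, -8), voxel_size = 0.75)
  pl <- fit_endplate_plane(vol$landmarks)
  m1 <- measure_endplate_rotation(
    extract_true_axial(vol, pl, 70, 0.5), angle_step = 0.1)
  m2 <- measure_endplate_rotation(
    extract_true_axial(vol, pl, 140, 0.5), angle_step = 0.1)
  m3 <- measure_endplate_rotation(
    extract_true_axial(vol, pl, 70, 0.25), angle_step = 0.1)
  expect_lt(circ_dist(m1$phi, m2$phi), 0.3)
  expect_lt(circ_dist(m1$phi, m3$phi), 0.6)
})

test_that("rotating the slice pixel grid is undone by reference correction", {
  vol <- generate_tilted_volume(shape_params(), true_angle = 60,
                                tilt = c(12, 6), voxel_size = 0.75)
  pl <- fit_endplate_plane(vol$landmarks)
  sl <- extract_true_axial(vol, pl, 70, 0.5)
  phi <- measure_endplate_rotation(sl, angle_step = 0.1)$phi
  # re-grid the same plane with the pixel axes rotated 90 deg clockwise:
  # the in-plane reference is now along +x, so measured angles shift by 90
  rot_mask <- t(sl$mask)[ncol(sl$mask):1, , drop = FALSE]
  sl90 <- binary_endplate_image(rot_mask, sl$pixel_spacing)
  phi90 <- measure_endplate_rotation(sl90, angle_step = 0.1)$phi
  expect_lt(circ_dist(phi90 - 90, phi), 0.3)
})

test_that("a plane missing the volume raises an empty-slice error", {
  vol <- generate_tilted_volume(shape_params(), 10, c(0, 0), 1.5,
                                body_height = 10)
  far <- structure(list(origin = c(0, 0, 500), normal = c(0, 0, 1),
                        in_plane_reference = c(0, 1, 0)),
                   class = "endplate_plane")
  expect_error(extract_true_axial(vol, far, 40, 1),
               class = "vertrot_empty_slice_error")
})
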