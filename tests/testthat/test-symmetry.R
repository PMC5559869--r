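test_that("a disc is symmetric about every diameter", {
  o <- generate_endplate_outline(disc_shape_params(), 0)
  img <- rasterize_outline(o, 0.4)
  r <- symmetry_ratio(img, c(0, 17, 45, 90, 133))
  expect_true(all(r > 0.99))
  expect_true(all(r <= 1))
})

test_that("a mask that is its own mirror scores exactly 1", {
  # build an exactly column-symmetric mask: M union mirror(M)
  set.seed(1)
  half <- matrix(runif(30 * 15) > 0.4, 30, 15)
  mask <- cbind(half, half[, 15:1])
  img <- binary_endplate_image(mask, 1)
  # centroid sits on the vertical mirror line by construction
  expect_equal(symmetry_ratio(img, 0), 1, tolerance = 1e-12)
})

test_that("ratio is 180-degree periodic exactly and bounded in [0, 1]", {
  o <- generate_endplate_outline(shape_params(), 58)
  img <- rasterize_outline(o, 0.5)
  a <- seq(0, 175, by = 12.5)
  r1 <- symmetry_ratio(img, a)
  r2 <- symmetry_ratio(img, a + 180)
  expect_identical(r1, r2)
  expect_true(all(r1 >= 0 & r1 <= 1))
})

test_that("the true axis beats an off-axis candidate on pedicled phantoms", {
  for (theta in c(12, 95, 160)) {
    img <- rasterize_outline(
      generate_endplate_outline(shape_params(), theta), 0.5)
    expect_gt(symmetry_ratio(img, theta),
              symmetry_ratio(img, (theta + 45) %% 180))
  }
})

test_that("symmetry ratio agrees with the per-pixel reflection oracle", {
  set.seed(8)
  for (i in 1:4) {
    p <- shape_params(body_width = 22, body_depth = 17,
                      pedicle_length = 5, pedicle_width = 5)
    img <- rasterize_outline(
      generate_endplate_outline(p, runif(1, 0, 180)), 0.5)
    expect_lte(nrow(img$mask), 64)
    expect_lte(ncol(img$mask), 64)
    npx <- sum(img$mask)
    for (a in runif(3, 0, 180)) {
      expect_lt(abs(symmetry_ratio(img, a) -
                      oracle_symmetry_ratio(img$mask, a)) * npx, 1)
    }
  }
})

test_that("profiles of ellipse, pedicled and disc phantoms behave as expected", {
  # ellipse: two peaks ~90 deg apart, ambiguous
  pe <- compute_symmetry_profile(
    rasterize_outline(generate_endplate_outline(ellipse_shape_params(), 40),
                      0.4))
  pk <- attr(pe, "peaks")
  expect_equal(nrow(pk), 2)
  expect_equal(circ_dist(pk$angle[1], pk$angle[2]), 90, tolerance = 2)
  expect_true(attr(pe, "ambiguous"))

  # pedicled: one dominant peak at the true angle, unambiguous
  pp <- compute_symmetry_profile(
    rasterize_outline(generate_endplate_outline(shape_params(), 40), 0.4))
  expect_false(attr(pp, "ambiguous"))
  best <- attr(pp, "peaks")$angle[1]
  expect_lt(circ_dist(best, 40), 0.5)

  # disc: flat profile, ambiguous, no usable peaks
  pd <- compute_symmetry_profile(
    rasterize_outline(generate_endplate_outline(disc_shape_params(), 0), 0.4))
  expect_true(attr(pd, "ambiguous"))
  expect_equal(nrow(attr(pd, "peaks")), 0)
  expect_lt(max(pd$ratio) - min(pd$ratio), 0.02)
})

test_that("angle selection follows the prior-resolution rule", {
  fake_profile <- function(peaks, ambiguous) {
    structure(tibble::tibble(angle = numeric(), ratio = numeric(),
                             smoothed = numeric()),
              class = c("symmetry_profile", "tbl_df", "tbl", "data.frame"),
              peaks = peaks, ambiguous = ambiguous,
              config = symmetry_config())
  }
  # three near-symmetric axes; a prior near 95 selects 100.3
  pk <- tibble::tibble(angle = c(45.4, 100.3, 142.1), ratio = c(1, 1, 1),
                       prominence = 0.1)
  sel <- select_rotation_angle(fake_profile(pk, TRUE), prior_angle = 95)
  expect_equal(sel$phi, 100.3)
  expect_equal(sel$quality, "ambiguous_resolved")

  # single unambiguous peak needs no prior
  pk1 <- tibble::tibble(angle = 89.8, ratio = 0.99, prominence = 0.2)
  sel1 <- select_rotation_angle(fake_profile(pk1, FALSE))
  expect_equal(sel1$phi, 89.8)
  expect_equal(sel1$quality, "ok")

  # ambiguous without prior -> unmeasurable
  sel2 <- select_rotation_angle(fake_profile(pk, TRUE))
  expect_equal(sel2$quality, "unmeasurable")
  expect_true(is.na(sel2$phi))

  # flat profile -> unmeasurable even with a prior
  empty <- tibble::tibble(angle = numeric(), ratio = numeric(),
                          prominence = numeric())
  sel3 <- select_rotation_angle(fake_profile(empty, TRUE), prior_angle = 10)
  expect_equal(sel3$quality, "unmeasurable")

  # prior equidistant from two equal peaks breaks the tie to the smaller angle
  pk2 <- tibble::tibble(angle = c(40, 80), ratio = c(1, 1), prominence = 0.1)
  sel4 <- select_rotation_angle(fake_profile(pk2, TRUE), prior_angle = 60)
  expect_equal(sel4$phi, 40)
})

test_that("end-to-end measurement recovers known phantom angles", {
  for (theta in c(0, 123)) {
    m <- measure_endplate_rotation(
      generate_endplate_outline(shape_params(), theta),
      pixel_spacing = 0.4, angle_step = 0.1)
    expect_equal(m$quality, "ok")
    expect_lt(circ_dist(m$phi, theta), 0.6)
  }
})

test_that("measurement is equivariant under rigid rotation of the shape", {
  o <- generate_endplate_outline(shape_params(), 20)
  base <- measure_endplate_rotation(o, 0.4, 0.1)$phi
  for (delta in c(30, 77.5, 140)) {
    m <- measure_endplate_rotation(rotate_outline(o, delta), 0.4, 0.1)$phi
    expect_lt(circ_dist(m, base + delta), 0.6)
  }
})

test_that("measured angle is stable when the pixel spacing doubles", {
  step <- 0.5
  for (theta in c(20, 77, 141)) {
    o <- generate_endplate_outline(shape_params(), theta)
    m1 <- measure_endplate_rotation(o, 0.4, step)$phi
    m2 <- measure_endplate_rotation(o, 0.8, step)$phi
    expect_lt(circ_dist(m1, m2), 2 * step)
  }
})

test_that("metadata travels from outline to measurement row", {
  o <- generate_endplate_outline(shape_params(), 10, patient = "P01",
                                 level = "T8", side = "superior",
                                 timepoint = "t1")
  m <- measure_endplate_rotation(o, 0.5, 0.5)
  expect_equal(m$patient, "P01")
  expect_equal(m$level, "T8")
  expect_equal(m$side, "superior")
  expect_equal(m$timepoint, "t1")
})
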