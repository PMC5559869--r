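test_that("inter-endplate rotation is the signed minimal axial difference", {
  expect_equal(inter_endplate_rotation(93, 90), 3)
  expect_equal(inter_endplate_rotation(90, 90), 0)
  expect_equal(inter_endplate_rotation(1, 179), 2)   # wraps across the seam
  expect_equal(inter_endplate_rotation(179, 1), -2)
  expect_true(is.na(inter_endplate_rotation(NA, 90)))
  expect_error(inter_endplate_rotation(190, 90),
               class = "vertrot_parameter_error")
})

test_that("wrap_angle_diff maps into (-90, 90] and matches a brute-force oracle", {
  # oracle: the representative of x mod 180 with smallest magnitude,
  # preferring +90 at the boundary
  oracle <- function(x) {
    cand <- x + 180 * (-3:3)
    cand <- cand[cand > -90 & cand <= 90]
    cand[1]
  }
  xs <- c(-269, -180, -90.5, -90, -3, 0, 45, 90, 90.5, 178, 359)
  expect_equal(wrap_angle_diff(xs), vapply(xs, oracle, numeric(1)))
})

test_that("intra-vertebral rotation is antisymmetric in the endplate roles", {
  st <- generate_spine_study(spine_study_spec(seed = 2), outlines = FALSE)
  rot <- truth_rotations(st)
  v <- intra_vertebral_rotation(st, "T8", "t1", rot)
  swapped <- rot
  swapped$side <- ifelse(swapped$side == "superior", "inferior", "superior")
  expect_equal(intra_vertebral_rotation(st, "T8", "t1", swapped), -v)
})

test_that("inter-vertebral rotation validates adjacency and telescopes", {
  st <- generate_spine_study(spine_study_spec(seed = 3), outlines = FALSE)
  expect_error(inter_vertebral_rotation(st, c("T4", "T6"), "t1"),
               class = "vertrot_usage_error")
  # sum of all inter-endplate rotations telescopes to top-vs-bottom
  rot <- truth_rotations(st)
  ep <- st$truth[st$truth$timepoint == "t1", ]
  phis <- ep$true_angle
  steps <- vertrot::wrap_angle_diff(head(phis, -1) - tail(phis, -1))
  expect_equal(sum(steps),
               inter_endplate_rotation(phis[1], phis[length(phis)]),
               tolerance = 1e-12)
})

test_that("rotation change matches the worked sign-convention example", {
  expect_equal(rotation_change(3, 4), 1)
  expect_equal(rotation_change(4, 4), 0)
  expect_equal(rotation_change(4, 3), -rotation_change(3, 4))
})

test_that("classification applies the strict gate and the apex sign rule", {
  r <- classify_change(4, "below", 8.2)
  expect_false(r$significant)
  expect_true(r$loss_of_correction)   # loss direction, not significant

  r2 <- classify_change(-9, "above", 8.2)
  expect_true(r2$significant)
  expect_true(r2$loss_of_correction)

  r3 <- classify_change(8.2, "below", 8.2)  # boundary: strict inequality
  expect_false(r3$significant)

  r4 <- classify_change(5, "at", 8.2)
  expect_true(is.na(r4$loss_of_correction))

  r5 <- classify_change(9, "above", 8.2)    # gain of correction above apex
  expect_true(r5$significant)
  expect_false(r5$loss_of_correction)

  expect_error(classify_change(1, "below", -2),
               class = "vertrot_parameter_error")
  expect_error(classify_change(1, "sideways", 8.2),
               class = "vertrot_parameter_error")
})

test_that("change arithmetic is invariant to a common mod-180 offset", {
  st <- generate_spine_study(
    spine_study_spec(injected_changes = c("T7" = 9, "T9/T10" = -11),
                     seed = 6),
    outlines = FALSE)
  base <- study_changes(st)
  for (offset in c(30, 89.5, 150)) {
    shifted <- st
    shifted$truth$true_angle <- (shifted$truth$true_angle + offset) %% 180
    expect_equal(study_changes(shifted)$change, base$change,
                 tolerance = 1e-9)
  }
})

test_that("unmeasurable endplates propagate as missing, never zero", {
  st <- generate_spine_study(spine_study_spec(seed = 7), outlines = FALSE)
  rot <- truth_rotations(st)
  rot$quality[rot$level == "T8" & rot$side == "superior" &
                rot$timepoint == "t2"] <- "unmeasurable"
  ch <- study_changes(st, rotations = rot, limit = 8.2)
  expect_true(is.na(ch$change[ch$level_key == "T8"]))
  expect_true(is.na(ch$change[ch$level_key == "T7/T8"]))
  expect_false(anyNA(ch$change[!ch$level_key %in% c("T8", "T7/T8")]))
})

test_that("significance flags mark exactly the injected-above-limit levels", {
  inj <- c("T6" = 10, "T8/T9" = -9, "T10" = 3)
  st <- generate_spine_study(spine_study_spec(injected_changes = inj,
                                              seed = 8), outlines = FALSE)
  ch <- study_changes(st, limit = 8.2)
  expect_setequal(ch$level_key[which(ch$significant)], c("T6", "T8/T9"))
})
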