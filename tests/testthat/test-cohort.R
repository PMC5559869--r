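test_that("the change matrix aligns patients by anatomical level", {
  s1 <- generate_spine_study(spine_study_spec(patient = "P01", seed = 1),
                             outlines = FALSE)
  s2 <- generate_spine_study(
    spine_study_spec(levels = c(paste0("T", 5:12), "L1", "L2"),
                     instrumented_range = c("T6", "L1"), apex = "T9",
                     patient = "P02", seed = 2),
    outlines = FALSE)
  ch <- cohort_changes(list(s1, s2), limit = 8.2)
  mat <- build_change_matrix(ch)
  expect_equal(nrow(mat), nrow(ch))   # conservation: every record is a cell
  keys1 <- spine_entities(s1$levels)$level_key
  keys2 <- spine_entities(s2$levels)$level_key
  expect_setequal(unique(mat$level_key), union(keys1, keys2))
  # rows come out in anatomical order
  ranks <- vertrot:::level_key_rank(mat$level_key)
  expect_true(all(diff(ranks) >= 0))
  # duplicate records are a data error
  expect_error(build_change_matrix(rbind(ch, ch[1, ])),
               class = "vertrot_data_error")
})

test_that("junction means are zero without injected junction changes", {
  studies <- make_cohort(6)
  js <- junction_summary(studies, limit = 8.2)
  expect_true(all(abs(js$summary$mean_change) < 1e-9))
  expect_false(js$en_bloc)
})

test_that("an en-bloc cohort is detected at the junction discs", {
  studies <- make_cohort(5, function(i) c("T4/T5" = -10, "T12/L1" = 10))
  js <- junction_summary(studies, limit = 8.2)
  s <- js$summary
  expect_equal(s$mean_change[s$category == "adjacent_superior_disc"], -10)
  expect_equal(s$mean_change[s$category == "adjacent_inferior_disc"], 10)
  expect_true(js$en_bloc)
})

test_that("junction means equal independently recomputed patient means", {
  studies <- make_cohort(4, function(i) {
    stats::setNames(c(i, -i), c("T4", "T4/T5"))
  })
  js <- junction_summary(studies, limit = 8.2)
  s <- js$summary
  expect_equal(s$mean_change[s$category == "adjacent_superior_vertebra"],
               mean(1:4))
  expect_equal(s$mean_change[s$category == "adjacent_superior_disc"],
               mean(-(1:4)))
  expect_equal(s$min_change[s$category == "adjacent_superior_vertebra"], 1)
  expect_equal(s$max_change[s$category == "adjacent_superior_vertebra"], 4)
})

test_that("patients with at least one measurable change are counted", {
  studies <- make_cohort(8, function(i) {
    if (i <= 3) c("T7" = 10) else c("T7" = 2)
  })
  ch <- cohort_changes(studies, limit = 8.2)
  expect_equal(count_patients_with_change(ch), 3)
  expect_equal(count_patients_with_change(gate_cohort(ch, 100)), 0)
  expect_equal(count_patients_with_change(gate_cohort(ch, 1)), 8)
})

test_that("unmeasurable endplates exclude the whole patient", {
  studies <- make_cohort(3)
  # patient 2 has an apex endplate with an unresolvable ambiguity
  bad <- truth_rotations(studies[[2]])
  bad$quality[bad$level == "T8" & bad$side == "superior"] <- "unmeasurable"
  bad$phi[bad$level == "T8" & bad$side == "superior"] <- NA
  studies[[2]]$rotations <- bad
  rep <- exclusion_report(studies)
  expect_equal(rep$n_excluded, 1)
  expect_equal(rep$excluded_patients, "P02")
  expect_equal(unique(rep$details$reason), "unresolvable ambiguity")
  ch <- cohort_changes(studies, limit = 8.2)
  expect_false("P02" %in% ch$patient)
  summ <- cohort_summary(studies, limit = 8.2)
  expect_equal(summ$n_patients, 2)
  expect_false("P02" %in% summ$matrix$patient)
})

test_that("cohort summaries survive CSV serialization to 1e-9", {
  studies <- make_cohort(4, function(i) c("T6/T7" = 9.123456789))
  ch <- cohort_changes(studies, limit = 8.2)
  path <- tempfile(fileext = ".csv")
  write_changes_csv(ch, path)
  back <- read_changes_csv(path)
  expect_equal(back$change, ch$change, tolerance = 1e-9)
  m1 <- tapply(ch$change, ch$level_key, mean)
  m2 <- tapply(back$change, back$level_key, mean)
  expect_equal(m2[names(m1)], m1, tolerance = 1e-9)
})

test_that("the full pipeline is deterministic for a fixed seed", {
  a <- cohort_summary(make_cohort(3, function(i) c("T8" = 10)), limit = 8.2)
  b <- cohort_summary(make_cohort(3, function(i) c("T8" = 10)), limit = 8.2)
  expect_equal(glance(a), glance(b))
  expect_equal(tidy(a), tidy(b))
  expect_equal(a$junctions$summary, b$junctions$summary)
})
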