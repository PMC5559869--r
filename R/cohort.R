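#' Exclusion report for a cohort of spine studies
#'
#' Patients with any endplate whose rotation could not be measured (an
#' ambiguous symmetry profile with no resolvable prior) are excluded from all
#' cohort summaries, mirroring the exclusion of unmeasurable datasets from
#' the analysis.
#'
#' @param studies List of `spine_study` objects (measured or truth-backed).
#' @return A list with `n_excluded`, `excluded_patients` (character) and
#'   `details` (tibble `patient`, `level`, `side`, `timepoint`, `reason`).
#' @export
exclusion_report <- function(studies) {
  details <- purrr::map_dfr(studies, function(st) {
    rot <- study_rotation_table(st)
    bad <- rot[!is.na(rot$quality) & rot$quality == "unmeasurable", ,
               drop = FALSE]
    if (nrow(bad) == 0) return(NULL)
    tibble(patient = st$patient, level = bad$level, side = bad$side,
           timepoint = bad$timepoint, reason = "unresolvable ambiguity")
  })
  if (nrow(details) == 0) {
    details <- tibble(patient = character(), level = character(),
                      side = character(), timepoint = character(),
                      reason = character())
  }
  excluded <- unique(details$patient)
  list(n_excluded = length(excluded), excluded_patients = excluded,
       details = details)
}

#' Gated change records for a whole cohort
#'
#' Runs [study_changes()] for every non-excluded study and binds the records
#' into one long table, the cohort's analysis dataset.
#'
#' @param studies List of `spine_study` objects.
#' @param limit Significance limit in degrees (the 95% limit of agreement).
#' @param timepoints Character of length 2, earlier then later.
#' @return Tibble of change records across patients; excluded patients
#'   contribute no rows. The exclusion report is attached as attribute
#'   `exclusions`.
#' @export
cohort_changes <- function(studies, limit, timepoints = c("t1", "t2")) {
  excl <- exclusion_report(studies)
  keep <- purrr::keep(studies,
                      ~ !.x$patient %in% excl$excluded_patients)
  out <- purrr::map_dfr(keep, study_changes, timepoints = timepoints,
                        limit = limit)
  attr(out, "exclusions") <- excl
  out
}

#' Level-by-patient change matrix
#'
#' Arranges a cohort's change records as the level-key x patient grid used
#' for cohort reporting: rows are anatomical entities ordered cephalad to
#' caudal, columns are patients, and each cell carries the change, its
#' significance, the instrumented flag and the apex marker. Patients with
#' different instrumented ranges are aligned by anatomical level; cells a
#' patient was not measured at are simply absent.
#'
#' @param changes Tibble of change records from [cohort_changes()] (or a
#'   single study's [study_changes()]).
#' @return The validated long grid (class `cohort_matrix`), ordered by
#'   anatomical level then patient. Use [tidyr::pivot_wider()] or
#'   [autoplot()] for a wide/graphic view.
#' @export
build_change_matrix <- function(changes) {
  if (anyDuplicated(changes[, c("patient", "level_key")])) {
    abort("duplicate (patient, level_key) records.",
          class = "vertrot_data_error")
  }
  out <- changes[order(level_key_rank(changes$level_key), changes$patient), ]
  class(out) <- c("cohort_matrix", class(out))
  out
}

# anatomical ordering rank for vertebra and disc keys
level_key_rank <- function(keys) {
  ladder <- level_ladder()
  vapply(strsplit(keys, "/", fixed = TRUE), function(parts) {
    mean(match(parts, ladder)) * 2
  }, numeric(1))
}

#' Junction and apex summary, with en-bloc assessment
#'
#' Summarises the rotation changes at the five anatomical categories that
#' diagnose en-bloc movement of the fused construct: the first
#' un-instrumented vertebra above and below the construct (intra-vertebral
#' change), the adjacent un-instrumented disc above and below (inter-
#' vertebral change), and the curve apex. If the whole construct rotated as a
#' rigid unit between timepoints, the two junction discs must absorb that
#' rotation with equal magnitude and opposite sign; the en-bloc verdict
#' therefore requires both junction-disc mean changes to exceed the limit in
#' magnitude with opposite, construct-consistent signs.
#'
#' @param studies List of `spine_study` objects.
#' @param limit Significance limit in degrees.
#' @param timepoints Character of length 2.
#' @return A list of class `junction_summary`: `summary` (tibble `category`,
#'   `mean_change`, `min_change`, `max_change`, `n`), `en_bloc` (logical
#'   verdict) and `limit`.
#' @export
junction_summary <- function(studies, limit, timepoints = c("t1", "t2")) {
  excl <- exclusion_report(studies)
  keep <- purrr::keep(studies,
                      ~ !.x$patient %in% excl$excluded_patients)
  per_patient <- purrr::map_dfr(keep, function(st) {
    ch <- study_changes(st, timepoints = timepoints, limit = limit)
    i1 <- match(st$instrumented_range[1], st$levels)
    i2 <- match(st$instrumented_range[2], st$levels)
    cats <- c(
      adjacent_superior_vertebra = st$levels[i1 - 1],
      adjacent_inferior_vertebra = st$levels[i2 + 1],
      adjacent_superior_disc = paste(st$levels[i1 - 1], st$levels[i1],
                                     sep = "/"),
      adjacent_inferior_disc = paste(st$levels[i2], st$levels[i2 + 1],
                                     sep = "/"),
      apex = st$apex
    )
    tibble(patient = st$patient, category = names(cats),
           change = ch$change[match(cats, ch$level_key)])
  })
  summ <- per_patient |>
    dplyr::group_by(.data$category) |>
    dplyr::summarise(mean_change = mean(.data$change, na.rm = TRUE),
                     min_change = suppressWarnings(min(.data$change, na.rm = TRUE)),
                     max_change = suppressWarnings(max(.data$change, na.rm = TRUE)),
                     n = sum(!is.na(.data$change)), .groups = "drop")
  sup <- summ$mean_change[summ$category == "adjacent_superior_disc"]
  inf <- summ$mean_change[summ$category == "adjacent_inferior_disc"]
  en_bloc <- length(sup) == 1 && length(inf) == 1 &&
    !is.na(sup) && !is.na(inf) &&
    abs(sup) > limit && abs(inf) > limit && sign(sup) == -sign(inf)
  structure(list(summary = summ, en_bloc = en_bloc, limit = limit),
            class = "junction_summary")
}

#' @export
print.junction_summary <- function(x, ...) {
  cat(sprintf("<junction_summary> limit %.1f deg, en-bloc movement %s\n",
              x$limit, if (x$en_bloc) "DETECTED" else "not detected"))
  print(x$summary)
  invisible(x)
}

#' Number of patients with at least one measurable change
#'
#' @param changes Gated change records (from [cohort_changes()] or
#'   [gate_cohort()]).
#' @return Count of distinct patients with `significant == TRUE` anywhere in
#'   their measured range.
#' @export
count_patients_with_change <- function(changes) {
  length(unique(changes$patient[which(changes$significant)]))
}

#' Full cohort summary
#'
#' Assembles the cohort-level outputs in one object: patient and exclusion
#' counts, the count of patients with at least one significant change, the
#' junction/apex summary with the en-bloc verdict, and the level x patient
#' change matrix.
#'
#' @param studies List of `spine_study` objects.
#' @param limit Significance limit in degrees.
#' @param timepoints Character of length 2.
#' @return A list of class `cohort_summary`.
#' @export
#' @examples
#' studies <- lapply(1:3, function(i) {
#'   generate_spine_study(spine_study_spec(patient = sprintf("P%02d", i),
#'                                         seed = i), outlines = FALSE)
#' })
#' cohort_summary(studies, limit = 8.2)
cohort_summary <- function(studies, limit, timepoints = c("t1", "t2")) {
  excl <- exclusion_report(studies)
  changes <- cohort_changes(studies, limit = limit, timepoints = timepoints)
  structure(list(
    n_patients = length(studies) - excl$n_excluded,
    exclusions = excl,
    patients_with_significant_change = count_patients_with_change(changes),
    junctions = junction_summary(studies, limit = limit,
                                 timepoints = timepoints),
    matrix = build_change_matrix(changes),
    limit = limit
  ), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf(
    "<cohort_summary> %d patients analysed (%d excluded), limit %.1f deg\n  %d patient(s) with at least one significant rotation change\n",
    x$n_patients, x$exclusions$n_excluded, x$limit,
    x$patients_with_significant_change))
  print(x$junctions)
  invisible(x)
}
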