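#' Signed minimal difference between two axial angles
#'
#' Endplate orientation is axial (undirected), so angles live on a
#' 180-degree-periodic circle. `wrap_angle_diff()` maps any signed degree
#' difference into the half-open interval `(-90, 90]`, which makes
#' differences well defined across the 0/180 seam.
#'
#' @param x Signed degree difference(s).
#' @return Value(s) in `(-90, 90]`.
#' @export
#' @examples
#' wrap_angle_diff(1 - 179) # +2: wraps across the seam
wrap_angle_diff <- function(x) {
  m <- x %% 180
  ifelse(m > 90, m - 180, m)
}

#' Inter-endplate rotation between two endplate angles
#'
#' The relative rotation of the cephalad (upper) endplate over the caudal
#' (lower) endplate, `phi_upper - phi_lower`, as a signed minimal difference
#' in `(-90, 90]`. Positive values are clockwise rotations of the cephalad
#' endplate viewed from above.
#'
#' @param phi_upper,phi_lower Endplate angles in degrees, `[0, 180)`; `NA`
#'   (unmeasurable) propagates.
#' @return Signed degrees in `(-90, 90]`.
#' @export
#' @examples
#' inter_endplate_rotation(93, 90) # +3
inter_endplate_rotation <- function(phi_upper, phi_lower) {
  ok <- !is.na(phi_upper) & !is.na(phi_lower)
  if (any(ok & (phi_upper < 0 | phi_upper >= 180 |
                phi_lower < 0 | phi_lower >= 180))) {
    abort("endplate angles must lie in [0, 180) degrees.",
          class = "vertrot_parameter_error")
  }
  wrap_angle_diff(phi_upper - phi_lower)
}

#' Change in a level's rotation between two timepoints
#'
#' @param value_t1,value_t2 Signed inter-endplate rotations in degrees at the
#'   earlier and later timepoint.
#' @return `value_t2 - value_t1` after wrap normalization; `NA` propagates.
#' @export
#' @examples
#' rotation_change(3, 4) # +1
rotation_change <- function(value_t1, value_t2) {
  wrap_angle_diff(value_t2 - value_t1)
}

#' Classify a rotation change against the significance gate and the apex
#'
#' A change is significant when its magnitude strictly exceeds the limit of
#' agreement. A loss of surgical correction is a change whose sign pushes the
#' level back toward the pre-operative deformity: negative changes above the
#' curve apex or positive changes below it. At the apex itself the loss flag
#' is undefined (`NA`).
#'
#' @param change Signed change(s) in degrees.
#' @param direction_vs_apex `"above"`, `"below"` or `"at"`.
#' @param limit Positive significance limit in degrees (the 1.96 x SD_intra
#'   limit of agreement).
#' @return Tibble with logical columns `significant` and `loss_of_correction`.
#' @export
#' @examples
#' classify_change(4, "below", 8.2) # loss direction but not significant
classify_change <- function(change, direction_vs_apex, limit) {
  if (!is.numeric(limit) || length(limit) != 1 || limit <= 0) {
    abort("`limit` must be a single positive number of degrees.",
          class = "vertrot_parameter_error")
  }
  direction_vs_apex <- match_direction(direction_vs_apex, length(change))
  significant <- abs(change) > limit
  loss <- ifelse(direction_vs_apex == "at", NA,
                 (change < 0 & direction_vs_apex == "above") |
                 (change > 0 & direction_vs_apex == "below"))
  tibble(significant = significant, loss_of_correction = loss)
}

match_direction <- function(x, n) {
  x <- as.character(x)
  if (length(x) == 1) x <- rep(x, n)
  bad <- !x %in% c("above", "below", "at")
  if (any(bad & !is.na(x))) {
    abort("`direction_vs_apex` must be 'above', 'below' or 'at'.",
          class = "vertrot_parameter_error")
  }
  x
}

# canonical cephalad -> caudal vertebral ladder used for ordering level keys
level_ladder <- function() {
  c(paste0("C", 1:7), paste0("T", 1:12), paste0("L", 1:5), "S1")
}

#' Interleaved vertebra/disc entity sequence for a set of levels
#'
#' @param levels Ordered cephalad-to-caudal vertebral labels, e.g.
#'   `c("T4", "T5", ...)`.
#' @return Tibble with columns `level_key` (e.g. `"T4"`, `"T4/T5"`) and
#'   `kind` (`"intra_vertebral"` or `"inter_vertebral"`), ordered
#'   cephalad to caudal.
#' @export
spine_entities <- function(levels) {
  n <- length(levels)
  keys <- character(2 * n - 1)
  kind <- character(2 * n - 1)
  keys[seq(1, 2 * n - 1, by = 2)] <- levels
  kind[seq(1, 2 * n - 1, by = 2)] <- "intra_vertebral"
  if (n > 1) {
    keys[seq(2, 2 * n - 2, by = 2)] <-
      paste(levels[-n], levels[-1], sep = "/")
    kind[seq(2, 2 * n - 2, by = 2)] <- "inter_vertebral"
  }
  tibble(level_key = keys, kind = kind)
}

lookup_phi <- function(rotations, level, side, timepoint) {
  row <- rotations[rotations$level == level & rotations$side == side &
                   rotations$timepoint == timepoint, , drop = FALSE]
  if (nrow(row) == 0) return(NA_real_)
  if (nrow(row) > 1) {
    abort(sprintf("duplicate rotation record for %s %s %s",
                  level, side, timepoint),
          class = "vertrot_data_error")
  }
  if (!is.na(row$quality) && row$quality == "unmeasurable") return(NA_real_)
  row$phi
}

#' Intra-vertebral rotation of one level at one timepoint
#'
#' The rotational deformity within a single vertebra: the inter-endplate
#' rotation of its superior endplate over its inferior endplate.
#'
#' @param study A `spine_study`.
#' @param level Vertebral label present in `study$levels`.
#' @param timepoint Timepoint label.
#' @param rotations Optional rotation table overriding the study's own (a
#'   tibble with columns `level`, `side`, `timepoint`, `phi`, `quality`).
#' @return Signed degrees in `(-90, 90]`, `NA` if an endplate is missing or
#'   unmeasurable.
#' @export
intra_vertebral_rotation <- function(study, level, timepoint,
                                     rotations = NULL) {
  rot <- rotations %||% study_rotation_table(study)
  inter_endplate_rotation(lookup_phi(rot, level, "superior", timepoint),
                          lookup_phi(rot, level, "inferior", timepoint))
}

#' Inter-vertebral (intra-discal) rotation at one disc at one timepoint
#'
#' The relative rotation between the inferior endplate of the cephalad
#' vertebra and the superior endplate of the adjacent caudal vertebra.
#'
#' @param study A `spine_study`.
#' @param disc_between Character of length 2 (`c("T7", "T8")`) or a disc key
#'   (`"T7/T8"`); the two levels must be adjacent in `study$levels`.
#' @inheritParams intra_vertebral_rotation
#' @return Signed degrees in `(-90, 90]`.
#' @export
inter_vertebral_rotation <- function(study, disc_between, timepoint,
                                     rotations = NULL) {
  if (length(disc_between) == 1) {
    disc_between <- strsplit(disc_between, "/", fixed = TRUE)[[1]]
  }
  i <- match(disc_between, study$levels)
  if (anyNA(i) || i[2] != i[1] + 1) {
    abort("`disc_between` must name two adjacent levels of the study.",
          class = "vertrot_usage_error")
  }
  rot <- rotations %||% study_rotation_table(study)
  inter_endplate_rotation(
    lookup_phi(rot, disc_between[1], "inferior", timepoint),
    lookup_phi(rot, disc_between[2], "superior", timepoint)
  )
}

#' Inter/intra-vertebral rotation change records for one patient study
#'
#' Computes, for every vertebra (intra-vertebral) and every adjacent disc
#' (inter-vertebral) in the study, the signed rotation at both timepoints,
#' the change between them, its position relative to the curve apex, and —
#' when a significance limit is supplied — the significance and
#' loss-of-correction flags.
#'
#' @param study A `spine_study`.
#' @param rotations Optional rotation table (defaults to the study's measured
#'   rotations if present, otherwise its ground truth).
#' @param timepoints Character of length 2, earlier then later.
#' @param limit Optional significance limit in degrees (e.g. the 1.96 x SD
#'   limit of agreement); when `NULL` the flag columns are `NA`.
#' @return Tibble with one row per entity: `patient`, `level_key`, `kind`,
#'   `instrumented`, `direction_vs_apex`, `value_t1`, `value_t2`, `change`,
#'   `significant`, `loss_of_correction`.
#' @export
study_changes <- function(study, rotations = NULL,
                          timepoints = c("t1", "t2"), limit = NULL) {
  stopifnot(inherits(study, "spine_study"))
  rot <- rotations %||% study_rotation_table(study)
  ents <- spine_entities(study$levels)
  value_at <- function(tp) {
    purrr::map_dbl(seq_len(nrow(ents)), function(j) {
      if (ents$kind[j] == "intra_vertebral") {
        intra_vertebral_rotation(study, ents$level_key[j], tp, rot)
      } else {
        inter_vertebral_rotation(study, ents$level_key[j], tp, rot)
      }
    })
  }
  v1 <- value_at(timepoints[1])
  v2 <- value_at(timepoints[2])
  apex_i <- match(study$apex, ents$level_key)
  if (is.na(apex_i)) {
    abort("study apex is not an entity of the study levels.",
          class = "vertrot_data_error")
  }
  dir <- ifelse(seq_len(nrow(ents)) < apex_i, "above",
                ifelse(seq_len(nrow(ents)) > apex_i, "below", "at"))
  instr <- entity_instrumented(ents, study$instrumented_range, study$levels)
  out <- tibble(
    patient = study$patient,
    level_key = ents$level_key, kind = ents$kind,
    instrumented = instr, direction_vs_apex = dir,
    value_t1 = v1, value_t2 = v2,
    change = rotation_change(v1, v2)
  )
  if (is.null(limit)) {
    out$significant <- NA
    out$loss_of_correction <- NA
  } else {
    cls <- classify_change(out$change, out$direction_vs_apex, limit)
    out$significant <- cls$significant
    out$loss_of_correction <- cls$loss_of_correction
  }
  out
}

entity_instrumented <- function(ents, instrumented_range, levels) {
  i1 <- match(instrumented_range[1], levels)
  i2 <- match(instrumented_range[2], levels)
  in_range <- function(l) {
    k <- match(l, levels)
    !is.na(k) && k >= i1 && k <= i2
  }
  vapply(ents$level_key, function(k) {
    parts <- strsplit(k, "/", fixed = TRUE)[[1]]
    all(vapply(parts, in_range, logical(1)))
  }, logical(1), USE.NAMES = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
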