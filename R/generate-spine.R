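#' Specification of a synthetic spine study
#'
#' Describes one synthetic patient: the imaged levels (the instrumented
#' segment plus exactly one adjacent un-instrumented vertebra above and
#' below), the curve apex, the ground-truth endplate angles at the first
#' timepoint, and the inter/intra-vertebral rotation changes injected between
#' the two timepoints.
#'
#' @param levels Ordered cephalad-to-caudal vertebral labels. The default
#'   `T4..L1` emulates a thoracic fusion spanning `T5..T12` imaged with one
#'   adjacent level on each side.
#' @param instrumented_range Character of length 2, first and last
#'   instrumented vertebra; must leave exactly one study level above and one
#'   below.
#' @param apex Level key of the curve apex: a vertebra (`"T8"`) or a disc
#'   (`"T8/T9"`), inside the instrumented range.
#' @param truth_angles_t1 Ground-truth endplate angles (degrees, `[0, 180)`)
#'   at the first timepoint, one per endplate in cephalad-to-caudal order
#'   (superior then inferior per level; length `2 * length(levels)`). The
#'   default places all endplates at 90 degrees with a smooth residual
#'   rotation pattern of amplitude `rot_amplitude` peaking at the apex,
#'   emulating a partially corrected right thoracic curve.
#' @param injected_changes Named numeric vector of signed degree changes in
#'   inter/intra-vertebral rotation applied between the timepoints, named by
#'   entity key (`"T8"` for intra-vertebral, `"T8/T9"` for inter-vertebral).
#' @param rot_amplitude Amplitude in degrees of the default apical rotation
#'   pattern.
#' @param tracing_noise_sd_mm Radial SD in mm of the simulated manual-tracing
#'   noise applied to outline vertices (0 = noise-free).
#' @param patient Patient identifier.
#' @param seed Integer seed controlling every random element of the study.
#' @return A list of class `spine_study_spec`.
#' @export
spine_study_spec <- function(levels = c(paste0("T", 4:12), "L1"),
                             instrumented_range = c("T5", "T12"),
                             apex = "T8",
                             truth_angles_t1 = NULL,
                             injected_changes = numeric(),
                             rot_amplitude = 12,
                             tracing_noise_sd_mm = 0,
                             patient = "P01",
                             seed = 1L) {
  i <- match(instrumented_range, levels)
  if (anyNA(i) || i[1] != 2 || i[2] != length(levels) - 1) {
    abort(paste("`instrumented_range` must leave exactly one un-instrumented",
                "level above and one below within `levels`."),
          class = "vertrot_parameter_error")
  }
  ents <- spine_entities(levels)
  if (!apex %in% ents$level_key) {
    abort("`apex` must be a vertebra or disc key of `levels`.",
          class = "vertrot_parameter_error")
  }
  instr_ents <- ents$level_key[
    entity_instrumented(ents, instrumented_range, levels)]
  if (!apex %in% instr_ents) {
    abort("`apex` must lie inside the instrumented range.",
          class = "vertrot_parameter_error")
  }
  n_ep <- 2 * length(levels)
  if (is.null(truth_angles_t1)) {
    # smooth residual axial rotation peaking at the apex
    apex_i <- match(apex, ents$level_key)
    pos <- seq(1, 2 * length(levels) - 1, length.out = n_ep)
    truth_angles_t1 <-
      (90 + rot_amplitude * exp(-((pos - apex_i) / 4)^2)) %% 180
  }
  if (length(truth_angles_t1) != n_ep ||
      any(truth_angles_t1 < 0 | truth_angles_t1 >= 180)) {
    abort("`truth_angles_t1` must give one angle in [0, 180) per endplate.",
          class = "vertrot_parameter_error")
  }
  if (length(injected_changes) &&
      (is.null(names(injected_changes)) ||
       !all(names(injected_changes) %in% ents$level_key))) {
    abort("`injected_changes` must be named by entity keys of the study.",
          class = "vertrot_parameter_error")
  }
  if (tracing_noise_sd_mm < 0) {
    abort("`tracing_noise_sd_mm` must be >= 0.",
          class = "vertrot_parameter_error")
  }
  structure(list(levels = levels, instrumented_range = instrumented_range,
                 apex = apex, truth_angles_t1 = truth_angles_t1,
                 injected_changes = injected_changes,
                 tracing_noise_sd_mm = tracing_noise_sd_mm,
                 patient = patient, seed = as.integer(seed)),
            class = "spine_study_spec")
}

#' Generate a synthetic spine study with known ground truth
#'
#' Builds the full two-timepoint study described by a [spine_study_spec()]:
#' a ground-truth angle table for every endplate at both timepoints and, when
#' `outlines = TRUE`, a traced outline per endplate and timepoint. Injected
#' inter/intra-vertebral changes are realized by rotating, for each affected
#' entity, every endplate cephalad of (and including) its upper endplate by
#' the injected amount — which changes exactly that entity's relative
#' rotation and leaves all others untouched. Identical spec and seed
#' reproduce identical output.
#'
#' Superior endplates carry pedicle lobes (as traced through the pedicles at
#' their narrowest point); inferior endplates are pedicle-free but
#' posteriorly flattened, so both have a unique symmetry axis.
#'
#' @param spec A [spine_study_spec()].
#' @param outlines Generate polygon outlines (set `FALSE` for angle-table
#'   only studies, which is much faster).
#' @return A list of class `spine_study` with elements `patient`, `levels`,
#'   `instrumented_range`, `apex`, `truth` (tibble `level`, `side`,
#'   `timepoint`, `true_angle`), `outlines` (named list, keys
#'   `"level.side.timepoint"`, or `NULL`), `rotations` (measured angles;
#'   empty until [measure_spine_study()] is run) and `spec`.
#' @export
#' @examples
#' spec <- spine_study_spec(injected_changes = c("T8" = 10))
#' study <- generate_spine_study(spec, outlines = FALSE)
#' study_changes(study)
generate_spine_study <- function(spec, outlines = TRUE) {
  stopifnot(inherits(spec, "spine_study_spec"))
  levels <- spec$levels
  n <- length(levels)
  ents <- spine_entities(levels)
  ep <- tibble(
    level = rep(levels, each = 2),
    side = rep(c("superior", "inferior"), n)
  )
  # entity i sits between endplate i and endplate i + 1; adding the injected
  # change to endplates 1..i shifts that entity's relative rotation only
  c_ent <- stats::setNames(numeric(nrow(ents)), ents$level_key)
  if (length(spec$injected_changes)) {
    c_ent[names(spec$injected_changes)] <- spec$injected_changes
  }
  delta <- unname(rev(cumsum(rev(c(c_ent, 0)))))[seq_len(nrow(ep))]
  t1 <- spec$truth_angles_t1
  t2 <- (t1 + delta) %% 180
  truth <- dplyr::bind_rows(
    dplyr::mutate(ep, timepoint = "t1", true_angle = t1),
    dplyr::mutate(ep, timepoint = "t2", true_angle = t2)
  )
  out_list <- NULL
  if (outlines) {
    shape_jitter <- withr::with_seed(spec$seed, {
      tibble(level = levels,
             width = 32 * exp(rnorm(n, 0, 0.05)),
             depth = 24 * exp(rnorm(n, 0, 0.05)))
    })
    out_list <- purrr::pmap(truth, function(level, side, timepoint,
                                            true_angle) {
      sj <- shape_jitter[shape_jitter$level == level, ]
      params <- if (side == "superior") {
        shape_params(body_width = sj$width, body_depth = sj$depth)
      } else {
        shape_params(body_width = sj$width, body_depth = sj$depth * 0.95,
                     pedicle_present = FALSE, posterior_flattening = 0.35)
      }
      generate_endplate_outline(
        params, true_angle,
        noise_sd_mm = spec$tracing_noise_sd_mm,
        seed = outline_seed(spec$seed, level, side, timepoint),
        patient = spec$patient, level = level, side = side,
        timepoint = timepoint)
    })
    names(out_list) <- paste(truth$level, truth$side, truth$timepoint,
                             sep = ".")
  }
  structure(list(patient = spec$patient, levels = levels,
                 instrumented_range = spec$instrumented_range,
                 apex = spec$apex, truth = truth, outlines = out_list,
                 rotations = NULL, spec = spec),
            class = "spine_study")
}

# deterministic per-endplate noise seed below 2^31
outline_seed <- function(seed, level, side, timepoint) {
  key <- paste(level, side, timepoint, sep = ".")
  h <- sum(utf8ToInt(key) * seq_along(utf8ToInt(key)))
  (as.integer(seed) * 7919L + as.integer(h)) %% 2147483587L
}

#' Ground-truth rotation table of a synthetic study
#'
#' Presents the study's true endplate angles in the same shape as a measured
#' rotation table, with every quality `"ok"`; running the rotation calculus
#' on it recovers the injected changes exactly.
#'
#' @param study A `spine_study`.
#' @return Tibble with columns `level`, `side`, `timepoint`, `phi`,
#'   `quality`.
#' @export
truth_rotations <- function(study) {
  stopifnot(inherits(study, "spine_study"))
  dplyr::transmute(study$truth,
                   level = .data$level, side = .data$side,
                   timepoint = .data$timepoint, phi = .data$true_angle,
                   quality = "ok")
}

study_rotation_table <- function(study) {
  if (!is.null(study$rotations)) study$rotations else truth_rotations(study)
}

#' Measure every endplate of a synthetic study through the imaging pipeline
#'
#' Rasterizes and measures each generated outline. The first timepoint is
#' measured without a prior; the second timepoint uses the first timepoint's
#' angle at the same endplate as the disambiguation prior, mirroring how an
#' analyst would resolve an ambiguous symmetry profile.
#'
#' @param study A `spine_study` generated with `outlines = TRUE`.
#' @param pixel_spacing Rasterization spacing in mm.
#' @param angle_step Angular step in degrees.
#' @param config A [symmetry_config()].
#' @return The study with its `rotations` element filled (tibble `level`,
#'   `side`, `timepoint`, `phi`, `quality`).
#' @export
measure_spine_study <- function(study, pixel_spacing = 0.4, angle_step = 0.1,
                                config = symmetry_config()) {
  stopifnot(inherits(study, "spine_study"))
  if (is.null(study$outlines)) {
    abort("study has no outlines; regenerate with `outlines = TRUE`.",
          class = "vertrot_usage_error")
  }
  measure_one <- function(key, prior) {
    m <- measure_endplate_rotation(study$outlines[[key]],
                                   pixel_spacing = pixel_spacing,
                                   angle_step = angle_step,
                                   prior_angle = prior, config = config)
    tibble(level = m$level, side = m$side, timepoint = m$timepoint,
           phi = m$phi, quality = m$quality)
  }
  ep <- unique(study$truth[, c("level", "side")])
  rows <- purrr::pmap(ep, function(level, side) {
    r1 <- measure_one(paste(level, side, "t1", sep = "."), prior = NULL)
    r2 <- measure_one(paste(level, side, "t2", sep = "."), prior = r1$phi)
    dplyr::bind_rows(r1, r2)
  })
  study$rotations <- dplyr::bind_rows(rows)
  study
}

#' @export
print.spine_study <- function(x, ...) {
  cat(sprintf(
    "<spine_study> %s: %s-%s (instrumented %s-%s, apex %s), %d endplates x 2 timepoints\n",
    x$patient, x$levels[1], x$levels[length(x$levels)],
    x$instrumented_range[1], x$instrumented_range[2], x$apex,
    2 * length(x$levels)))
  invisible(x)
}
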