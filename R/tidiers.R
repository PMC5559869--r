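#' Tidiers for vertrot result objects
#'
#' Broom-style accessors: `tidy()` returns the per-component table of an
#' object, `glance()` a one-row summary.
#'
#' @param x A `symmetry_profile`, `reliability_result`, `junction_summary` or
#'   `cohort_summary`.
#' @param ... Unused.
#' @return A tibble.
#' @name vertrot-tidiers
NULL

#' @rdname vertrot-tidiers
#' @export
tidy.symmetry_profile <- function(x, ...) {
  peaks <- attr(x, "peaks")
  if (is.null(peaks)) peaks <- tibble(angle = numeric(), ratio = numeric(),
                                      prominence = numeric())
  peaks
}

#' @rdname vertrot-tidiers
#' @export
glance.symmetry_profile <- function(x, ...) {
  peaks <- attr(x, "peaks")
  tibble(n_angles = nrow(x),
         angle_step = attr(x, "config")$angle_step,
         max_ratio = max(x$ratio),
         n_peaks = if (is.null(peaks)) 0L else nrow(peaks),
         ambiguous = isTRUE(attr(x, "ambiguous")))
}

#' @rdname vertrot-tidiers
#' @export
tidy.reliability_result <- function(x, ...) {
  tibble(pair = seq_along(x$delta_alpha), delta_alpha = x$delta_alpha)
}

#' @rdname vertrot-tidiers
#' @export
glance.reliability_result <- function(x, ...) {
  tibble(sd_intra = x$sd_intra, loa95 = x$loa95, n_pairs = x$n_pairs,
         method = x$method)
}

#' @rdname vertrot-tidiers
#' @export
tidy.junction_summary <- function(x, ...) {
  x$summary
}

#' @rdname vertrot-tidiers
#' @export
glance.junction_summary <- function(x, ...) {
  tibble(en_bloc = x$en_bloc, limit = x$limit)
}

#' @rdname vertrot-tidiers
#' @export
tidy.cohort_summary <- function(x, ...) {
  as_tibble(x$matrix)
}

#' @rdname vertrot-tidiers
#' @export
glance.cohort_summary <- function(x, ...) {
  tibble(n_patients = x$n_patients,
         n_excluded = x$exclusions$n_excluded,
         patients_with_significant_change =
           x$patients_with_significant_change,
         en_bloc = x$junctions$en_bloc,
         limit = x$limit)
}
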