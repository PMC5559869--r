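#' Intra-observer differences of repeated change measurements
#'
#' The absolute difference `|alpha_n - alpha_m|` between the two repeated
#' measurements of each inter-endplate rotation change, order-preserving.
#'
#' @param pairs Data frame with columns `alpha_n` and `alpha_m` (degrees), as
#'   produced by [generate_rater_pairs()] or read from a repeatability CSV.
#' @return Numeric vector of nonnegative differences in degrees.
#' @export
intra_observer_differences <- function(pairs) {
  if (is.null(pairs) || nrow(pairs) == 0) {
    abort("`pairs` is empty.", class = "vertrot_empty_input_error")
  }
  if (!all(c("alpha_n", "alpha_m") %in% names(pairs))) {
    abort("`pairs` must have columns `alpha_n` and `alpha_m`.",
          class = "vertrot_parameter_error")
  }
  abs(pairs$alpha_n - pairs$alpha_m)
}

#' Intra-observer 95% limits of agreement
#'
#' Bland-Altman-style repeatability limit used as the significance gate for
#' rotation changes: `loa95 = 1.96 * sd_intra`, where `sd_intra` is the
#' sample standard deviation of the intra-observer differences. The default
#' (`method = "absolute"`) takes the SD of the absolute differences
#' `|alpha_n - alpha_m|`; `method = "signed"` is the classical Bland-Altman
#' variant on the signed differences.
#'
#' @param delta_alpha Numeric vector of intra-observer differences in degrees
#'   (from [intra_observer_differences()]), or — when `method = "signed"` — of
#'   signed differences.
#' @param method `"absolute"` (default) or `"signed"`.
#' @return An object of class `reliability_result`: list with `sd_intra`,
#'   `loa95`, `n_pairs`, `method` and the input `delta_alpha`. Report with
#'   [glance()]; the conventional reporting precision is one decimal place
#'   (an SD of 4.2 degrees gates at 1.96 x 4.2 = 8.232, reported 8.2).
#' @export
#' @examples
#' res <- limits_of_agreement(c(2.1, 5.0, 0.4, 6.8, 3.9))
#' glance(res)
limits_of_agreement <- function(delta_alpha, method = c("absolute", "signed")) {
  method <- match.arg(method)
  delta_alpha <- as.numeric(delta_alpha)
  if (length(delta_alpha) < 2) {
    abort("at least 2 differences are required.",
          class = "vertrot_insufficient_data_error")
  }
  if (any(!is.finite(delta_alpha))) {
    abort("`delta_alpha` must be finite.", class = "vertrot_parameter_error")
  }
  if (method == "absolute" && any(delta_alpha < 0)) {
    abort("absolute differences must be nonnegative; use method = \"signed\" for signed differences.",
          class = "vertrot_parameter_error")
  }
  sd_intra <- sd(delta_alpha)
  structure(list(sd_intra = sd_intra, loa95 = 1.96 * sd_intra,
                 n_pairs = length(delta_alpha), method = method,
                 delta_alpha = delta_alpha),
            class = "reliability_result")
}

#' @export
print.reliability_result <- function(x, ...) {
  cat(sprintf(
    "<reliability_result> n = %d pairs (%s differences)\n  SD_intra = %.1f deg, 95%% limit of agreement = %.1f deg\n",
    x$n_pairs, x$method, x$sd_intra, x$loa95))
  invisible(x)
}

#' Analytic limit of agreement for Gaussian measurement noise
#'
#' For two independent measurements with per-measurement noise SD `sigma`,
#' the signed difference is `N(0, 2 sigma^2)` and the absolute difference is
#' half-normal, whose SD is `sqrt(2 sigma^2 (1 - 2 / pi))`. This closed form
#' is the recovery target for simulated rater pairs.
#'
#' @param sigma Per-measurement noise SD in degrees.
#' @param method `"absolute"` or `"signed"`, matching
#'   [limits_of_agreement()].
#' @return The analytic `loa95` in degrees.
#' @export
analytic_loa95 <- function(sigma, method = c("absolute", "signed")) {
  method <- match.arg(method)
  sd_intra <- if (method == "absolute") {
    sqrt(2 * sigma^2 * (1 - 2 / pi))
  } else {
    sqrt(2) * sigma
  }
  1.96 * sd_intra
}

#' Gate a table of rotation-change records by a limit of agreement
#'
#' Re-applies the significance rule (`|change| > loa95`, strict) across a
#' cohort's change records; loss-of-correction flags are unchanged. The
#' operation is idempotent and the significant count is non-increasing in the
#' limit.
#'
#' @param changes Tibble of change records (from [study_changes()] or
#'   [cohort_changes()]) with columns `change` and `direction_vs_apex`.
#' @param loa95 Positive limit in degrees.
#' @return `changes` with `significant` and `loss_of_correction` recomputed.
#' @export
gate_cohort <- function(changes, loa95) {
  cls <- classify_change(changes$change, changes$direction_vs_apex, loa95)
  changes$significant <- cls$significant
  changes$loss_of_correction <- cls$loss_of_correction
  changes
}
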