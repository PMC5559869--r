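#' Generate repeated-observer measurement pairs
#'
#' Simulates an intra-observer repeatability exercise: each underlying
#' inter-endplate rotation change is measured twice with independent
#' zero-mean Gaussian measurement noise, as when the same observer re-traces
#' and re-measures the same CT levels after a washout interval.
#'
#' @param base_changes Numeric vector of true underlying change values in
#'   degrees, one per measured level.
#' @param measurement_noise_sd SD in degrees of the per-measurement noise.
#' @param seed Integer seed; identical inputs reproduce the table exactly.
#' @param n_pairs Number of pairs; must equal `length(base_changes)` (kept as
#'   an explicit argument so mismatches fail loudly).
#' @return Tibble with columns `pair`, `base`, `alpha_n`, `alpha_m`.
#' @export
#' @examples
#' pairs <- generate_rater_pairs(c(2, -1, 5), measurement_noise_sd = 3, seed = 7)
#' limits_of_agreement(intra_observer_differences(pairs))
generate_rater_pairs <- function(base_changes, measurement_noise_sd,
                                 seed = 1L,
                                 n_pairs = length(base_changes)) {
  if (n_pairs != length(base_changes)) {
    abort("`n_pairs` must equal length(base_changes).",
          class = "vertrot_parameter_error")
  }
  if (n_pairs < 2) {
    abort("at least 2 pairs are required.",
          class = "vertrot_parameter_error")
  }
  if (measurement_noise_sd < 0) {
    abort("`measurement_noise_sd` must be >= 0.",
          class = "vertrot_parameter_error")
  }
  withr::with_seed(as.integer(seed), {
    tibble(pair = seq_len(n_pairs),
           base = base_changes,
           alpha_n = base_changes + rnorm(n_pairs, 0, measurement_noise_sd),
           alpha_m = base_changes + rnorm(n_pairs, 0, measurement_noise_sd))
  })
}
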