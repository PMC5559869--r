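#' Parameters of a synthetic vertebral-endplate cross-section
#'
#' Defines the parametric family used by the phantom generator: a superellipse
#' vertebral body with an optional posterior flattening (gated by
#' `asymmetry_strength`) and an optional pair of posterior pedicle lobes.
#' With `asymmetry_strength = 0` and `pedicle_present = FALSE` the body is a
#' pure superellipse with two perpendicular reflection-symmetry axes (the
#' degenerate, ambiguous case); turning on either the pedicles or the
#' asymmetry breaks the fore-aft mirror and leaves exactly one symmetry axis,
#' which is what makes the maximum-symmetry measurement well posed.
#'
#' @param body_width Mediolateral extent of the body in mm.
#' @param body_depth Anteroposterior extent of the body in mm.
#' @param posterior_flattening Relative depth of the posterior flattening,
#'   dimensionless in `[0, 1]`. Its effect is scaled by `asymmetry_strength`,
#'   so the flattening vanishes whenever `asymmetry_strength = 0`.
#' @param pedicle_present Whether to add the two posterior pedicle lobes.
#' @param pedicle_length Radial protrusion of each pedicle lobe in mm.
#' @param pedicle_width Mediolateral width of each pedicle lobe in mm.
#' @param asymmetry_strength Dimensionless gain (`>= 0`) on the fore-aft
#'   symmetry-breaking terms. `0` restores the two-axis superellipse.
#' @param squareness Superellipse exponent; `2` is an exact ellipse, larger
#'   values give the flatter-sided, more vertebra-like outline.
#' @param n_vertices Number of polygon vertices used when sampling the shape.
#'
#' @return An object of class `shape_params`.
#' @seealso [generate_endplate_outline()], [disc_shape_params()],
#'   [ellipse_shape_params()]
#' @export
#' @examples
#' p <- shape_params()
#' outline <- generate_endplate_outline(p, true_angle = 30)
shape_params <- function(body_width = 32,
                         body_depth = 24,
                         posterior_flattening = 0.25,
                         pedicle_present = TRUE,
                         pedicle_length = 7,
                         pedicle_width = 6,
                         asymmetry_strength = 1,
                         squareness = 2.5,
                         n_vertices = 256) {
  if (!is.numeric(body_width) || body_width <= 0 ||
      !is.numeric(body_depth) || body_depth <= 0) {
    abort("`body_width` and `body_depth` must be positive lengths in mm.",
          class = "vertrot_parameter_error")
  }
  if (posterior_flattening < 0 || posterior_flattening > 1) {
    abort("`posterior_flattening` must lie in [0, 1].",
          class = "vertrot_parameter_error")
  }
  if (asymmetry_strength < 0) {
    abort("`asymmetry_strength` must be >= 0.",
          class = "vertrot_parameter_error")
  }
  if (posterior_flattening * asymmetry_strength >= 0.9) {
    abort("posterior_flattening * asymmetry_strength must stay below 0.9 or the outline degenerates.",
          class = "vertrot_parameter_error")
  }
  if (isTRUE(pedicle_present) && (pedicle_length <= 0 || pedicle_width <= 0)) {
    abort("pedicle dimensions must be positive when `pedicle_present` is TRUE.",
          class = "vertrot_parameter_error")
  }
  if (squareness < 2) {
    abort("`squareness` must be >= 2.", class = "vertrot_parameter_error")
  }
  if (n_vertices < 16) {
    abort("`n_vertices` must be at least 16.", class = "vertrot_parameter_error")
  }
  structure(
    list(body_width = body_width, body_depth = body_depth,
         posterior_flattening = posterior_flattening,
         pedicle_present = isTRUE(pedicle_present),
         pedicle_length = pedicle_length, pedicle_width = pedicle_width,
         asymmetry_strength = asymmetry_strength,
         squareness = squareness, n_vertices = as.integer(n_vertices)),
    class = "shape_params"
  )
}

#' @rdname shape_params
#' @param diameter Diameter of the circular disc phantom in mm.
#' @export
disc_shape_params <- function(diameter = 28, n_vertices = 256) {
  shape_params(body_width = diameter, body_depth = diameter,
               posterior_flattening = 0, pedicle_present = FALSE,
               asymmetry_strength = 0, squareness = 2,
               n_vertices = n_vertices)
}

#' @rdname shape_params
#' @export
ellipse_shape_params <- function(body_width = 32, body_depth = 24,
                                 n_vertices = 256) {
  shape_params(body_width = body_width, body_depth = body_depth,
               posterior_flattening = 0, pedicle_present = FALSE,
               asymmetry_strength = 0, squareness = 2,
               n_vertices = n_vertices)
}

# Radius of the canonical (unrotated) cross-section along direction psi,
# where psi is measured clockwise from the anterior (+y) direction so the
# canonical symmetry axis is the y axis: r(psi) == r(-psi) always; the
# fore-aft mirror r(psi) == r(pi - psi) holds only when the flattening and
# pedicle terms vanish.
canonical_radius <- function(psi, params) {
  a <- params$body_width / 2
  b <- params$body_depth / 2
  n <- params$squareness
  s <- abs(sin(psi)) / a
  cpsi <- cos(psi)
  cc <- abs(cpsi) / b
  r0 <- (s^n + cc^n)^(-1 / n)
  # localized posterior flattening (the canal notch): a smooth radial dip
  # centred on the posterior midline. A localized dip (rather than a global
  # low-order modulation) is what actually disambiguates the mirror-overlap
  # ratio, because centroid-anchored reflection absorbs first-harmonic
  # (translation-like) radius changes.
  eff <- params$posterior_flattening * params$asymmetry_strength
  dpost <- (psi - pi + pi) %% (2 * pi) - pi
  r <- r0 * (1 - eff * exp(-0.5 * (dpost / 0.5)^2))
  if (params$pedicle_present) {
    sigma <- params$pedicle_width / (2 * b)
    for (centre in c(pi - 0.6, pi + 0.6)) {
      d <- (psi - centre + pi) %% (2 * pi) - pi
      r <- r + params$pedicle_length * exp(-0.5 * (d / sigma)^2)
    }
  }
  r
}
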