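#' Generate a synthetic endplate outline with known rotation
#'
#' Samples the parametric endplate cross-section of [shape_params()] as a
#' closed polygon, optionally perturbs its vertices with radial tracing noise
#' (emulating a manual polygonal trace), and rotates it so that its symmetry
#' axis lies at `true_angle`. Angles follow the package convention: degrees in
#' `[0, 180)`, measured clockwise (viewed from above) from the
#' anteroposterior reference direction, so `true_angle = 0` puts the symmetry
#' axis along the vertical image axis.
#'
#' @param params A [shape_params()] object.
#' @param true_angle Ground-truth axial rotation in degrees, `[0, 180)`.
#' @param centroid Numeric length-2, centre of the outline in mm.
#' @param noise_sd_mm Standard deviation (mm) of independent radial Gaussian
#'   perturbation of the vertices before resampling; `0` for a noise-free
#'   outline.
#' @param seed Integer seed for the tracing noise; required when
#'   `noise_sd_mm > 0` so outlines are reproducible.
#' @param patient,level,side,timepoint Optional identity metadata carried as
#'   attributes and into measurement results.
#'
#' @return A tibble of class `endplate_outline` with columns `x`, `y` (mm,
#'   open polygon, implicitly closed), and attributes `true_angle`,
#'   `centroid`, `params` and the identity metadata.
#' @export
#' @examples
#' o <- generate_endplate_outline(shape_params(), true_angle = 30)
#' polygon_area(o)
generate_endplate_outline <- function(params, true_angle,
                                      centroid = c(0, 0),
                                      noise_sd_mm = 0, seed = NULL,
                                      patient = NA_character_,
                                      level = NA_character_,
                                      side = NA_character_,
                                      timepoint = NA_character_) {
  if (!inherits(params, "shape_params")) {
    abort("`params` must be a shape_params object.",
          class = "vertrot_parameter_error")
  }
  if (!is.numeric(true_angle) || length(true_angle) != 1 ||
      true_angle < 0 || true_angle >= 180) {
    abort("`true_angle` must be a single angle in [0, 180) degrees.",
          class = "vertrot_parameter_error")
  }
  if (noise_sd_mm < 0) {
    abort("`noise_sd_mm` must be >= 0.", class = "vertrot_parameter_error")
  }
  n <- params$n_vertices
  psi <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  r <- canonical_radius(psi, params)
  if (noise_sd_mm > 0) {
    if (is.null(seed)) {
      abort("`seed` is required when `noise_sd_mm` > 0.",
            class = "vertrot_parameter_error")
    }
    r <- withr::with_seed(seed, r + rnorm(n, 0, noise_sd_mm))
    xy <- cbind(r * sin(psi), r * cos(psi))
    xy <- resample_polygon(xy, n)
  } else {
    xy <- cbind(r * sin(psi), r * cos(psi))
  }
  th <- true_angle * pi / 180
  rot <- cbind(xy[, 1] * cos(th) + xy[, 2] * sin(th),
               -xy[, 1] * sin(th) + xy[, 2] * cos(th))
  out <- tibble(x = rot[, 1] + centroid[1], y = rot[, 2] + centroid[2])
  structure(out,
            class = c("endplate_outline", class(out)),
            true_angle = true_angle, centroid = centroid, params = params,
            patient = patient, level = level, side = side,
            timepoint = timepoint)
}

# Resample a closed polygon (n x 2 matrix, open representation) to `n_out`
# vertices equally spaced in arc length, starting from the first vertex.
resample_polygon <- function(xy, n_out) {
  closed <- rbind(xy, xy[1, ])
  seg <- sqrt(diff(closed[, 1])^2 + diff(closed[, 2])^2)
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  target <- seq(0, total, length.out = n_out + 1)[-(n_out + 1)]
  cbind(approx(s, closed[, 1], xout = target)$y,
        approx(s, closed[, 2], xout = target)$y)
}

#' Rigidly rotate an endplate outline about its centroid
#'
#' Rotation is clockwise viewed from above, matching the angle convention, so
#' `measure_endplate_rotation(rotate_outline(o, d))` equals the measurement of
#' `o` shifted by `d` modulo 180.
#'
#' @param outline An `endplate_outline`.
#' @param delta Rotation in degrees (clockwise positive, viewed from above).
#' @return The rotated `endplate_outline`; its `true_angle` attribute is
#'   advanced by `delta` modulo 180.
#' @export
rotate_outline <- function(outline, delta) {
  c0 <- attr(outline, "centroid")
  th <- delta * pi / 180
  dx <- outline$x - c0[1]
  dy <- outline$y - c0[2]
  out <- outline
  out$x <- dx * cos(th) + dy * sin(th) + c0[1]
  out$y <- -dx * sin(th) + dy * cos(th) + c0[2]
  ta <- attr(outline, "true_angle")
  attr(out, "true_angle") <- if (is.null(ta)) NULL else (ta + delta) %% 180
  out
}

#' Shoelace area of a closed polygon
#'
#' @param outline An `endplate_outline` or any data frame with `x`, `y`
#'   columns describing a simple closed polygon (open representation).
#' @return Area in squared input units (mm^2 for outlines).
#' @export
polygon_area <- function(outline) {
  x <- outline$x
  y <- outline$y
  n <- length(x)
  j <- c(n, seq_len(n - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}

#' @export
print.endplate_outline <- function(x, ...) {
  cat(sprintf("<endplate_outline> %d vertices, true angle %s deg\n",
              nrow(x),
              formatC(attr(x, "true_angle"), format = "fg")))
  NextMethod()
}
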