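#' Generate a tilted 3D vertebra-like phantom volume
#'
#' Voxelizes a vertebra-like solid: the endplate cross-section of
#' [shape_params()], extruded along the endplate-plane normal, with the
#' endplate plane tilted away from the scanner axial plane by the given
#' frontal and sagittal angles and rotated in-plane by `true_angle`. The
#' in-plane rotation is defined relative to the projection of the scanner
#' anteroposterior axis into the endplate plane, so measuring the
#' reformatted true-axial slice recovers `true_angle`. Landmark points lying
#' exactly on the endplate plane are returned for plane fitting.
#'
#' @param params A [shape_params()] object.
#' @param true_angle In-plane rotation in degrees, `[0, 180)`.
#' @param tilt Numeric length 2: tilt of the endplate plane in degrees about
#'   the scanner y axis (frontal) and x axis (sagittal); each `|tilt| < 45`.
#' @param voxel_size Isotropic voxel size in mm; a resolution error is raised
#'   when it is too coarse to resolve the shape.
#' @param body_height Extrusion height of the solid in mm.
#' @param n_landmarks Number of endplate landmark points (>= 3).
#' @return A list of class `tilted_volume`: `volume` (3D 0/1 array, dims x,
#'   y, z), `voxel_size`, `origin_mm` (mm centre of voxel `[1,1,1]`),
#'   `landmarks` (tibble `x_mm`, `y_mm`, `z_mm`), `plane` (the ground-truth
#'   [fit_endplate_plane()]-style plane), `true_angle` and `params`.
#' @export
#' @examples
#' vol <- generate_tilted_volume(shape_params(), true_angle = 30,
#'                               tilt = c(15, 0), voxel_size = 1)
#' dim(vol$volume)
generate_tilted_volume <- function(params, true_angle, tilt = c(0, 0),
                                   voxel_size = 0.75, body_height = 16,
                                   n_landmarks = 8) {
  stopifnot(inherits(params, "shape_params"))
  if (any(abs(tilt) >= 45)) {
    abort("|tilt| components must be below 45 degrees.",
          class = "vertrot_parameter_error")
  }
  min_feature <- min(params$body_width, params$body_depth) / 8
  if (params$pedicle_present) {
    min_feature <- min(min_feature, params$pedicle_width / 2)
  }
  if (voxel_size > min_feature) {
    abort(sprintf("voxel_size %.2f mm too coarse to resolve the shape (needs <= %.2f mm).",
                  voxel_size, min_feature),
          class = "vertrot_resolution_error")
  }

  tf <- tilt[1] * pi / 180  # about scanner y (frontal)
  ts <- tilt[2] * pi / 180  # about scanner x (sagittal)
  rot_x <- function(a) matrix(c(1, 0, 0, 0, cos(a), sin(a),
                                0, -sin(a), cos(a)), 3, 3)
  rot_y <- function(a) matrix(c(cos(a), 0, -sin(a), 0, 1, 0,
                                sin(a), 0, cos(a)), 3, 3)
  nrm <- as.numeric(rot_y(tf) %*% rot_x(ts) %*% c(0, 0, 1))
  e2 <- c(0, 1, 0) - sum(c(0, 1, 0) * nrm) * nrm
  e2 <- e2 / sqrt(sum(e2^2))
  e1 <- cross3(e2, nrm)

  rmax <- max(canonical_radius(seq(0, 2 * pi, length.out = 720), params))
  ext <- rmax + body_height / 2 + 2 * voxel_size
  half <- ceiling(ext / voxel_size)
  coords <- (-half:half) * voxel_size
  nd <- length(coords)
  gx <- rep(coords, times = nd * nd)
  gy <- rep(rep(coords, each = nd), times = nd)
  gz <- rep(coords, each = nd * nd)

  s1 <- gx * e1[1] + gy * e1[2] + gz * e1[3]
  s2 <- gx * e2[1] + gy * e2[2] + gz * e2[3]
  s3 <- gx * nrm[1] + gy * nrm[2] + gz * nrm[3]
  th <- true_angle * pi / 180
  cu <- s1 * cos(th) - s2 * sin(th)
  cv <- s1 * sin(th) + s2 * cos(th)
  psi <- atan2(cu, cv)
  inside <- abs(s3) <= body_height / 2 &
    sqrt(cu^2 + cv^2) <= canonical_radius(psi, params)
  vol <- array(as.numeric(inside), dim = c(nd, nd, nd))

  # landmarks on the endplate plane (s3 = 0), within 60% of the body radius
  ang <- seq(0, 2 * pi, length.out = n_landmarks + 1)[-(n_landmarks + 1)]
  la <- 0.3 * params$body_width * cos(ang)
  lb <- 0.3 * params$body_depth * sin(ang)
  lm <- tibble(
    x_mm = la * e1[1] + lb * e2[1],
    y_mm = la * e1[2] + lb * e2[2],
    z_mm = la * e1[3] + lb * e2[3]
  )

  structure(list(volume = vol, voxel_size = voxel_size,
                 origin_mm = rep(coords[1], 3), landmarks = lm,
                 plane = structure(list(origin = c(0, 0, 0), normal = nrm,
                                        in_plane_reference = e2),
                                   class = "endplate_plane"),
                 true_angle = true_angle, params = params),
            class = "tilted_volume")
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
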