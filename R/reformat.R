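#' Fit an endplate plane through landmark points
#'
#' Least-squares plane through at least three non-collinear landmark points
#' (total least squares via SVD). The normal is oriented toward the cranial
#' (+z) direction, which fixes the viewed-from-above handedness of the
#' extracted slice; the in-plane reference is the normalized projection of
#' the scanner anteroposterior (+y) axis onto the plane, so in-plane angles
#' remain comparable across endplates.
#'
#' @param landmarks Data frame or matrix of landmark coordinates in mm;
#'   columns `x_mm`, `y_mm`, `z_mm` (or `x`, `y`, `z`, or three unnamed
#'   columns).
#' @return An object of class `endplate_plane`: list with unit-norm `normal`
#'   and `in_plane_reference` (orthogonal to within 1e-9) and `origin` (the
#'   landmark centroid).
#' @export
#' @examples
#' lm <- data.frame(x_mm = c(0, 10, 0, 10), y_mm = c(0, 0, 10, 10),
#'                  z_mm = c(5, 5, 5, 5))
#' fit_endplate_plane(lm)$normal
fit_endplate_plane <- function(landmarks) {
  pts <- landmark_matrix(landmarks)
  if (nrow(pts) < 3) {
    abort("at least 3 landmark points are required.",
          class = "vertrot_degenerate_geometry_error")
  }
  ctr <- colMeans(pts)
  centred <- sweep(pts, 2, ctr)
  sv <- svd(centred)
  if (sv$d[2] < max(sv$d[1], 1e-8) * 1e-7) {
    abort("landmark points are collinear; the plane is undefined.",
          class = "vertrot_degenerate_geometry_error")
  }
  nrm <- sv$v[, 3]
  if (nrm[3] < 0) nrm <- -nrm
  ap <- c(0, 1, 0)
  ref <- ap - sum(ap * nrm) * nrm
  nref <- sqrt(sum(ref^2))
  if (nref < 1e-8) {
    abort("the anteroposterior axis is parallel to the plane normal; the in-plane reference is undefined.",
          class = "vertrot_reference_undefined_error")
  }
  structure(list(origin = as.numeric(ctr), normal = as.numeric(nrm),
                 in_plane_reference = as.numeric(ref / nref)),
            class = "endplate_plane")
}

landmark_matrix <- function(landmarks) {
  if (is.matrix(landmarks)) return(landmarks[, 1:3, drop = FALSE])
  nm <- names(landmarks)
  cols <- if (all(c("x_mm", "y_mm", "z_mm") %in% nm)) {
    c("x_mm", "y_mm", "z_mm")
  } else if (all(c("x", "y", "z") %in% nm)) {
    c("x", "y", "z")
  } else {
    nm[1:3]
  }
  as.matrix(landmarks[, cols])
}

#' @export
print.endplate_plane <- function(x, ...) {
  cat(sprintf("<endplate_plane> normal (%.3f, %.3f, %.3f), AP reference (%.3f, %.3f, %.3f)\n",
              x$normal[1], x$normal[2], x$normal[3],
              x$in_plane_reference[1], x$in_plane_reference[2],
              x$in_plane_reference[3]))
  invisible(x)
}

#' Extract a true-axial slice in the plane of an endplate
#'
#' Resamples a 3D volume on the endplate plane by trilinear interpolation and
#' rebinarizes at 0.5, producing a slice in viewed-from-above orientation:
#' the slice y axis is the in-plane anteroposterior reference, the x axis
#' completes a right-handed frame with the cranial plane normal. Angles
#' measured on the slice relative to its y axis are therefore directly
#' comparable across endplates regardless of the plane's tilt.
#'
#' @param volume A `tilted_volume`, or a list with elements `volume` (3D
#'   array), `voxel_size` (mm) and `origin_mm` (mm centre of voxel
#'   `[1,1,1]`).
#' @param plane An `endplate_plane` from [fit_endplate_plane()].
#' @param field_of_view Side length of the square slice in mm.
#' @param pixel_spacing Slice pixel spacing in mm.
#' @return A `binary_endplate_image` centred on the plane origin; attribute
#'   `reference_direction` is the in-plane reference in slice pixel
#'   coordinates (always `c(0, 1)` by construction).
#' @export
extract_true_axial <- function(volume, plane, field_of_view = 80,
                               pixel_spacing = 0.5) {
  stopifnot(inherits(plane, "endplate_plane"))
  vol <- volume$volume
  vs <- volume$voxel_size
  org <- volume$origin_mm
  nrm <- plane$normal
  e2 <- plane$in_plane_reference
  e1 <- cross3(e2, nrm)
  npix <- max(3L, as.integer(round(field_of_view / pixel_spacing)))
  offs <- (seq_len(npix) - (npix + 1) / 2) * pixel_spacing
  a <- rep(offs, each = npix)   # x (e1), varies over columns
  b <- rep(offs, times = npix)  # y (e2), varies over rows
  px <- plane$origin[1] + a * e1[1] + b * e2[1]
  py <- plane$origin[2] + a * e1[2] + b * e2[2]
  pz <- plane$origin[3] + a * e1[3] + b * e2[3]
  vals <- trilinear_sample(vol, (px - org[1]) / vs + 1,
                           (py - org[2]) / vs + 1, (pz - org[3]) / vs + 1)
  mask <- matrix(vals >= 0.5, nrow = npix, ncol = npix)
  if (!any(mask)) {
    abort("the plane does not intersect the volume foreground.",
          class = "vertrot_empty_slice_error")
  }
  img <- binary_endplate_image(mask, pixel_spacing,
                               origin = c(offs[1], offs[1]))
  attr(img, "reference_direction") <- c(0, 1)
  attr(img, "plane") <- plane
  img
}

# Trilinear interpolation of a 3D array at continuous 1-based voxel indices;
# points outside the grid sample as 0.
trilinear_sample <- function(vol, ix, iy, iz) {
  d <- dim(vol)
  x0 <- floor(ix); y0 <- floor(iy); z0 <- floor(iz)
  fx <- ix - x0; fy <- iy - y0; fz <- iz - z0
  val <- numeric(length(ix))
  at <- function(x, y, z) {
    ok <- x >= 1 & x <= d[1] & y >= 1 & y <= d[2] & z >= 1 & z <= d[3]
    v <- numeric(length(x))
    if (any(ok)) {
      v[ok] <- vol[cbind(x[ok], y[ok], z[ok])]
    }
    v
  }
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) fx else 1 - fx) * (if (dy) fy else 1 - fy) *
      (if (dz) fz else 1 - fz)
    val <- val + w * at(x0 + dx, y0 + dy, z0 + dz)
  }
  val
}
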