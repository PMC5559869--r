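#' Serialize an endplate outline to JSON
#'
#' Writes the vertex list (mm `[x, y]` pairs) together with the identity
#' metadata and, for synthetic outlines, the ground-truth angle.
#'
#' @param outline An `endplate_outline`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_outline_json <- function(outline, path) {
  payload <- list(
    vertices = unname(as.matrix(outline[, c("x", "y")])),
    units = "mm",
    true_angle_deg = attr(outline, "true_angle"),
    centroid = attr(outline, "centroid"),
    patient = attr(outline, "patient"), level = attr(outline, "level"),
    side = attr(outline, "side"), timepoint = attr(outline, "timepoint")
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_outline_json
#' @export
read_outline_json <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- tibble(x = p$vertices[, 1], y = p$vertices[, 2])
  structure(out, class = c("endplate_outline", class(out)),
            true_angle = p$true_angle_deg,
            centroid = as.numeric(p$centroid),
            patient = p$patient %||% NA_character_,
            level = p$level %||% NA_character_,
            side = p$side %||% NA_character_,
            timepoint = p$timepoint %||% NA_character_)
}

#' Write a binary endplate image as PNG with a JSON sidecar
#'
#' The PNG stores the mask (foreground white); the sidecar
#' (`<path>.json`) stores the pixel spacing, origin and in-plane reference
#' direction, without which the image is not interpretable in mm.
#'
#' @param image A `binary_endplate_image`.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(image, path) {
  # PNG rows run top-to-bottom; our rows run bottom-to-top (anterior up)
  png::writePNG(1 * image$mask[nrow(image$mask):1, , drop = FALSE], path)
  sidecar <- list(pixel_spacing_mm = image$pixel_spacing,
                  origin_mm = image$origin,
                  reference_direction =
                    attr(image, "reference_direction") %||% c(0, 1))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_mask_png
#' @export
read_mask_png <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  sidecar <- jsonlite::read_json(paste0(path, ".json"),
                                 simplifyVector = TRUE)
  img <- binary_endplate_image(m[nrow(m):1, , drop = FALSE] > 0.5,
                               sidecar$pixel_spacing_mm,
                               origin = sidecar$origin_mm)
  attr(img, "reference_direction") <- sidecar$reference_direction
  img
}

#' Per-endplate rotation table I/O
#'
#' Long CSV with one row per endplate measurement: `patient`, `level`,
#' `side`, `timepoint`, `phi_deg`, `quality`.
#'
#' @param rotations Tibble with columns `patient` (optional), `level`,
#'   `side`, `timepoint`, `phi`, `quality`.
#' @param path CSV path.
#' @return `path` / the tibble, invisibly for the writer.
#' @export
write_endplate_csv <- function(rotations, path) {
  df <- as.data.frame(rotations)
  names(df)[names(df) == "phi"] <- "phi_deg"
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_endplate_csv
#' @export
read_endplate_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(df)[names(df) == "phi_deg"] <- "phi"
  as_tibble(df)
}

#' Change-record table I/O
#'
#' Long CSV of rotation-change records (`patient`, `level_key`, `kind`,
#' `value_t1`, `value_t2`, `change`, `significant`, `loss_of_correction`,
#' ...).
#'
#' @param changes Change-record tibble.
#' @param path CSV path.
#' @return `path` / the tibble.
#' @export
write_changes_csv <- function(changes, path) {
  utils::write.csv(as.data.frame(changes), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_changes_csv
#' @export
read_changes_csv <- function(path) {
  as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Volume I/O in NIfTI format
#'
#' @param volume A `tilted_volume` (or list with `volume`, `voxel_size`).
#' @param path Output `.nii`/`.nii.gz` path.
#' @return `path` / a list with `volume`, `voxel_size`, `origin_mm`.
#' @export
write_volume_nifti <- function(volume, path) {
  img <- RNifti::asNifti(volume$volume)
  RNifti::pixdim(img) <- rep(volume$voxel_size, 3)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume_nifti
#' @param origin_mm Millimetre position of voxel `[1,1,1]` to restore (the
#'   generator's origin is not stored in the NIfTI header by this writer).
#' @export
read_volume_nifti <- function(path, origin_mm = NULL) {
  img <- RNifti::readNifti(path)
  vs <- RNifti::pixdim(img)[1]
  arr <- array(as.numeric(img), dim = dim(img))
  if (is.null(origin_mm)) {
    half <- (dim(arr) - 1) / 2
    origin_mm <- -half * vs
  }
  list(volume = arr, voxel_size = vs, origin_mm = origin_mm)
}

#' Landmark table I/O (CSV with x_mm, y_mm, z_mm)
#'
#' @param landmarks Tibble with `x_mm`, `y_mm`, `z_mm`.
#' @param path CSV path.
#' @return `path` / the tibble.
#' @export
write_landmarks_csv <- function(landmarks, path) {
  utils::write.csv(as.data.frame(landmarks), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_landmarks_csv
#' @export
read_landmarks_csv <- function(path) {
  as_tibble(utils::read.csv(path))
}
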