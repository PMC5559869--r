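#' Plot a symmetry-ratio profile
#'
#' The symmetry ratio against candidate axis angle, with detected peaks
#' marked; the measurement's diagnostic curve, on which ambiguous profiles
#' show two or more near-maximal peaks.
#'
#' @param object A `symmetry_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.symmetry_profile <- function(object, ...) {
  peaks <- attr(object, "peaks")
  p <- ggplot2::ggplot(as_tibble(object),
                       ggplot2::aes(x = .data$angle, y = .data$ratio)) +
    ggplot2::geom_line(colour = "grey30") +
    ggplot2::labs(x = "candidate axis angle (deg)",
                  y = "symmetry ratio",
                  title = if (isTRUE(attr(object, "ambiguous"))) {
                    "Symmetry profile (ambiguous)"
                  } else {
                    "Symmetry profile"
                  }) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::theme_minimal()
  if (!is.null(peaks) && nrow(peaks)) {
    p <- p +
      ggplot2::geom_vline(xintercept = peaks$angle, colour = "red",
                          linetype = "dashed", alpha = 0.6) +
      ggplot2::geom_point(data = peaks, colour = "red", size = 2)
  }
  p
}

#' Plot an endplate outline
#'
#' @param object An `endplate_outline`.
#' @param ... Unused.
#' @return A ggplot object showing the closed trace with the anteroposterior
#'   reference (vertical) and, when known, the true symmetry axis.
#' @export
autoplot.endplate_outline <- function(object, ...) {
  df <- as_tibble(object)
  df <- rbind(df, df[1, ])
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm, anterior up)") +
    ggplot2::theme_minimal()
  ta <- attr(object, "true_angle")
  if (!is.null(ta) && !is.na(ta)) {
    ctr <- attr(object, "centroid")
    r <- max(abs(df$x - ctr[1]), abs(df$y - ctr[2]))
    th <- ta * pi / 180
    ax <- tibble(x = ctr[1] + c(-1, 1) * r * sin(th),
                 y = ctr[2] + c(-1, 1) * r * cos(th))
    p <- p + ggplot2::geom_line(data = ax, colour = "red",
                                linetype = "dashed")
  }
  p
}

#' Heat-matrix plot of cohort rotation changes
#'
#' The level-by-patient grid of rotation changes: fill encodes the signed
#' change, significant cells are outlined, instrumented levels are marked.
#'
#' @param object A `cohort_matrix` from [build_change_matrix()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cohort_matrix <- function(object, ...) {
  df <- as_tibble(object)
  df$level_key <- factor(df$level_key,
                         levels = rev(unique(df$level_key[
                           order(level_key_rank(df$level_key))])))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$patient, y = .data$level_key,
                                   fill = .data$change)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::geom_tile(data = df[which(df$significant), , drop = FALSE],
                       colour = "black", linewidth = 0.8, fill = NA) +
    ggplot2::geom_point(data = df[df$instrumented, , drop = FALSE],
                        shape = 20, size = 0.5, colour = "grey40") +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", midpoint = 0,
                                  name = "change (deg)") +
    ggplot2::labs(x = "patient", y = NULL,
                  title = "Inter/intra-vertebral rotation changes") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x =
                     ggplot2::element_text(angle = 90, vjust = 0.5))
}
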