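#' Topographic scalp map of a per-channel value
#'
#' Interpolates channel values over the 2D projection of the scalp
#' (azimuthal projection of the unit-sphere electrode positions) by
#' inverse-distance weighting and draws the map with the bipolar
#' convention: deficits blue, excesses red, white at zero.  The
#' interpolation is deterministic, so a map regenerates identically from
#' the same table.
#'
#' @param values named numeric vector (names = channel labels).
#' @param montage an [eeg_montage] or built-in name.
#' @param title plot title.
#' @param resolution interpolation grid resolution (default 64).
#' @param power inverse-distance weighting exponent (default 2).
#' @return A ggplot object.
#' @export
plot_topomap <- function(values, montage = "10-20-19", title = NULL,
                         resolution = 64L, power = 2) {
  if (is.character(montage)) montage <- load_montage(montage)
  idx <- match(tolower(names(values)), tolower(montage$labels))
  if (anyNA(idx))
    stop("montage is missing electrode(s): ",
         paste(names(values)[is.na(idx)], collapse = ", "), call. = FALSE)
  pos <- montage$positions[idx, , drop = FALSE]
  # azimuthal projection: radius = polar angle from +z (Cz at the center)
  th <- acos(pmin(pmax(pos[, 3], -1), 1))
  ph <- atan2(pos[, 2], pos[, 1])
  ex <- th / (pi / 2) * cos(ph)
  ey <- th / (pi / 2) * sin(ph)
  gx <- seq(-1.05, 1.05, length.out = resolution)
  gr <- expand.grid(x = gx, y = gx)
  keep <- gr$x^2 + gr$y^2 <= 1.05^2
  gr <- gr[keep, ]
  d2 <- outer(gr$x, ex, "-")^2 + outer(gr$y, ey, "-")^2
  w <- 1 / (d2^(power / 2) + 1e-9)
  gr$value <- as.vector((w %*% values) / rowSums(w))
  lim <- max(abs(values), 1e-12)
  ggplot2::ggplot(gr, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                                  limits = c(-lim, lim)) +
    ggplot2::annotate("point", x = ex, y = ey, size = 1) +
    ggplot2::annotate("text", x = ex, y = ey + 0.07,
                      label = names(values), size = 2.5) +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = title, fill = NULL) +
    ggplot2::theme_void()
}

#' Heatmap of a z-map (location by frequency)
#'
#' @param object a [z_maps] object.
#' @param ... unused.
#' @return A ggplot object with the bipolar palette; suprathreshold
#'   entries, when a corrected threshold is present, are outlined.
#' @method autoplot z_maps
#' @export
autoplot.z_maps <- function(object, ...) {
  df <- tidy(object)
  lim <- max(abs(df$z), 1e-12)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$frequency, y = .data$location,
                                        fill = .data$z)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                                  limits = c(-lim, lim)) +
    ggplot2::labs(x = "frequency (Hz)", y = NULL, fill = "z")
  if (!is.null(object$threshold) && any(df$significant))
    p <- p + ggplot2::geom_tile(data = df[df$significant, ],
                                colour = "black", linewidth = 0.4)
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
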