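#' Tidy a displacement grid
#'
#' @param x A [displacement_grid()].
#' @param ... Unused.
#' @return Tibble with one row per mesh node.
#' @export
tidy.displacement_grid <- function(x, ...) {
  as_tibble(x) |> mutate(magnitude = sqrt(.data$ux^2 + .data$uy^2 + .data$uz^2))
}

#' Summarise a displacement grid
#'
#' @param x A [displacement_grid()].
#' @param ... Unused.
#' @return One-row tibble: node counts, untracked fraction, median quality,
#'   peak displacement magnitude (micrometres).
#' @export
glance.displacement_grid <- function(x, ...) {
  mag <- sqrt(x$ux^2 + x$uy^2 + x$uz^2)
  tibble(n_nodes = nrow(x), n_untracked = sum(x$untracked),
         frac_untracked = mean(x$untracked),
         median_quality = median(x$quality[!x$untracked]),
         peak_magnitude = max(mag))
}

#' Tidy a traction field
#'
#' @param x A [traction_field()].
#' @param ... Unused.
#' @return Tibble with node indices, traction components and magnitude (Pa).
#' @export
tidy.traction_field <- function(x, ...) {
  md <- x$mesh_dims
  grid <- expand.grid(i = seq_len(md[1]), j = seq_len(md[2]),
                      k = seq_len(md[3]))
  tibble(i = grid$i, j = grid$j, k = grid$k,
         Tx = c(x$Tx), Ty = c(x$Ty), Tz = c(x$Tz),
         magnitude = c(x$magnitude))
}

#' Summarise a traction field
#'
#' @param x A [traction_field()].
#' @param ... Unused.
#' @return One-row tibble: peak, mean and 95th-percentile traction (Pa).
#' @export
glance.traction_field <- function(x, ...) {
  m <- c(x$magnitude)
  tibble(peak_Pa = max(m), mean_Pa = mean(m),
         p95_Pa = as.numeric(quantile(m, 0.95)))
}

#' Tidy a mitochondrial segmentation
#'
#' @param x A `mito_segmentation`.
#' @param ... Unused.
#' @return The per-object tibble (label, area, perimeter, circularity).
#' @export
tidy.mito_segmentation <- function(x, ...) x$objects

#' Summarise a mitochondrial segmentation
#'
#' @param x A `mito_segmentation`.
#' @param ... Unused.
#' @return One-row tibble: object count, median area and circularity.
#' @export
glance.mito_segmentation <- function(x, ...) {
  tibble(n_objects = nrow(x$objects),
         median_area = if (nrow(x$objects)) median(x$objects$area) else NA_real_,
         median_circularity = if (nrow(x$objects)) {
           median(x$objects$circularity)
         } else NA_real_)
}

#' Tidy a spectra matrix
#'
#' @param x A [spectra_matrix()].
#' @param ... Unused.
#' @return Long tibble: `sample`, `ppm`, `intensity`.
#' @export
tidy.spectra_matrix <- function(x, ...) {
  tibble(sample = rep(seq_len(nrow(x$X)), each = ncol(x$X)),
         ppm = rep(x$ppm_axis, times = nrow(x$X)),
         intensity = c(t(x$X)))
}

#' Summarise a spectra matrix
#'
#' @param x A [spectra_matrix()].
#' @param ... Unused.
#' @return One-row tibble: sample/point counts, state, dilution-factor range.
#' @export
glance.spectra_matrix <- function(x, ...) {
  tibble(n_samples = nrow(x$X), n_points = ncol(x$X), state = x$state,
         min_dilution = if (is.null(x$dilution_factors)) NA_real_
                        else min(x$dilution_factors),
         max_dilution = if (is.null(x$dilution_factors)) NA_real_
                        else max(x$dilution_factors))
}

#' Plot a rendered traction map
#'
#' @param object A `traction_map` from [render_stress_map()].
#' @param ... Unused.
#' @return A ggplot: jet-coloured traction magnitude with a Pa colour bar.
#' @export
autoplot.traction_map <- function(object, ...) {
  df <- tidyr::expand_grid(x = seq_len(nrow(object$values)),
                           y = seq_len(ncol(object$values)))
  df$traction <- c(object$values)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$traction)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradientn(colours = object$palette,
                                  limits = c(0, max(object$scale_max, 1e-12)),
                                  name = "|T| (Pa)") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (node)", y = "y (node)") +
    ggplot2::theme_minimal()
}

#' Plot a spectra matrix
#'
#' @param object A [spectra_matrix()].
#' @param ... Unused.
#' @return A ggplot of intensity vs chemical shift, one line per sample,
#'   ppm axis reversed as conventional for NMR.
#' @export
autoplot.spectra_matrix <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$ppm, .data$intensity,
                                   colour = factor(.data$sample))) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(colour = "sample", x = "chemical shift (ppm)",
                  y = "intensity") +
    ggplot2::theme_minimal()
}

#' Plot a displacement grid as in-plane vectors
#'
#' @param object A [displacement_grid()].
#' @param slice_k Mesh z layer to draw (default 1).
#' @param ... Unused.
#' @return A ggplot quiver-style plot of (ux, uy) over the mesh.
#' @export
autoplot.displacement_grid <- function(object, slice_k = 1, ...) {
  df <- tidy(object) |> filter(.data$k == slice_k)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$x + .data$ux,
                                       yend = .data$y + .data$uy,
                                       colour = .data$magnitude),
                          arrow = ggplot2::arrow(length = ggplot2::unit(2, "pt"))) +
    ggplot2::scale_colour_viridis_c(name = "|u| (um)") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (voxel)", y = "y (voxel)") +
    ggplot2::theme_minimal()
}
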