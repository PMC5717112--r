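# Display helpers: maximum intensity projections and p-value map overlays.

#' Plot a maximum intensity projection of a volume
#'
#' @param volume 3D numeric array.
#' @param axis projection axis (default 2, the sagittal-like direction for
#'   the phantom orientation).
#' @param spacing voxel spacing in mm (for axis scaling).
#' @param title plot title.
#' @return a ggplot object.
#' @export
plot_mip <- function(volume, axis = 2, spacing = c(1, 1, 1), title = NULL) {
  mip <- maximum_intensity_projection(volume, axis)
  axes <- setdiff(1:3, axis)
  df <- expand.grid(
    u = (seq_len(nrow(mip)) - 1) * spacing[axes[1]],
    v = (seq_len(ncol(mip)) - 1) * spacing[axes[2]]
  )
  df$value <- as.vector(mip)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$u, y = .data$v,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = NULL) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = sprintf("axis %d (mm)", axes[1]),
                  y = sprintf("axis %d (mm)", axes[2]), title = title) +
    ggplot2::theme_minimal()
}

#' Autoplot a WSS map
#'
#' Wall points colored by |WSS|, projected on two axes.
#'
#' @param object \code{wss_map}.
#' @param axes which two coordinate axes to display.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.wss_map <- function(object, axes = c(1, 3), ...) {
  coords <- list(object$x, object$y, object$z)
  df <- tibble::tibble(u = coords[[axes[1]]], v = coords[[axes[2]]],
                       wss = object$wss_mag)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$u, y = .data$v,
                                   color = .data$wss)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_color_viridis_c(name = "|WSS| (Pa)") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = sprintf("axis %d (mm)", axes[1]),
                  y = sprintf("axis %d (mm)", axes[2])) +
    ggplot2::theme_minimal()
}

#' Significance overlay of a volumetric p-value map
#'
#' Projects the signed significance (+1 where cohort B is larger, -1 where
#' cohort A is larger) through the shared geometry.
#'
#' @param pmap \code{pvalue_map} computed on the voxel domain.
#' @param shared \code{shared_geometry} the map lives on.
#' @param axis projection axis.
#' @return a ggplot object.
#' @export
plot_pvalue_mip <- function(pmap, shared, axis = 2) {
  vol <- array(0, dim(shared$mask$data))
  loc <- which(shared$mask$data)
  sig <- pmap$significant & !is.na(pmap$direction)
  vol[loc[sig]] <- pmap$direction[sig]
  pos <- maximum_intensity_projection(vol, axis)
  neg <- -maximum_intensity_projection(-vol, axis)
  signed <- ifelse(pos > 0, pos, neg)
  axes <- setdiff(1:3, axis)
  sp <- shared$mask$spacing
  df <- expand.grid(
    u = (seq_len(nrow(signed)) - 1) * sp[axes[1]],
    v = (seq_len(ncol(signed)) - 1) * sp[axes[2]]
  )
  df$direction <- factor(as.vector(signed), levels = c(-1, 0, 1),
                         labels = c("A higher", "n.s.", "B higher"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$u, y = .data$v,
                                   fill = .data$direction)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = c("A higher" = "#2166ac",
                                          "n.s." = "grey90",
                                          "B higher" = "#b2182b"),
                               name = NULL) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = sprintf("axis %d (mm)", axes[1]),
                  y = sprintf("axis %d (mm)", axes[2])) +
    ggplot2::theme_minimal()
}
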