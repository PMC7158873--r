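#' Plot one slice of a volume
#'
#' @param vol a `vol3d` (scalar map, mask or visitation map).
#' @param slice slice index along `axis` (default: middle slice).
#' @param axis voxel axis to slice along (1, 2 or 3).
#' @return a ggplot object.
#' @export
plot_volume_slice <- function(vol, slice = NULL, axis = 3) {
  d <- dim(vol$data)
  if (is.null(slice)) slice <- ceiling(d[axis] / 2)
  sl <- switch(axis, vol$data[slice, , ], vol$data[, slice, ],
               vol$data[, , slice])
  df <- tidyr::expand_grid(i = seq_len(nrow(sl)), j = seq_len(ncol(sl)))
  df$value <- as.vector(sl)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$i, y = .data$j,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = paste0("slice ", slice, " (axis ", axis, ")"),
                  x = NULL, y = NULL)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Per-slice disconnection profile
#'
#' Plots the overlap fraction against slice index, marking the maximising
#' slice that defines the score.
#'
#' @param object a `disconnection_result` from [overlap_score()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.disconnection_result <- function(object, ...) {
  df <- object$profile
  ggplot2::ggplot(df, ggplot2::aes(x = .data$slice, y = .data$fraction)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$argmax_slice, linetype = 2) +
    ggplot2::labs(y = paste0("overlap fraction (", object$mode, ")"),
                  x = "coronal slice",
                  title = sprintf("disconnection score %.3f at slice %d",
                                  object$score, object$argmax_slice))
}

#' Arrow-table plot of a significance sign pattern
#'
#' @param pattern a tibble from [sign_pattern()].
#' @return a ggplot object.
#' @export
plot_sign_pattern <- function(pattern) {
  ggplot2::ggplot(pattern,
                  ggplot2::aes(x = .data$effect, y = .data$metric,
                               fill = .data$call)) +
    ggplot2::geom_tile(color = "grey30") +
    ggplot2::geom_text(ggplot2::aes(label = .data$symbol), size = 6) +
    ggplot2::scale_fill_manual(values = c(up = "#d7736c", down = "#6c8ed7",
                                          none = "grey90")) +
    ggplot2::labs(x = NULL, y = NULL, fill = NULL)
}
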