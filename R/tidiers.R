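#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a run into long format
#'
#' One row per frame and ROI: `frame`, `time_s`, `roi`, `mean_intensity`,
#' `relocated`. Convenient for dplyr/ggplot2 work on the traces.
#'
#' @param x a `polaroi_run`.
#' @param ... unused.
#' @return A long tibble.
#' @export
tidy.polaroi_run <- function(x, ...) {
  tidyr::pivot_longer(
    x$traces,
    cols = dplyr::starts_with("roi_"),
    names_to = "roi", names_prefix = "roi_",
    values_to = "mean_intensity"
  )
}

#' One-row summary of a run
#'
#' @param x a `polaroi_run`.
#' @param ... unused.
#' @return Tibble with `n_frames`, `n_soma_rois`, `angle_deg`, `threshold`,
#'   `n_relocations`, `n_layouts`.
#' @export
glance.polaroi_run <- function(x, ...) {
  tibble::tibble(
    n_frames = nrow(x$traces),
    n_soma_rois = sum(grepl("^roi_soma_", names(x$traces))),
    angle_deg = x$layouts[[1L]]$orientation$angle_deg,
    threshold = x$layouts[[1L]]$threshold,
    n_relocations = sum(x$traces$relocated),
    n_layouts = length(x$layouts)
  )
}

#' Plot the extracted traces
#'
#' Mean intensity per ROI over time, one colored line per ROI, with
#' relocation events marked by vertical dashed lines.
#'
#' @param object a `polaroi_run`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.polaroi_run <- function(object, ...) {
  long <- tidy.polaroi_run(object)
  p <- ggplot2::ggplot(long, ggplot2::aes(
    x = .data$time_s, y = .data$mean_intensity, colour = .data$roi
  )) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "mean ROI intensity (a.u.)",
                  colour = "ROI") +
    ggplot2::theme_minimal()
  reloc <- object$traces$time_s[object$traces$relocated]
  if (length(reloc) > 0) {
    p <- p + ggplot2::geom_vline(xintercept = reloc, linetype = "dashed",
                                 colour = "grey40")
  }
  p
}

#' Plot an ROI layout over a frame
#'
#' Renders a (rotated) frame as a grayscale raster with the ROI rectangles
#' outlined: process, soma ROIs and background in distinct colors.
#'
#' @param object an `roi_layout`.
#' @param frame optional rotated frame matrix to use as the backdrop.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.roi_layout <- function(object, frame = NULL, ...) {
  rois <- dplyr::mutate(
    object$rois,
    label = ifelse(.data$role == "soma", paste0("soma_", .data$order), .data$role)
  )
  p <- ggplot2::ggplot()
  if (!is.null(frame)) {
    df <- tidyr::expand_grid(row = seq_len(nrow(frame)), col = seq_len(ncol(frame)))
    df$value <- as.vector(t(frame))
    p <- p + ggplot2::geom_raster(
      data = df, ggplot2::aes(x = .data$col, y = .data$row, fill = .data$value)
    ) +
      ggplot2::scale_fill_gradient(low = "black", high = "white", guide = "none")
  }
  p +
    ggplot2::geom_rect(
      data = rois,
      ggplot2::aes(xmin = .data$left - 0.5, xmax = .data$left + .data$width - 0.5,
                   ymin = .data$top - 0.5, ymax = .data$top + .data$height - 0.5,
                   colour = .data$label),
      fill = NA, linewidth = 0.6
    ) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "column", y = "row", colour = "ROI") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
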