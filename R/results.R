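#' Write the per-frame results table to CSV
#'
#' Header: `frame,time_s,roi_process,roi_soma_1..m,roi_background,relocated`,
#' one row per frame (`frame` is 0-based), UTF-8, comma separator, "."
#' decimal. Reading the file back with [read_results()] reproduces the table
#' exactly for the integer/logical columns and to full printed precision for
#' the reals.
#'
#' @param x a `polaroi_run` or its `traces` tibble.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_results <- function(x, path) {
  traces <- if (inherits(x, "polaroi_run")) x$traces else tibble::as_tibble(x)
  if (nrow(traces) == 0L) stage_stop("tiffio", "results table is empty")
  readr::write_csv(traces, path)
  invisible(path)
}

#' Read a results table written by [write_results()]
#'
#' @param path CSV path.
#' @return The traces tibble.
#' @export
read_results <- function(path) {
  readr::read_csv(
    path,
    col_types = readr::cols(
      frame = readr::col_integer(),
      relocated = readr::col_logical(),
      .default = readr::col_double()
    )
  )
}

# Map a point from rotated-canvas coordinates back onto the original frame.
unrotate_point <- function(r, cc, angle_deg, frame_shape, canvas_shape) {
  th <- angle_deg * pi / 180
  co <- cos(th); si <- sin(th)
  cy <- (frame_shape[1L] + 1) / 2; cx <- (frame_shape[2L] + 1) / 2
  ncy <- (canvas_shape[1L] + 1) / 2; ncx <- (canvas_shape[2L] + 1) / 2
  dr <- r - ncy; dc <- cc - ncx
  cbind(cy + co * dr + si * dc, cx - si * dr + co * dc)
}

draw_segment <- function(img, p0, p1, col_rgb) {
  n <- max(2L, ceiling(max(abs(p1 - p0))) * 2L)
  t <- seq(0, 1, length.out = n)
  rrc <- p0[1L] + t * (p1[1L] - p0[1L])
  ccc <- p0[2L] + t * (p1[2L] - p0[2L])
  h <- dim(img)[1L]; w <- dim(img)[2L]
  # points on the half-pixel rectangle boundary are clamped into the frame;
  # only genuinely out-of-frame points are dropped
  keep <- rrc >= 0.5 & rrc <= h + 0.5 & ccc >= 0.5 & ccc <= w + 0.5
  if (!all(keep)) warning("ROI outline clipped at the frame border")
  rr <- pmin(pmax(round(rrc[keep]), 1L), h)
  cc <- pmin(pmax(round(ccc[keep]), 1L), w)
  if (length(rr) == 0L) return(img)
  for (ch in 1:3) img[cbind(rr, cc, ch)] <- col_rgb[ch]
  img
}

#' Save an ROI overlay image
#'
#' Renders the *original* (unrotated) frame as grayscale and draws each ROI
#' rectangle, mapped back to original-image coordinates through the inverse
#' of the saved rotation, in a role-specific color (process red, soma greens,
#' background blue). Written as PNG. Rectangles partly outside the frame are
#' clipped with a warning.
#'
#' @param frame original frame matrix.
#' @param layout an `roi_layout` built for that frame geometry.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_overlay <- function(frame, layout, path) {
  assert_frame(frame)
  rng <- range(frame)
  g <- if (diff(rng) == 0) frame * 0 else (frame - rng[1L]) / diff(rng)
  img <- array(rep(g, 3L), dim = c(dim(frame), 3L))
  n_soma <- max(1L, sum(layout$rois$role == "soma"))
  soma_cols <- grDevices::col2rgb(grDevices::hcl.colors(n_soma, "Greens 3"))[, , drop = FALSE] / 255
  angle <- layout$orientation$angle_deg
  for (i in seq_len(nrow(layout$rois))) {
    roi <- layout$rois[i, ]
    col_rgb <- switch(roi$role,
      process = c(1, 0, 0),
      background = c(0, 0.4, 1),
      soma = soma_cols[, min(roi$order, ncol(soma_cols))]
    )
    corners <- rbind(
      c(roi$top - 0.5, roi$left - 0.5),
      c(roi$top - 0.5, roi$left + roi$width - 0.5),
      c(roi$top + roi$height - 0.5, roi$left + roi$width - 0.5),
      c(roi$top + roi$height - 0.5, roi$left - 0.5)
    )
    orig <- unrotate_point(corners[, 1L], corners[, 2L], angle,
                           dim(frame), layout$canvas_shape)
    for (e in 1:4) {
      img <- draw_segment(img, orig[e, ], orig[e %% 4L + 1L, ], col_rgb)
    }
  }
  png::writePNG(img, path)
  invisible(path)
}
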