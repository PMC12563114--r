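roi_row <- function(role, order, top, left, height, width) {
  tibble::tibble(role = role, order = as.integer(order), top = as.integer(top),
                 left = as.integer(left), height = as.integer(height),
                 width = as.integer(width))
}

roi_pixels <- function(frame, roi) {
  frame[roi$top:(roi$top + roi$height - 1L),
        roi$left:(roi$left + roi$width - 1L)]
}

assert_roi_in_frame <- function(roi, shape, stage = "roimaker") {
  if (any(roi$top < 1L) || any(roi$left < 1L) ||
      any(roi$top + roi$height - 1L > shape[1L]) ||
      any(roi$left + roi$width - 1L > shape[2L])) {
    stage_stop(stage, "ROI outside frame bounds")
  }
  invisible(roi)
}

#' Locate the soma/process boundary in a column profile
#'
#' The boundary is the intensity gap between soma and process: the argmin of
#' the profile strictly between the two maxima (leftmost column on ties).
#' When the stretch between the maxima is flat (no value below both peak
#' heights) there is no gap; the midpoint between the maxima is used and the
#' result is flagged low-confidence. The process span runs from the column
#' right of the boundary to the rightmost column with any foreground.
#'
#' @param profile integer vector from [column_profile()].
#' @param maxima two-row tibble from [find_local_maxima()], the smaller peak
#'   on the right (i.e. after [resolve_orientation()]).
#' @return List with `boundary` (column), `span` (`c(first, last)` process
#'   columns) and `low_confidence`.
#' @export
locate_process <- function(profile, maxima) {
  if (nrow(maxima) != 2L) stage_stop("roimaker", "need exactly two profile maxima")
  c1 <- min(maxima$column); c2 <- max(maxima$column)
  interior <- if (c2 - c1 >= 2L) (c1 + 1L):(c2 - 1L) else integer(0)
  low_confidence <- FALSE
  if (length(interior) > 0L &&
      min(profile[interior]) < min(profile[c1], profile[c2])) {
    boundary <- interior[which.min(profile[interior])]
  } else {
    boundary <- (c1 + c2) %/% 2L
    low_confidence <- TRUE
    warning("no intensity gap between the profile maxima; using their midpoint")
  }
  last_fg <- max(which(profile > 0))
  if (boundary + 1L > last_fg) stage_stop("roimaker", "no process columns right of the boundary")
  list(boundary = as.integer(boundary),
       span = c(as.integer(boundary + 1L), as.integer(last_fg)),
       low_confidence = low_confidence)
}

#' ROI over the head of the process
#'
#' The bounding box of the foreground within the process columns fixes the
#' process thickness; the ROI is a square of that side placed on the apical
#' head (right-aligned at the process tip), capped at the process length when
#' the process is shorter than thick. Its dimensions become the template every
#' other ROI must share, so that per-ROI means are directly comparable.
#'
#' @param mask binary 0/1 matrix (leveled).
#' @param span process column span, e.g. `locate_process(...)$span`.
#' @return One-row ROI tibble (`role = "process"`).
#' @export
make_process_roi <- function(mask, span) {
  assert_mask(mask)
  sub <- mask[, span[1L]:span[2L], drop = FALSE]
  px <- which(sub == 1, arr.ind = TRUE)
  if (nrow(px) == 0L) stage_stop("roimaker", "no foreground in the process span")
  top <- min(px[, 1L]); bottom <- max(px[, 1L])
  left_rel <- min(px[, 2L]); right_rel <- max(px[, 2L])
  h <- bottom - top + 1L
  bw <- right_rel - left_rel + 1L
  w <- min(h, bw)
  right_abs <- span[1L] - 1L + right_rel
  if (h == 1L && w == 1L) warning("single-pixel process ROI")
  roi_row("process", 0L, top, right_abs - w + 1L, h, w)
}

#' Soma midline rows
#'
#' For each requested column, the mean row of the foreground pixels in that
#' column, rounded half-up; columns with no foreground are dropped.
#'
#' @param mask binary 0/1 matrix.
#' @param cols columns to evaluate.
#' @return Named integer vector (names = columns).
#' @export
soma_midline <- function(mask, cols) {
  assert_mask(mask)
  mid <- vapply(cols, function(cc) {
    rows <- which(mask[, cc] == 1)
    if (length(rows) == 0L) NA_real_ else round_half_up(mean(rows))
  }, numeric(1L))
  out <- as.integer(mid[!is.na(mid)])
  names(out) <- cols[!is.na(mid)]
  out
}

#' Tile template-sized ROIs along the soma midline
#'
#' Walks from the soma's apical (rightmost) foreground column toward its base,
#' placing non-overlapping rectangles of the template size whose horizontal
#' span steps by the template width and whose vertical position centers on the
#' midline row at each rectangle's center column. Tiling stops when the next
#' rectangle would pass the soma's leftmost foreground column or leave the
#' frame; ROIs are numbered 1..m apical to basal. The count is therefore
#' `floor(soma extent / template width)` (frame bounds permitting).
#'
#' @param mask binary 0/1 matrix (leveled).
#' @param template `c(height, width)` shared ROI dimensions.
#' @param boundary_col soma/process boundary column from [locate_process()];
#'   soma foreground is searched in columns 1..boundary_col.
#' @return ROI tibble (`role = "soma"`), ordered apical to basal.
#' @export
tile_soma_rois <- function(mask, template, boundary_col) {
  assert_mask(mask)
  th <- as.integer(template[1L]); tw <- as.integer(template[2L])
  if (th < 1L || tw < 1L) stage_stop("roimaker", "template dimensions must be >= 1")
  prof <- colSums(mask[, seq_len(boundary_col), drop = FALSE])
  fg <- which(prof > 0)
  if (length(fg) == 0L) stage_stop("roimaker", "no soma foreground left of the boundary")
  soma_left <- min(fg); soma_right <- max(fg)
  mid <- soma_midline(mask, soma_left:soma_right)
  mid_cols <- as.integer(names(mid))
  rois <- list()
  right <- soma_right
  ord <- 1L
  repeat {
    left <- right - tw + 1L
    if (left < soma_left) break
    cc <- left + tw %/% 2L
    near <- mid_cols[which.min(abs(mid_cols - cc))]
    top <- mid[[as.character(near)]] - th %/% 2L
    if (top < 1L || top + th - 1L > nrow(mask)) break
    rois[[ord]] <- roi_row("soma", ord, top, left, th, tw)
    ord <- ord + 1L
    right <- right - tw
  }
  if (length(rois) == 0L) stage_stop("roimaker", "soma shorter than process ROI")
  dplyr::bind_rows(rois)
}

#' Background reference ROI
#'
#' A template-sized rectangle containing zero foreground pixels, placed as far
#' from the cell as possible (maximal Chebyshev distance from the foreground
#' bounding box) so the cell's emitted light does not contaminate the
#' reference. The search is exhaustive over all positions via an integral
#' image; `valid` restricts it to pixels with genuine image support (after a
#' rotation, the grown canvas corners hold no data).
#'
#' @param mask binary 0/1 matrix.
#' @param template `c(height, width)`.
#' @param valid optional logical matrix, same shape, `TRUE` where the pixel
#'   holds real image content.
#' @return One-row ROI tibble (`role = "background"`).
#' @export
place_background_roi <- function(mask, template, valid = NULL) {
  assert_mask(mask)
  th <- as.integer(template[1L]); tw <- as.integer(template[2L])
  h <- nrow(mask); w <- ncol(mask)
  if (th > h || tw > w) stage_stop("roimaker", "no clean background region")
  px <- which(mask == 1, arr.ind = TRUE)
  if (nrow(px) == 0L) stage_stop("roimaker", "empty mask; nothing to stay away from")
  bt <- min(px[, 1L]); bb <- max(px[, 1L])
  bl <- min(px[, 2L]); br <- max(px[, 2L])
  ii_fg <- integral_image(mask)
  ii_bad <- if (is.null(valid)) NULL else integral_image(1 - valid)
  tops <- seq_len(h - th + 1L)
  lefts <- seq_len(w - tw + 1L)
  dr <- pmax(bt - (tops + th - 1L), tops - bb, 0L)
  dc <- pmax(bl - (lefts + tw - 1L), lefts - br, 0L)
  d <- outer(dr, dc, pmax)
  # test candidates from farthest inward; the first empty one wins
  for (k in order(d, decreasing = TRUE)) {
    top <- tops[(k - 1L) %% length(tops) + 1L]
    left <- lefts[(k - 1L) %/% length(tops) + 1L]
    if (rect_sum(ii_fg, top, left, th, tw) > 0) next
    if (!is.null(ii_bad) && rect_sum(ii_bad, top, left, th, tw) > 0) next
    return(roi_row("background", 0L, top, left, th, tw))
  }
  stage_stop("roimaker", "no clean background region")
}

#' Build the full ROI layout from a first frame
#'
#' Composes the first-frame pipeline: clean -> fit/refine rotation ->
#' orientation flip -> column profile -> process location -> process ROI ->
#' soma midline tiling -> background ROI. Every stage error is tagged with
#' its stage name. Supplying `config$manual_angle_deg` skips the regression
#' fit (the semi-automatic escape hatch); `template` forces the ROI
#' dimensions, which is how relocation preserves size and shape.
#'
#' @param frame numeric first-frame matrix (unrotated).
#' @param config a [run_config()].
#' @param template optional `c(height, width)` forcing ROI dimensions.
#' @param valid_from_frame 0-based frame index from which the layout applies.
#' @return An object of class `roi_layout`: `orientation`, `rois` (tibble:
#'   role, order, top, left, height, width — coordinates in the rotated
#'   canvas, 1-based inclusive), `valid_from_frame`, `threshold`,
#'   `canvas_shape`, `frame_shape`.
#' @export
build_layout <- function(frame, config = run_config(), template = NULL,
                         valid_from_frame = 0L) {
  assert_frame(frame)
  mask <- with_stage("cleaner", clean_frame(
    frame,
    max_iterations = config$max_clean_iterations,
    interactive = config$interactive,
    threshold = config$manual_threshold,
    n_bins = config$n_bins
  ))
  base_angle <- if (!is.null(config$manual_angle_deg)) {
    config$manual_angle_deg
  } else {
    with_stage("orient", estimate_rotation(mask))
  }
  orientation <- with_stage("orient", resolve_orientation(
    mask, base_angle,
    min_separation = config$min_peak_separation,
    smoothing_window = config$smoothing_window
  ))
  rmask <- rotate_mask(mask, orientation$angle_deg)
  if (sum(rmask) == 0) stage_stop("orient", "mask empty after rotation")
  prof <- column_profile(rmask)
  maxima <- with_stage("orient", find_local_maxima(
    prof, config$min_peak_separation, config$smoothing_window
  ))
  if (nrow(maxima) < 2L) {
    stage_stop("orient", "process not distinguishable; retry after cleaning or a slight tilt")
  }
  loc <- with_stage("roimaker", locate_process(prof, maxima))
  proc <- with_stage("roimaker", make_process_roi(rmask, loc$span))
  if (!is.null(template)) {
    th <- as.integer(template[1L]); tw <- as.integer(template[2L])
    ctr_row <- proc$top + proc$height %/% 2L
    right <- proc$left + proc$width - 1L
    proc <- roi_row("process", 0L,
                    max(1L, min(ctr_row - th %/% 2L, nrow(rmask) - th + 1L)),
                    max(1L, right - tw + 1L), th, tw)
  }
  soma <- with_stage("roimaker", tile_soma_rois(
    rmask, c(proc$height, proc$width), loc$boundary
  ))
  support <- rotation_support(dim(frame), orientation$angle_deg)
  bg <- with_stage("roimaker", place_background_roi(
    rmask, c(proc$height, proc$width), valid = support
  ))
  rois <- dplyr::bind_rows(proc, soma, bg)
  assert_roi_in_frame(rois, dim(rmask))
  structure(
    list(orientation = orientation, rois = rois,
         valid_from_frame = as.integer(valid_from_frame),
         threshold = attr(mask, "threshold"),
         canvas_shape = dim(rmask), frame_shape = dim(frame),
         low_confidence_boundary = loc$low_confidence),
    class = "roi_layout"
  )
}

#' @export
print.roi_layout <- function(x, ...) {
  cat(sprintf(
    "<roi_layout> angle %.2f deg, %d soma ROI(s), template %dx%d, from frame %d\n",
    x$orientation$angle_deg, sum(x$rois$role == "soma"),
    x$rois$height[1L], x$rois$width[1L], x$valid_from_frame
  ))
  invisible(x)
}

#' Serialize an ROI layout to JSON
#'
#' Writes the saved rotation angle, the ROI rectangles (1-based inclusive
#' rotated-canvas coordinates) and the validity frame so a run can be
#' reproduced or rendered later.
#'
#' @param layout an `roi_layout`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_layout_json <- function(layout, path) {
  stopifnot(inherits(layout, "roi_layout"))
  jsonlite::write_json(
    list(
      angle_deg = layout$orientation$angle_deg,
      flipped = layout$orientation$flipped,
      valid_from_frame = layout$valid_from_frame,
      threshold = layout$threshold,
      canvas_shape = layout$canvas_shape,
      frame_shape = layout$frame_shape,
      coordinates = "1-based inclusive [top, top+height-1] x [left, left+width-1]",
      rois = layout$rois
    ),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
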