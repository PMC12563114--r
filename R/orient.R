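#' Long-axis angle of a binary mask by regression
#'
#' Ordinary least-squares fit of the foreground pixels' row coordinates on
#' their column coordinates. The returned angle, `atan(slope)` in degrees, is
#' the rotation that [rotate_frame()] must apply to level the fitted line.
#' A single fit underestimates steep angles on blobs of finite aspect ratio
#' (regression dilution); [estimate_rotation()] removes that bias by
#' iterating, and is what the pipeline uses.
#'
#' @param mask binary 0/1 matrix with at least 2 foreground pixels spanning
#'   at least 2 distinct columns.
#' @return Angle in degrees in (-90, 90).
#' @export
fit_axis <- function(mask) {
  assert_mask(mask)
  px <- which(mask == 1, arr.ind = TRUE)
  if (nrow(px) < 2L || length(unique(px[, 2L])) < 2L) {
    stage_stop("orient", "axis undefined; tilt the preparation")
  }
  r <- px[, 1L]; cc <- px[, 2L]
  slope <- stats::cov(r, cc) / stats::var(cc)
  atan(slope) * 180 / pi
}

#' Iteratively refined rotation angle
#'
#' Repeats fit -> rotate -> refit on the mask until the residual fitted angle
#' falls below `tol` (or `max_iter` is hit) and returns the accumulated
#' angle. The fixed point has zero row/column covariance, i.e. the principal
#' axis exactly horizontal, so the attenuation of a single OLS fit at steep
#' orientations cancels.
#'
#' @param mask binary 0/1 matrix.
#' @param refine iterate (`TRUE`, the default) or do a single fit.
#' @param tol convergence tolerance in degrees.
#' @param max_iter iteration cap.
#' @return Accumulated angle in degrees, normalized to (-180, 180].
#' @export
estimate_rotation <- function(mask, refine = TRUE, tol = 0.1, max_iter = 10L) {
  total <- fit_axis(mask)
  if (!refine) return(normalize_angle(total))
  for (i in seq_len(max_iter)) {
    rot <- rotate_mask(mask, total)
    if (sum(rot) == 0) break
    step <- tryCatch(fit_axis(rot), error = function(e) 0)
    total <- total + step
    if (abs(step) < tol) break
  }
  normalize_angle(total)
}

#' Rotate a frame about its center
#'
#' Rotation by `angle_deg` with bilinear interpolation, on a canvas grown to
#' contain the whole rotated content; pixels with no source support are 0.
#' The convention: rotating by `a` maps a line of slope `tan(a)` (row over
#' column, row axis pointing down) to a horizontal line, so the output of
#' [fit_axis()] can be applied directly. An angle of 0 is a bit-exact
#' identity.
#'
#' @param frame numeric matrix.
#' @param angle_deg rotation angle in degrees.
#' @return Numeric matrix (possibly larger than the input).
#' @export
rotate_frame <- function(frame, angle_deg) {
  assert_frame(frame)
  if (angle_deg %% 360 == 0) return(frame)
  th <- angle_deg * pi / 180
  co <- cos(th); si <- sin(th)
  h <- nrow(frame); w <- ncol(frame)
  nh <- ceiling(h * abs(co) + w * abs(si) - 1e-9)
  nw <- ceiling(h * abs(si) + w * abs(co) - 1e-9)
  # grow the canvas without changing the center's pixel-grid phase, so
  # near-axis rotations stay grid-aligned instead of smearing by half a pixel
  if (abs(co) >= abs(si)) {
    nh <- nh + (nh - h) %% 2L
    nw <- nw + (nw - w) %% 2L
  } else {
    nh <- nh + (nh - w) %% 2L
    nw <- nw + (nw - h) %% 2L
  }
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  ncy <- (nh + 1) / 2; ncx <- (nw + 1) / 2
  dr <- seq_len(nh) - ncy
  dc <- seq_len(nw) - ncx
  # inverse map: source = center + R(-angle) %*% offset
  sr <- outer(co * dr, si * dc, "+") + cy
  sc <- outer(-si * dr, co * dc, "+") + cx
  r0 <- floor(sr); c0 <- floor(sc)
  fr <- sr - r0; fc <- sc - c0
  # pad by 2 so clamped out-of-range lookups land on zeros
  p <- matrix(0, h + 4L, w + 4L)
  p[3:(h + 2L), 3:(w + 2L)] <- frame
  r0 <- pmin(pmax(r0, -1), h + 1) + 2L
  c0 <- pmin(pmax(c0, -1), w + 1) + 2L
  idx <- function(ri, ci) p[cbind(as.vector(ri), as.vector(ci))]
  v <- (1 - fr) * (1 - fc) * idx(r0, c0) +
       (1 - fr) * fc       * idx(r0, c0 + 1L) +
       fr       * (1 - fc) * idx(r0 + 1L, c0) +
       fr       * fc       * idx(r0 + 1L, c0 + 1L)
  matrix(v, nh, nw)
}

#' Rotate a binary mask
#'
#' [rotate_frame()] followed by re-binarization at 0.5, since interpolation
#' produces fractional values at the boundary.
#'
#' @inheritParams rotate_frame
#' @param mask binary 0/1 matrix.
#' @return Binary 0/1 matrix.
#' @export
rotate_mask <- function(mask, angle_deg) {
  assert_mask(mask)
  (rotate_frame(mask, angle_deg) > 0.5) * 1
}

# Fraction of each rotated-canvas pixel that maps inside the original frame;
# used to keep background ROIs off the zero-filled canvas corners.
rotation_support <- function(shape, angle_deg) {
  ones <- matrix(1, shape[1L], shape[2L])
  rotate_frame(ones, angle_deg) >= 1 - 1e-6
}

#' Column profile of a binary mask
#'
#' Per-column count of foreground pixels: the projection of the leveled cell
#' onto the x axis. Its two local maxima locate the soma and the process;
#' the minimum between them is the inter-compartment intensity gap.
#'
#' @param mask binary 0/1 matrix.
#' @return Integer vector of length `ncol(mask)`.
#' @export
column_profile <- function(mask) {
  assert_mask(mask)
  as.integer(colSums(mask))
}

#' Local maxima of a column profile
#'
#' Smooths the profile with a centered moving average (window shrinks at the
#' edges) and reports peaks: positions strictly greater than both flanking
#' values, where a plateau of equal values with strictly lower flanks counts
#' as one peak at its center column. At most the two tallest peaks at least
#' `min_separation` columns apart are kept — the soma hump and the process
#' hump; smaller noise humps must not masquerade as the process.
#'
#' @param profile numeric vector (length >= 3).
#' @param min_separation minimal column distance between reported maxima.
#' @param smoothing_window moving-average window (columns); 1 disables.
#' @return Tibble with columns `column` and `height` (smoothed height),
#'   ordered by column; zero rows when the profile is monotone.
#' @export
find_local_maxima <- function(profile, min_separation = 10L, smoothing_window = 5L) {
  n <- length(profile)
  if (n < 3L) stage_stop("orient", "profile too short")
  k <- max(0L, (as.integer(smoothing_window) - 1L) %/% 2L)
  cs <- cumsum(c(0, profile))
  lo <- pmax(seq_len(n) - k, 1L)
  hi <- pmin(seq_len(n) + k, n)
  s <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  runs <- rle(s)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  m <- length(runs$values)
  peaks <- tibble::tibble(column = integer(0), height = numeric(0))
  if (m >= 3L) {
    is_peak <- c(FALSE, runs$values[2:(m - 1L)] > runs$values[1:(m - 2L)] &
                        runs$values[2:(m - 1L)] > runs$values[3:m], FALSE)
    if (any(is_peak)) {
      ctr <- starts[is_peak] + (runs$lengths[is_peak] - 1L) %/% 2L
      peaks <- tibble::tibble(column = ctr, height = runs$values[is_peak])
    }
  }
  if (nrow(peaks) == 0L) return(peaks)
  ord <- order(-peaks$height, peaks$column)
  kept <- integer(0)
  for (i in ord) {
    if (length(kept) == 2L) break
    if (all(abs(peaks$column[kept] - peaks$column[i]) >= min_separation)) {
      kept <- c(kept, i)
    }
  }
  out <- peaks[sort(kept), , drop = FALSE]
  out[order(out$column), , drop = FALSE]
}

#' Resolve the left/right orientation of the process
#'
#' Rotates the mask by `base_angle_deg`, projects it onto columns and finds
#' the two profile maxima. The smaller maximum is the process; it must end up
#' on the right of the soma, so if it lies left the rotation is flipped by
#' 180 degrees. The final angle is what the engine saves and applies to every
#' subsequent frame without recomputation.
#'
#' @param mask binary 0/1 matrix (cleaned first-frame mask).
#' @param base_angle_deg leveling angle, e.g. from [estimate_rotation()].
#' @param min_separation,smoothing_window passed to [find_local_maxima()].
#' @return A list of class `polaroi_orientation`: `angle_deg` in (-180, 180]
#'   and `flipped` (whether 180 degrees was added).
#' @export
resolve_orientation <- function(mask, base_angle_deg, min_separation = 10L,
                                smoothing_window = 5L) {
  rot <- rotate_mask(mask, base_angle_deg)
  prof <- column_profile(rot)
  maxima <- find_local_maxima(prof, min_separation, smoothing_window)
  if (nrow(maxima) < 2L) {
    stage_stop("orient", "process not distinguishable; retry after cleaning or a slight tilt")
  }
  smaller <- which.min(maxima$height)
  larger <- which.max(maxima$height)
  flipped <- maxima$column[smaller] < maxima$column[larger]
  angle <- normalize_angle(base_angle_deg + if (flipped) 180 else 0)
  structure(list(angle_deg = angle, flipped = flipped),
            class = "polaroi_orientation")
}

#' @export
print.polaroi_orientation <- function(x, ...) {
  cat(sprintf("<orientation> angle %.2f deg%s\n", x$angle_deg,
              if (x$flipped) " (flipped 180)" else ""))
  invisible(x)
}
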