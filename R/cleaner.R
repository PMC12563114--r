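#' Intensity histogram of the nonzero pixels
#'
#' Builds the intensity histogram used for background/cell separation. Pixels
#' with intensity exactly 0 are excluded: cropped recordings store the unused
#' canvas as zeros and those pixels carry no information about the scene.
#' Integer-valued frames get one bin per integer level spanning the nonzero
#' range; float frames get 256 equal-width bins over (0, max]. `n_bins`
#' overrides either default with equal-width bins over (0, max].
#'
#' @param frame numeric intensity matrix.
#' @param n_bins optional positive integer, number of equal-width bins.
#' @return A tibble with columns `intensity` (bin centers, strictly
#'   increasing) and `count`; counts sum to the number of nonzero pixels.
#' @export
intensity_histogram <- function(frame, n_bins = NULL) {
  assert_frame(frame)
  v <- frame[frame != 0]
  if (length(v) == 0L) stage_stop("cleaner", "empty image after zero exclusion")
  if (is.null(n_bins)) {
    if (all(v == round(v))) {
      lo <- min(v); hi <- max(v)
      centers <- seq(lo, hi)
      counts <- tabulate(v - lo + 1L, nbins = hi - lo + 1L)
      return(tibble::tibble(intensity = as.numeric(centers), count = counts))
    }
    n_bins <- 256L
  }
  n_bins <- as.integer(n_bins)
  if (n_bins < 1L) stage_stop("cleaner", "`n_bins` must be positive")
  hi <- max(v)
  breaks <- seq(0, hi, length.out = n_bins + 1L)
  idx <- pmin(pmax(findInterval(v, breaks, left.open = TRUE), 1L), n_bins)
  counts <- tabulate(idx, nbins = n_bins)
  centers <- (breaks[-1L] + breaks[-(n_bins + 1L)]) / 2
  tibble::tibble(intensity = centers, count = counts)
}

#' Histogram mode (background intensity level)
#'
#' The most frequent nonzero intensity; for a single labeled cell the image
#' is dominated by background, so the mode estimates the background level.
#' Ties are broken toward the lowest intensity, which biases the downstream
#' elbow search to see more of the histogram tail.
#'
#' @param hist tibble as returned by [intensity_histogram()].
#' @return The bin center (numeric scalar) of the maximal count.
#' @export
find_mode <- function(hist) {
  if (nrow(hist) == 0L) stage_stop("cleaner", "empty histogram")
  hist$intensity[which.max(hist$count)]
}

#' Kneedle elbow-point detection
#'
#' Finds the "elbow" of a decreasing, convex-ish curve by the kneedle
#' construction: min-max normalize both axes to \[0, 1\] and return the input
#' point maximizing the difference `(1 - y_norm) - x_norm`, i.e. the point of
#' maximal deviation below the descending diagonal. No sensitivity smoothing
#' is applied: the curves this package feeds in (histogram tails right of the
#' mode) have the decreasing-convex orientation by construction. Violations of
#' that shape only warn; on a perfectly straight line the difference curve is
#' identically zero and the first point is returned.
#'
#' @param xs strictly increasing numeric vector (at least 3 points).
#' @param ys numeric vector, same length as `xs`.
#' @return A list with elements `x`, `y` (the elbow coordinates) and `index`.
#' @export
kneedle <- function(xs, ys) {
  if (length(xs) < 3L) stage_stop("cleaner", "kneedle needs at least 3 points")
  if (length(ys) != length(xs)) stage_stop("cleaner", "xs and ys lengths differ")
  if (any(diff(xs) <= 0)) stage_stop("cleaner", "xs must be strictly increasing")
  xr <- diff(range(xs))
  yr <- diff(range(ys))
  if (ys[1L] < ys[length(ys)]) {
    warning("kneedle: curve is not decreasing; elbow may be meaningless")
  }
  xn <- (xs - xs[1L]) / xr
  yn <- if (yr == 0) rep(0, length(ys)) else (ys - min(ys)) / yr
  d <- (1 - yn) - xn
  i <- which.max(d)  # first index on ties (degenerate straight-line case)
  list(x = xs[i], y = ys[i], index = i)
}

#' Cell/background intensity threshold
#'
#' Passes the part of the nonzero-pixel histogram strictly to the right of its
#' mode to [kneedle()]; the elbow's intensity separates the background lobe
#' from the flat cell tail. This restriction is what guarantees the curve
#' holds a single elbow.
#'
#' @inheritParams intensity_histogram
#' @return Threshold intensity (numeric scalar).
#' @export
compute_threshold <- function(frame, n_bins = NULL) {
  hist <- intensity_histogram(frame, n_bins = n_bins)
  mode <- find_mode(hist)
  tail <- hist[hist$intensity > mode, , drop = FALSE]
  if (nrow(tail) < 3L) {
    stage_stop("cleaner", "degenerate histogram; supply threshold manually")
  }
  kneedle(tail$intensity, tail$count)$x
}

#' Binarize a frame at a threshold
#'
#' Pixels strictly above the threshold become 1, all others (including pixels
#' exactly at the threshold) become 0.
#'
#' @param frame numeric intensity matrix.
#' @param threshold numeric scalar.
#' @return A binary 0/1 matrix of the same shape.
#' @export
binarize <- function(frame, threshold) {
  assert_frame(frame)
  (frame > threshold) * 1
}

#' Remove weakly connected foreground pixels
#'
#' One synchronous pass of a Game-of-Life style survival rule: a foreground
#' pixel stays 1 iff at least 3 of its 8 neighbors are 1 (edge pixels count
#' only their existing neighbors); background pixels never turn on. Isolated
#' speckle noise in the background dies, compact cell bodies survive.
#'
#' @param mask binary 0/1 matrix.
#' @return A binary matrix; never contains more 1s than the input.
#' @export
prune_noise <- function(mask) {
  assert_mask(mask)
  h <- nrow(mask); w <- ncol(mask)
  p <- matrix(0, h + 2L, w + 2L)
  p[2:(h + 1L), 2:(w + 1L)] <- mask
  nb <- p[1:h, 1:w]         + p[1:h, 2:(w + 1L)]         + p[1:h, 3:(w + 2L)] +
        p[2:(h + 1L), 1:w]                               + p[2:(h + 1L), 3:(w + 2L)] +
        p[3:(h + 2L), 1:w]  + p[3:(h + 2L), 2:(w + 1L)]  + p[3:(h + 2L), 3:(w + 2L)]
  mask * (nb >= 3)
}

#' Segment the first frame into a clean binary cell mask
#'
#' Thresholds the frame ([compute_threshold()] unless `threshold` is given),
#' binarizes, then repeatedly applies [prune_noise()]. In batch mode pruning
#' runs `max_iterations` passes or until a pass changes no pixel, whichever
#' comes first; in interactive mode the mask is shown after each pass and the
#' user is asked whether to continue. Per-pass removed-pixel counts are kept
#' in the `passes` attribute and the threshold used in `threshold`.
#'
#' @param frame numeric intensity matrix.
#' @param max_iterations non-negative integer, pruning passes in batch mode.
#' @param interactive prompt after each pass instead of running a fixed count.
#' @param threshold optional manual threshold overriding [compute_threshold()].
#' @param n_bins passed to [intensity_histogram()].
#' @return Binary mask with attributes `threshold` and `passes`.
#' @export
clean_frame <- function(frame, max_iterations = 2L, interactive = FALSE,
                        threshold = NULL, n_bins = NULL) {
  assert_frame(frame)
  thr <- threshold %||% compute_threshold(frame, n_bins = n_bins)
  mask <- binarize(frame, thr)
  removed <- integer(0)
  it <- 0L
  repeat {
    go <- if (interactive) {
      tryCatch(graphics::image(t(mask[nrow(mask):1, , drop = FALSE]),
                               useRaster = TRUE, axes = FALSE),
               error = function(e) NULL)
      cat(sprintf("foreground: %d px after %d pass(es)\n", sum(mask), it))
      tolower(readline("prune weak pixels (another pass)? [y/N] ")) %in% c("y", "yes")
    } else {
      it < max_iterations
    }
    if (!go) break
    nxt <- prune_noise(mask)
    removed <- c(removed, sum(mask) - sum(nxt))
    changed <- !identical(nxt, mask)
    mask <- nxt
    it <- it + 1L
    if (!interactive && !changed) break
  }
  if (sum(mask) == 0) stage_stop("cleaner", "cleaning removed the entire cell")
  attr(mask, "threshold") <- thr
  attr(mask, "passes") <- removed
  mask
}
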