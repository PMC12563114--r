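#' Background-correct a fluorescence trace
#'
#' Pointwise subtraction of the background ROI's trace from a cell ROI's
#' trace, removing stray light and camera offset.
#'
#' @param cell_trace,bg_trace numeric vectors of equal length.
#' @return Numeric vector `cell_trace - bg_trace`.
#' @export
background_correct <- function(cell_trace, bg_trace) {
  if (length(cell_trace) != length(bg_trace)) {
    stage_stop("traces", "trace lengths differ")
  }
  cell_trace - bg_trace
}

#' Relative fluorescence change dF/F0
#'
#' `(F_t - F0) / F0` with `F0` the mean of the trace over the baseline
#' window. The result is invariant under gain changes of the detector and
#' measures the transient on the physiologically meaningful relative scale.
#'
#' @param trace numeric vector of per-frame intensities.
#' @param baseline_window integer positions (1-based into `trace`) of the
#'   baseline frames.
#' @return Numeric vector, same length as `trace`.
#' @export
dff0 <- function(trace, baseline_window) {
  baseline_window <- as.integer(baseline_window)
  if (length(baseline_window) == 0L ||
      any(baseline_window < 1L | baseline_window > length(trace))) {
    stage_stop("traces", "invalid baseline window")
  }
  f0 <- mean(trace[baseline_window])
  if (f0 == 0) stage_stop("traces", "zero baseline; check background correction")
  (trace - f0) / f0
}

# Linear interpolation of the time at which the trace crosses `level` between
# samples i and i+1.
cross_time <- function(y, t, i, level) {
  t[i] + (level - y[i]) / (y[i + 1L] - y[i]) * (t[i + 1L] - t[i])
}

#' Amplitude and 50%-width of a transient
#'
#' The amplitude is the maximum of the dF/F0 trace (no smoothing; see
#' `smooth_window`). The response width is the time between the 50%-of-max
#' crossings on the rising and the falling phase, both obtained by linear
#' interpolation between the bracketing samples — at 1 Hz sampling a
#' nearest-sample width would be biased by up to a full second. Non-uniform
#' sampling is supported through `times_s`. If the trace never falls back
#' below half maximum after the peak (or never rises through it before), the
#' width is undefined and flagged missing.
#'
#' @param dff numeric dF/F0 trace with a strictly positive maximum.
#' @param times_s per-sample times in seconds; defaults to 0-based sample
#'   index.
#' @param smooth_window optional centered moving-average window applied
#'   before peak extraction (default 1 = off).
#' @return One-row tibble: `amplitude`, `t_peak_s`, `width_s`,
#'   `width_missing`.
#' @export
transient_stats <- function(dff, times_s = NULL, smooth_window = 1L) {
  n <- length(dff)
  times_s <- times_s %||% (seq_len(n) - 1)
  if (length(times_s) != n) stage_stop("traces", "times length differs from trace")
  if (smooth_window > 1L) {
    k <- (as.integer(smooth_window) - 1L) %/% 2L
    cs <- cumsum(c(0, dff))
    lo <- pmax(seq_len(n) - k, 1L); hi <- pmin(seq_len(n) + k, n)
    dff <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  }
  amp <- max(dff)
  if (!(amp > 0)) stage_stop("traces", "trace has no positive maximum")
  ipk <- which.max(dff)
  half <- amp / 2
  before <- which(dff[seq_len(ipk)] < half)
  rise <- if (length(before) == 0L) NA_real_ else {
    i <- max(before)  # last sample below half before the peak
    cross_time(dff, times_s, i, half)
  }
  after <- which(dff[ipk:n] < half)
  fall <- if (length(after) == 0L) NA_real_ else {
    j <- ipk + min(after) - 1L  # first sample below half after the peak
    cross_time(dff, times_s, j - 1L, half)
  }
  width <- fall - rise
  tibble::tibble(
    amplitude = amp,
    t_peak_s = times_s[ipk],
    width_s = if (is.na(width)) NA_real_ else width,
    width_missing = is.na(width)
  )
}

#' Per-ROI transient statistics of a run
#'
#' For every cell ROI trace: background-correct against the background ROI,
#' normalize to dF/F0 over the baseline window and extract amplitude, peak
#' time and 50%-width. The default baseline window is the first 10% of
#' frames — stimulus timing is experimental metadata the program cannot
#' infer, so set `baseline_frames` to the pre-stimulus period when known.
#'
#' @param x a `polaroi_run` or its `traces` tibble.
#' @param baseline_frames 0-based frame indices of the baseline window
#'   (matching the `frame` column); `NULL` = first 10% of frames.
#' @param smooth_window passed to [transient_stats()].
#' @return Tibble with one row per cell ROI: `roi`, `amplitude`, `t_peak_s`,
#'   `width_s`, `width_missing`.
#' @export
summarize_transients <- function(x, baseline_frames = NULL, smooth_window = 1L) {
  traces <- if (inherits(x, "polaroi_run")) x$traces else x
  baseline_frames <- baseline_frames %||%
    (if (inherits(x, "polaroi_run")) x$config$baseline_frames else NULL)
  n <- nrow(traces)
  if (is.null(baseline_frames)) {
    baseline_frames <- traces$frame[seq_len(max(1L, ceiling(0.1 * n)))]
  }
  win <- match(as.integer(baseline_frames), traces$frame)
  if (anyNA(win)) stage_stop("traces", "baseline frames not present in the table")
  roi_cols <- c("roi_process", grep("^roi_soma_", names(traces), value = TRUE))
  purrr::map_dfr(roi_cols, function(col) {
    corrected <- background_correct(traces[[col]], traces$roi_background)
    d <- dff0(corrected, win)
    dplyr::bind_cols(tibble::tibble(roi = sub("^roi_", "", col)),
                     transient_stats(d, traces$time_s, smooth_window = smooth_window))
  })
}
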