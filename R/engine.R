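#' Run configuration
#'
#' Collects the user-tunable knobs of an analysis run. `alpha` is the
#' significance level of the motion check: the cell is declared lost (and the
#' ROIs relocated) when the cell-vs-background Wilcoxon comparison is *not*
#' significant at `alpha`, so smaller `alpha` relocates more readily — choose
#' it by the expected motion of the preparation and the time available.
#' `check_every` is the cadence in frames of that check.
#'
#' @param alpha significance level in (0, 1).
#' @param check_every run the motion check on every `check_every`-th frame.
#' @param max_clean_iterations pruning passes in [clean_frame()] (batch mode).
#' @param interactive prompt during cleaning instead of a fixed pass count.
#' @param motion_correct disable drift detection entirely when `FALSE`.
#' @param n_bins histogram bins override for [intensity_histogram()].
#' @param manual_threshold manual intensity threshold (skips the elbow search).
#' @param manual_angle_deg manual rotation angle (skips the regression fit).
#' @param smoothing_window,min_peak_separation peak detection knobs, see
#'   [find_local_maxima()].
#' @param baseline_frames 0-based frame indices of the baseline window used by
#'   [summarize_transients()]; `NULL` = first 10% of frames.
#' @return A list of class `run_config`.
#' @export
run_config <- function(alpha = 0.05, check_every = 5L, max_clean_iterations = 2L,
                       interactive = FALSE, motion_correct = TRUE, n_bins = NULL,
                       manual_threshold = NULL, manual_angle_deg = NULL,
                       smoothing_window = 5L, min_peak_separation = 10L,
                       baseline_frames = NULL) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stage_stop("config", "`alpha` must be in (0, 1)")
  }
  check_every <- as.integer(check_every)
  if (check_every < 1L) stage_stop("config", "`check_every` must be >= 1")
  if (max_clean_iterations < 0) stage_stop("config", "`max_clean_iterations` must be >= 0")
  structure(
    list(alpha = alpha, check_every = check_every,
         max_clean_iterations = as.integer(max_clean_iterations),
         interactive = isTRUE(interactive),
         motion_correct = isTRUE(motion_correct),
         n_bins = n_bins, manual_threshold = manual_threshold,
         manual_angle_deg = manual_angle_deg,
         smoothing_window = as.integer(smoothing_window),
         min_peak_separation = as.integer(min_peak_separation),
         baseline_frames = baseline_frames),
    class = "run_config"
  )
}

#' Mean ROI intensities of one (rotated) frame
#'
#' Arithmetic means of the raw pixel intensities inside each layout
#' rectangle. The frame must already be rotated by the layout's saved angle —
#' the engine applies that rotation to every incoming frame.
#'
#' @param frame rotated-frame matrix (dimensions = `layout$canvas_shape`).
#' @param layout an `roi_layout`.
#' @return List with `process` (scalar), `soma` (numeric vector ordered
#'   apical to basal) and `background` (scalar).
#' @export
measure_frame <- function(frame, layout) {
  assert_frame(frame)
  assert_roi_in_frame(layout$rois, dim(frame), stage = "engine")
  mean_of <- function(roi) mean(roi_pixels(frame, roi))
  rois <- layout$rois
  soma <- rois[rois$role == "soma", , drop = FALSE]
  soma <- soma[order(soma$order), , drop = FALSE]
  list(
    process = mean_of(rois[rois$role == "process", , drop = FALSE][1L, ]),
    soma = vapply(seq_len(nrow(soma)), function(i) mean_of(soma[i, ]), numeric(1L)),
    background = mean_of(rois[rois$role == "background", , drop = FALSE][1L, ])
  )
}

# Signed-rank test on paired differences; exact null for small n, normal
# approximation with continuity correction otherwise. Zero differences are
# dropped before testing.
signed_rank_test <- function(d, exact_max_n = 25L) {
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) return(list(statistic = NA_real_, p_value = 1, n = 0L))
  wt <- suppressWarnings(
    stats::wilcox.test(d, mu = 0, alternative = "two.sided",
                       exact = n <= exact_max_n, correct = TRUE)
  )
  list(statistic = unname(wt$statistic), p_value = wt$p.value, n = n)
}

#' Drift check: are the cell ROIs still on the cell?
#'
#' Pools the cell ROIs (process and each soma ROI) by averaging their pixels
#' positionally — all ROIs share dimensions, which is what makes the pooling
#' well defined — pairs the pooled pixels with the background ROI's pixels
#' and runs one two-sided Wilcoxon signed-rank test on the paired
#' differences, giving a single drift decision per frame. (Concatenating the
#' per-ROI differences instead would reuse every background pixel once per
#' cell ROI; that dependence makes the test anti-conservative and relocation
#' would fire far more often than the chosen significance level.) While the
#' cell sits under its ROIs the differences are overwhelmingly positive and
#' the test is significant; when the preparation has drifted the ROIs sample
#' background, the differences shrink to noise and significance is lost.
#' Drift is therefore declared when `p >= alpha`. If every difference is
#' zero the ROIs are indistinguishable from background and drift is declared
#' outright.
#'
#' @param frame rotated-frame matrix.
#' @param layout an `roi_layout`.
#' @param alpha significance level.
#' @return Logical `drifted`, with attributes `p_value` and `per_roi` (a
#'   tibble of per-ROI diagnostic p-values).
#' @export
motion_check <- function(frame, layout, alpha = 0.05) {
  rois <- layout$rois
  bg <- rois[rois$role == "background", , drop = FALSE][1L, ]
  cells <- rois[rois$role != "background", , drop = FALSE]
  if (!all(cells$height == bg$height & cells$width == bg$width)) {
    stage_stop("engine", "ROIs must share dimensions for the paired test")
  }
  bg_px <- as.vector(roi_pixels(frame, bg))
  diffs_by_roi <- lapply(seq_len(nrow(cells)), function(i) {
    as.vector(roi_pixels(frame, cells[i, ])) - bg_px
  })
  pooled <- Reduce(`+`, diffs_by_roi) / length(diffs_by_roi)
  res <- signed_rank_test(pooled)
  per_roi <- tibble::tibble(
    role = cells$role, order = cells$order,
    p_value = vapply(diffs_by_roi, function(d) signed_rank_test(d)$p_value,
                     numeric(1L))
  )
  drifted <- res$n == 0L || res$p_value >= alpha
  structure(drifted, p_value = res$p_value, per_roi = per_roi)
}

#' Relocate the ROI layout after drift
#'
#' Re-runs the whole first-frame pipeline (cleaning, orientation, process
#' location, tiling, background placement) on the current frame, but forces
#' the ROI template to the old layout's dimensions so that size and shape are
#' preserved across the relocation. If re-segmentation fails (cell lost), the
#' old layout is kept, a warning is raised and the run continues — partial
#' data beats none on a long recording.
#'
#' @param frame *unrotated* current frame.
#' @param old_layout the layout in force before the drift.
#' @param config a [run_config()].
#' @param frame_index 0-based index of `frame` (stamped as the new layout's
#'   validity start).
#' @return A new `roi_layout` (or the old one, flagged, when relocation
#'   failed — attribute `failed` is then `TRUE`).
#' @export
relocate_layout <- function(frame, old_layout, config, frame_index = 0L) {
  template <- c(old_layout$rois$height[1L], old_layout$rois$width[1L])
  tryCatch(
    build_layout(frame, config, template = template,
                 valid_from_frame = frame_index),
    error = function(e) {
      warning(sprintf("relocation failed at frame %d (%s); keeping previous layout",
                      frame_index, conditionMessage(e)))
      structure(old_layout, failed = TRUE)
    }
  )
}

#' Analyze a time-lapse stack
#'
#' The per-frame driver. The first frame fixes the rotation angle and the ROI
#' layout; every frame is then rotated by the saved angle and measured —
#' nothing is recomputed unless drift is detected. On every `check_every`-th
#' frame (after the first) [motion_check()] runs, and when it reports drift
#' the layout is rebuilt on the current frame with unchanged ROI dimensions.
#' Identical stack and config give a bit-identical result: there is no hidden
#' randomness anywhere in the analysis path.
#'
#' @param stack an [image_stack()] (or a path, which is passed to
#'   [read_stack()]).
#' @param config a [run_config()].
#' @return An object of class `polaroi_run`: `traces` (tibble: `frame`
#'   0-based, `time_s`, `roi_process`, `roi_soma_1..m`, `roi_background`,
#'   `relocated`), `layouts` (list of `roi_layout`s in force), `log`
#'   (tibble of stage/frame events incl. motion-check p-values), `config`.
#' @export
analyze_stack <- function(stack, config = run_config()) {
  if (is.character(stack)) stack <- read_stack(stack)
  stopifnot(inherits(stack, "image_stack"))
  n <- length(stack$frames)
  log <- list()
  note <- function(frame, stage, event, p_value = NA_real_) {
    log[[length(log) + 1L]] <<- tibble::tibble(
      frame = as.integer(frame), stage = stage, event = event, p_value = p_value
    )
  }
  layout <- build_layout(stack$frames[[1L]], config, valid_from_frame = 0L)
  note(0L, "layout", "built")
  layouts <- list(layout)
  m0 <- sum(layout$rois$role == "soma")
  rows <- vector("list", n)
  for (i in seq_len(n) - 1L) {
    raw <- stack$frames[[i + 1L]]
    rframe <- rotate_frame(raw, layout$orientation$angle_deg)
    relocated <- FALSE
    if (config$motion_correct && i > 0L && i %% config$check_every == 0L) {
      mc <- motion_check(rframe, layout, config$alpha)
      note(i, "engine", "motion_check", attr(mc, "p_value"))
      if (isTRUE(as.logical(mc))) {
        new_layout <- relocate_layout(raw, layout, config, frame_index = i)
        if (!isTRUE(attr(new_layout, "failed"))) {
          layout <- new_layout
          layouts[[length(layouts) + 1L]] <- layout
          rframe <- rotate_frame(raw, layout$orientation$angle_deg)
          relocated <- TRUE
          note(i, "engine", "relocated")
        } else {
          note(i, "engine", "relocation_failed")
        }
      }
    }
    meas <- measure_frame(rframe, layout)
    soma <- meas$soma
    if (length(soma) != m0) {  # layout epochs may disagree; keep the table rectangular
      soma <- c(soma, rep(NA_real_, max(0L, m0 - length(soma))))[seq_len(m0)]
    }
    rows[[i + 1L]] <- c(
      frame = i,
      time_s = if (is.null(stack$times)) i else stack$times[[i + 1L]],
      roi_process = meas$process,
      stats::setNames(soma, paste0("roi_soma_", seq_len(m0))),
      roi_background = meas$background,
      relocated = as.numeric(relocated)
    )
  }
  traces <- tibble::as_tibble(do.call(rbind, rows))
  traces$frame <- as.integer(traces$frame)
  traces$relocated <- as.logical(traces$relocated)
  structure(
    list(traces = traces, layouts = layouts,
         log = dplyr::bind_rows(log), config = config),
    class = "polaroi_run"
  )
}

#' @export
print.polaroi_run <- function(x, ...) {
  cat(sprintf(
    "<polaroi_run> %d frames, %d soma ROI(s), angle %.2f deg, %d relocation(s)\n",
    nrow(x$traces), sum(grepl("^roi_soma_", names(x$traces))),
    x$layouts[[1L]]$orientation$angle_deg, sum(x$traces$relocated)
  ))
  invisible(x)
}
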