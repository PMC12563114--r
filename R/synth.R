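#' Specification of a synthetic polarized-cell movie
#'
#' Parametric description of a single labeled polarized cell — an elliptical
#' soma with one thinner apical process — in a noisy time-lapse recording,
#' with compartment-specific transients and translational drift. The rendered
#' movies stand in for laboratory recordings during validation: every
#' geometric and photometric property is known exactly.
#'
#' Intensity model: background pixels sit at `bg_level`; compartment pixels at
#' `bg_level + (level - bg_level) * (1 + dff(t))`, i.e. the fluorescence
#' *above background* scales with the programmed dF/F0, so the
#' background-corrected relative change recovered downstream equals the
#' programmed peak. The transient rises linearly over `rise_frames` and then
#' decays exponentially with time constant `decay_frames`. i.i.d. Gaussian
#' noise of `noise_sd` is added to every pixel and the result clipped at 0.
#'
#' @param frame_shape `c(n_rows, n_cols)`.
#' @param soma_axes full axes `c(length, height)` of the soma ellipse in px.
#' @param process_length,process_width process rectangle dimensions in px
#'   (`process_width` must stay below the soma height so the column profile
#'   keeps two maxima).
#' @param theta_deg orientation of the cell axis in degrees (0 = horizontal).
#' @param chirality `"right"` or `"left"`: side the process points to before
#'   any rotation.
#' @param center `c(row, col)` soma center; `NULL` centers the whole cell.
#' @param bg_level,soma_level,process_level intensity levels (arbitrary
#'   units); both compartments must exceed the background.
#' @param noise_sd additive Gaussian noise SD.
#' @param transient list with `process`, `soma` (peak dF/F0 per compartment),
#'   `onset_frame` (0-based), `rise_frames`, `decay_frames`.
#' @param drift `NULL` or a data frame `(frame, drow, dcol)` of step
#'   translations applied from `frame` (0-based) onward (steps accumulate).
#' @param n_frames,frame_period_s movie length and sampling period.
#' @param seed integer; fixes the rendered movie bit-exactly.
#' @return A list of class `synth_spec`.
#' @export
synth_spec <- function(frame_shape = c(256L, 256L),
                       soma_axes = c(60, 24),
                       process_length = 40, process_width = 8,
                       theta_deg = 0, chirality = c("right", "left"),
                       center = NULL,
                       bg_level = 15, soma_level = 80, process_level = 70,
                       noise_sd = 3,
                       transient = list(process = 0.8, soma = 0.4,
                                        onset_frame = 40L, rise_frames = 4L,
                                        decay_frames = 10L),
                       drift = NULL,
                       n_frames = 120L, frame_period_s = 1,
                       seed = 1L) {
  chirality <- match.arg(chirality)
  if (process_width >= soma_axes[2L]) {
    stage_stop("synth", "process width must be below the soma height")
  }
  if (soma_level <= bg_level || process_level <= bg_level) {
    stage_stop("synth", "compartment levels must exceed the background level")
  }
  if (bg_level < 0) stage_stop("synth", "background level must be >= 0")
  if (n_frames < 1L) stage_stop("synth", "need at least one frame")
  if (!is.null(drift)) {
    drift <- tibble::as_tibble(drift)
    stopifnot(all(c("frame", "drow", "dcol") %in% names(drift)))
    drift <- drift[order(drift$frame), , drop = FALSE]
  }
  if (is.null(center)) {
    # Center the soma+process union in the frame (pre-rotation geometry).
    # Half-integer centers make even-sized compartments land symmetrically on
    # the pixel grid: the nominal ellipse/rectangle sizes are realized exactly
    # and the process is centered on the soma midline.
    half_len <- (soma_axes[1L] + process_length) / 2
    shift <- half_len - soma_axes[1L] / 2
    center <- c((frame_shape[1L] + 1) / 2,
                (frame_shape[2L] + 1) / 2 - if (chirality == "right") shift else -shift)
  }
  spec <- structure(
    list(frame_shape = as.integer(frame_shape), soma_axes = soma_axes,
         process_length = process_length, process_width = process_width,
         theta_deg = theta_deg, chirality = chirality, center = center,
         bg_level = bg_level, soma_level = soma_level,
         process_level = process_level, noise_sd = noise_sd,
         transient = transient, drift = drift,
         n_frames = as.integer(n_frames), frame_period_s = frame_period_s,
         seed = as.integer(seed)),
    class = "synth_spec"
  )
  validate_synth_spec(spec)
  spec
}

# Compartment masks at a given integer offset; membership is evaluated in the
# cell's own (axis, transverse) coordinates so arbitrary orientations render
# without interpolation.
synth_masks <- function(spec, offset = c(0L, 0L)) {
  h <- spec$frame_shape[1L]; w <- spec$frame_shape[2L]
  cr <- spec$center[1L] + offset[1L]; cc <- spec$center[2L] + offset[2L]
  th <- spec$theta_deg * pi / 180
  co <- cos(th); si <- sin(th)
  r <- matrix(seq_len(h) - cr, h, w)
  cl <- matrix(seq_len(w) - cc, h, w, byrow = TRUE)
  # template coords: v along the axis (process at +v), u transverse
  u <- co * r + si * cl
  v <- -si * r + co * cl
  if (spec$chirality == "left") v <- -v
  a <- spec$soma_axes[1L] / 2; b <- spec$soma_axes[2L] / 2
  soma <- (u / b)^2 + (v / a)^2 <= 1
  wp <- spec$process_width
  proc <- v > a & v <= a + spec$process_length &
          u >= -(wp %/% 2) & u < wp - wp %/% 2
  proc <- proc & !soma
  list(soma = soma * 1, process = proc * 1)
}

# Programmed dF/F0 time course of one compartment (0-based frame indices).
synth_dff <- function(peak, frames, onset, rise, decay) {
  dff <- numeric(length(frames))
  ramp <- frames >= onset & frames < onset + rise
  dff[ramp] <- peak * (frames[ramp] - onset + 1) / rise
  tail <- frames >= onset + rise
  dff[tail] <- peak * exp(-(frames[tail] - onset - rise + 1) / decay)
  dff
}

validate_synth_spec <- function(spec) {
  offs <- drift_offsets(spec)
  for (k in unique(asplit(offs, 1L))) {
    m <- synth_masks(spec, as.integer(k))
    fg <- (m$soma + m$process) > 0
    if (!any(fg)) stage_stop("synth", "cell renders empty")
    px <- which(fg, arr.ind = TRUE)
    if (min(px) < 1L || max(px[, 1L]) > spec$frame_shape[1L] ||
        max(px[, 2L]) > spec$frame_shape[2L] ||
        any(px[, 1L] %in% c(1L, spec$frame_shape[1L])) ||
        any(px[, 2L] %in% c(1L, spec$frame_shape[2L]))) {
      stage_stop("synth", "cell exits the frame under drift")
    }
  }
  invisible(spec)
}

# Per-frame cumulative (drow, dcol) offsets as an n_frames x 2 matrix.
drift_offsets <- function(spec) {
  offs <- matrix(0L, spec$n_frames, 2L)
  if (!is.null(spec$drift)) {
    for (j in seq_len(nrow(spec$drift))) {
      from <- spec$drift$frame[j] + 1L
      if (from <= spec$n_frames) {
        offs[from:spec$n_frames, 1L] <- offs[from:spec$n_frames, 1L] + spec$drift$drow[j]
        offs[from:spec$n_frames, 2L] <- offs[from:spec$n_frames, 2L] + spec$drift$dcol[j]
      }
    }
  }
  offs
}

#' Render a synthetic movie with ground truth
#'
#' Paints the compartment masks at each frame's drifted position, applies the
#' programmed per-compartment transients, adds seeded Gaussian noise and
#' clips at zero. The ground-truth record carries everything a validation
#' needs: the noise-free compartment masks (first frame and per-frame
#' offsets), the leveling angle the orientation stage should recover, the
#' programmed dF/F0 traces and the noise-free per-compartment mean traces.
#'
#' @param spec a [synth_spec()].
#' @return List with `stack` (an [image_stack()]) and `truth` (list: `soma_mask`,
#'   `process_mask`, `offsets`, `axis_angle_deg`, `theta_deg`, `chirality`,
#'   `traces` tibble with `frame`, `time_s`, `dff_process`, `dff_soma`,
#'   `mean_process`, `mean_soma`, `bg_level`, plus the spec itself).
#' @export
render_movie <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  set.seed(spec$seed)
  frames0 <- seq_len(spec$n_frames) - 1L
  offs <- drift_offsets(spec)
  dff_p <- synth_dff(spec$transient$process, frames0, spec$transient$onset_frame,
                     spec$transient$rise_frames, spec$transient$decay_frames)
  dff_s <- synth_dff(spec$transient$soma, frames0, spec$transient$onset_frame,
                     spec$transient$rise_frames, spec$transient$decay_frames)
  contrast_p <- spec$process_level - spec$bg_level
  contrast_s <- spec$soma_level - spec$bg_level
  h <- spec$frame_shape[1L]; w <- spec$frame_shape[2L]
  mask_cache <- list()
  frames <- vector("list", spec$n_frames)
  for (i in seq_len(spec$n_frames)) {
    key <- paste(offs[i, ], collapse = ",")
    if (is.null(mask_cache[[key]])) mask_cache[[key]] <- synth_masks(spec, offs[i, ])
    m <- mask_cache[[key]]
    f <- matrix(spec$bg_level, h, w)
    f[m$soma == 1] <- spec$bg_level + contrast_s * (1 + dff_s[i])
    f[m$process == 1] <- spec$bg_level + contrast_p * (1 + dff_p[i])
    if (spec$noise_sd > 0) f <- f + matrix(stats::rnorm(h * w, 0, spec$noise_sd), h, w)
    frames[[i]] <- pmax(f, 0)
  }
  times <- frames0 * spec$frame_period_s
  m0 <- synth_masks(spec, c(0L, 0L))
  truth <- list(
    soma_mask = m0$soma, process_mask = m0$process, offsets = offs,
    theta_deg = spec$theta_deg, chirality = spec$chirality,
    axis_angle_deg = normalize_angle(
      -spec$theta_deg + if (spec$chirality == "left") 180 else 0
    ),
    traces = tibble::tibble(
      frame = frames0, time_s = times,
      dff_process = dff_p, dff_soma = dff_s,
      mean_process = spec$bg_level + contrast_p * (1 + dff_p),
      mean_soma = spec$bg_level + contrast_s * (1 + dff_s),
      bg_level = spec$bg_level
    ),
    spec = spec
  )
  list(stack = image_stack(frames, times), truth = truth)
}

#' Default Deiters'-cell-like movie specification
#'
#' The package's reference study condition: a 256x256 field holding one cell
#' with a 60x24 px elliptical soma and a 40x8 px apical process, background
#' 15, soma 80 and process 70 intensity units, noise SD 3, 120 frames at 1 s
#' with a transient starting at frame 40 (process peak dF/F0 0.8, soma 0.4 —
#' the process responds more strongly, as its separate fluid compartment
#' suggests). Pass overrides (e.g. `theta_deg`, `drift`) through `...`.
#'
#' @param seed integer seed.
#' @param ... overrides forwarded to [synth_spec()].
#' @return A [synth_spec()].
#' @export
deiters_spec <- function(seed = 1L, ...) {
  args <- list(...)
  do.call(synth_spec, c(list(seed = seed), args))
}

#' Cone-photoreceptor-like movie specification
#'
#' A polarized cell with a different process/soma ratio: a longer, thicker
#' process (60x16 px) on a shorter soma (48x28 px). Because the ROI template
#' is sized from the process, fewer ROIs fit along the soma than for the
#' Deiters'-like default.
#'
#' @inheritParams deiters_spec
#' @return A [synth_spec()].
#' @export
cone_spec <- function(seed = 1L, ...) {
  args <- list(...)
  defaults <- list(seed = seed, soma_axes = c(48, 28), process_length = 60,
                   process_width = 16)
  do.call(synth_spec, utils::modifyList(defaults, args))
}
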