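#' Image stack container
#'
#' An `image_stack` holds an ordered sequence of same-shaped 2D intensity
#' frames (numeric matrices, row 1 at the top of the image) plus optional
#' per-frame acquisition times in seconds. Intensities are non-negative reals
#' on the scale of the source bit depth (no rescaling to \[0, 1\]; all
#' histogram/threshold logic downstream is scale-free).
#'
#' @param frames list of numeric matrices, all with identical dimensions.
#' @param times optional numeric vector of per-frame times in seconds
#'   (same length as `frames`), or `NULL` when unknown.
#' @return An object of class `image_stack` with elements `frames`, `times`
#'   and `shape` (`c(n_rows, n_cols)`).
#' @export
image_stack <- function(frames, times = NULL) {
  if (!is.list(frames) || length(frames) < 1L) {
    stage_stop("tiffio", "a stack needs at least one frame")
  }
  frames <- lapply(frames, function(f) {
    assert_frame(f)
    storage.mode(f) <- "double"
    f
  })
  shp <- dim(frames[[1L]])
  same <- vapply(frames, function(f) identical(dim(f), shp), logical(1L))
  if (!all(same)) stage_stop("tiffio", "all frames must share one shape")
  if (any(vapply(frames, function(f) any(f < 0), logical(1L)))) {
    stage_stop("tiffio", "intensities must be non-negative")
  }
  if (!is.null(times)) {
    times <- as.numeric(times)
    if (length(times) != length(frames)) {
      stage_stop("tiffio", "`times` must have one entry per frame")
    }
  }
  structure(
    list(frames = frames, times = times, shape = shp),
    class = "image_stack"
  )
}

#' @export
print.image_stack <- function(x, ...) {
  cat(sprintf(
    "<image_stack> %d frame(s) of %d x %d, times %s\n",
    length(x$frames), x$shape[1L], x$shape[2L],
    if (is.null(x$times)) "absent" else "present"
  ))
  invisible(x)
}

#' @export
length.image_stack <- function(x) length(x$frames)

# Parse per-page timestamps out of TIFF description tags. Accepts either a
# bare number or JSON carrying `time_s` (or `times` on the first page).
times_from_pages <- function(pages) {
  descs <- lapply(pages, attr, "description")
  if (all(vapply(descs, is.null, logical(1L)))) return(NULL)
  first <- descs[[1L]]
  if (!is.null(first)) {
    parsed <- tryCatch(jsonlite::fromJSON(first), error = function(e) NULL)
    if (is.list(parsed) && !is.null(parsed$times) &&
        length(parsed$times) == length(pages)) {
      return(as.numeric(parsed$times))
    }
  }
  one <- function(d) {
    if (is.null(d)) return(NA_real_)
    p <- tryCatch(jsonlite::fromJSON(d), error = function(e) NULL)
    if (is.list(p) && !is.null(p$time_s)) return(as.numeric(p$time_s)[1L])
    if (is.numeric(p) && length(p) == 1L) return(as.numeric(p))
    suppressWarnings(as.numeric(d))
  }
  times <- vapply(descs, one, numeric(1L))
  if (anyNA(times)) NULL else times
}

#' Read a multipage TIFF stack
#'
#' Reads all pages of a (single- or multi-page) grayscale TIFF in file order.
#' Integer pages are kept on their native scale (e.g. 0..65535 for 16 bit);
#' float pages are used as stored. Per-frame timestamps are taken from
#' per-page TIFF description tags when they parse as a time (bare seconds or
#' JSON with `time_s`), else from a plain-text sidecar `<path>.times.json`
#' (written by [write_stack()]), else left absent — downstream code then falls
#' back to the frame index as the time axis.
#'
#' @param path path to a TIFF file.
#' @return An [image_stack()].
#' @export
read_stack <- function(path) {
  if (!file.exists(path)) stage_stop("tiffio", "cannot read '", path, "'")
  pages <- tryCatch(
    suppressWarnings(tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE)),
    error = function(e) stage_stop("tiffio", "not a readable TIFF: ", conditionMessage(e))
  )
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) == 0L) stage_stop("tiffio", "TIFF has zero pages")
  frames <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1L]  # collapse to one channel
    matrix(as.numeric(p), nrow(p), ncol(p))   # drop TIFF tag attributes
  })
  times <- times_from_pages(pages)
  if (is.null(times)) {
    sidecar <- paste0(path, ".times.json")
    if (file.exists(sidecar)) {
      times <- tryCatch(as.numeric(jsonlite::fromJSON(sidecar)),
                        error = function(e) NULL)
      if (!is.null(times) && length(times) != length(frames)) times <- NULL
    }
  }
  image_stack(frames, times)
}

#' Write an image stack to a multipage TIFF
#'
#' Frames are rounded to integers and stored as 16-bit grayscale pages, so
#' integer-valued stacks round-trip exactly through [read_stack()]. When the
#' stack carries times, they are written to a plain-text JSON sidecar
#' `<path>.times.json` (the R TIFF writer does not support description tags).
#'
#' @param stack an [image_stack()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  mx <- 65535
  pages <- lapply(stack$frames, function(f) {
    f <- round(f)
    if (any(f > mx)) stage_stop("tiffio", "intensity exceeds 16-bit range")
    f / mx
  })
  ok <- tryCatch(
    tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none",
                    reduce = FALSE),
    error = function(e) stage_stop("tiffio", "cannot write '", path, "': ",
                                   conditionMessage(e))
  )
  if (!is.null(stack$times)) {
    jsonlite::write_json(stack$times, paste0(path, ".times.json"), digits = NA)
  }
  invisible(path)
}
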