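# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Stop with a stage-tagged message so pipeline errors name the step that failed.
stage_stop <- function(stage, ...) {
  stop(sprintf("[%s] %s", stage, paste0(...)), call. = FALSE)
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    msg <- conditionMessage(e)
    if (grepl("^\\[", msg)) stop(e) else stage_stop(stage, msg)
  })
}

assert_frame <- function(frame, arg = "frame") {
  if (!is.matrix(frame) || !is.numeric(frame)) {
    stop(sprintf("`%s` must be a numeric matrix", arg), call. = FALSE)
  }
  invisible(frame)
}

assert_mask <- function(mask, arg = "mask") {
  assert_frame(mask, arg)
  if (!all(mask %in% c(0, 1))) {
    stop(sprintf("`%s` must be binary (0/1)", arg), call. = FALSE)
  }
  invisible(mask)
}

# Summed-area table; pad row/col of zeros on top/left so lookups are branch-free.
integral_image <- function(m) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(0, h + 1L, w + 1L)
  out[-1L, -1L] <- apply(apply(m, 2L, cumsum), 1L, cumsum) |> t()
  out
}

# Sum of m over rows top..top+hh-1, cols left..left+ww-1 using its integral image.
rect_sum <- function(ii, top, left, hh, ww) {
  ii[top + hh, left + ww] - ii[top, left + ww] - ii[top + hh, left] + ii[top, left]
}

# Normalize an angle in degrees to (-180, 180].
normalize_angle <- function(a) {
  a <- a %% 360
  ifelse(a > 180, a - 360, a)
}

round_half_up <- function(x) floor(x + 0.5)
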