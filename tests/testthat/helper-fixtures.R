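# Fixtures are generated in code; no binary files are shipped.

# Two-population Gaussian test image: background N(bg_mean, bg_sd) everywhere,
# a centered square holding `cell_frac` of the pixels at N(cell_mean, cell_sd).
two_gaussian_frame <- function(seed, h = 120L, w = 120L, cell_frac = 0.05,
                               bg_mean = 20, bg_sd = 2,
                               cell_mean = 80, cell_sd = 5) {
  set.seed(seed)
  cellmask <- matrix(0, h, w)
  side <- round(sqrt(cell_frac * h * w))
  r0 <- (h - side) %/% 2L
  cellmask[r0:(r0 + side - 1L), r0:(r0 + side - 1L)] <- 1
  f <- matrix(stats::rnorm(h * w, bg_mean, bg_sd), h, w)
  f[cellmask == 1] <- stats::rnorm(sum(cellmask), cell_mean, cell_sd)
  list(frame = pmax(f, 0.01), cell_mask = cellmask)
}

# A small binary mask with a given set of 1-pixels.
mask_from_points <- function(h, w, rows, cols) {
  m <- matrix(0, h, w)
  m[cbind(rows, cols)] <- 1
  m
}

# Independent kneedle oracle: brute-force argmax of the normalized difference.
kneedle_oracle_index <- function(xs, ys) {
  xn <- (xs - min(xs)) / (max(xs) - min(xs))
  yn <- if (diff(range(ys)) == 0) rep(0, length(ys)) else
    (ys - min(ys)) / (max(ys) - min(ys))
  which.max((1 - yn) - xn)
}

# Independent signed-rank oracle: exact two-sided p by enumerating all 2^n
# sign assignments of the ranked absolute differences.
signed_rank_enumeration <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% r)
  mu <- n * (n + 1) / 4
  p <- if (v_obs > mu) mean(v_all >= v_obs) else mean(v_all <= v_obs)
  list(statistic = v_obs, p_value = min(2 * p, 1))
}

# Short no-drift movie used by several engine tests.
quick_movie <- function(seed = 1, n_frames = 20L, ...) {
  render_movie(deiters_spec(seed = seed, n_frames = n_frames, ...))
}
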