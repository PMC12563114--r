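test_that("intensity_histogram excludes zeros and bins integer levels", {
  f <- matrix(c(0, 0, 5, 5, 5, 0), 2, 3)
  h <- intensity_histogram(f)
  expect_equal(h$intensity[h$count > 0], 5)
  expect_equal(h$count[h$intensity == 5], 3)
  expect_equal(sum(h$count), 3)

  h1 <- intensity_histogram(f, n_bins = 1)
  expect_equal(nrow(h1), 1)
  expect_equal(h1$count, 3)

  expect_error(intensity_histogram(matrix(0, 3, 3)), "empty image")
})

test_that("histogram counts sum to the nonzero pixel count (float path)", {
  set.seed(11)
  f <- matrix(abs(rnorm(400, 10, 3)), 20, 20)
  f[1:5, 1] <- 0
  h <- intensity_histogram(f)
  expect_equal(nrow(h), 256)
  expect_equal(sum(h$count), sum(f != 0))
  expect_true(all(diff(h$intensity) > 0))
})

test_that("find_mode picks the maximal count, lowest intensity on ties", {
  h <- tibble::tibble(intensity = c(10, 20, 30), count = c(1, 9, 3))
  expect_equal(find_mode(h), 20)
  ht <- tibble::tibble(intensity = c(10, 20), count = c(5, 5))
  expect_equal(find_mode(ht), 10)
})

test_that("kneedle finds the knee of a piecewise-linear curve", {
  el <- kneedle(0:4, c(10, 1, 0.9, 0.8, 0.7))
  expect_equal(el$x, 1)
  expect_equal(el$index, 2L)
})

test_that("kneedle on a straight line returns the first point", {
  el <- kneedle(1:5, 10 - 2 * (1:5))
  expect_equal(el$index, 1L)
})

test_that("kneedle agrees with the chord-distance oracle on y = 1/x", {
  xs <- 1:9
  ys <- 1 / xs
  # perpendicular distance from the chord joining the endpoints
  x1 <- xs[1]; y1 <- ys[1]; x2 <- xs[9]; y2 <- ys[9]
  chord <- abs((y2 - y1) * xs - (x2 - x1) * ys + x2 * y1 - y2 * x1) /
    sqrt((y2 - y1)^2 + (x2 - x1)^2)
  expect_equal(kneedle(xs, ys)$index, which.max(chord))
})

test_that("kneedle validates its input and tolerates shape violations", {
  expect_error(kneedle(1:2, c(2, 1)), "at least 3")
  expect_error(kneedle(c(1, 3, 2), c(3, 2, 1)), "strictly increasing")
  expect_warning(kneedle(1:5, c(1, 2, 3, 4, 5)), "not decreasing")
})

test_that("kneedle matches the brute-force oracle on random convex curves", {
  set.seed(42)
  for (i in 1:60) {
    n <- sample(3:100, 1)
    xs <- sort(runif(n, 0, 10))
    while (any(diff(xs) == 0)) xs <- sort(runif(n, 0, 10))
    p <- runif(1, 1, 4)
    ys <- 5 + 20 * (1 - (xs - min(xs)) / diff(range(xs)))^p
    expect_equal(kneedle(xs, ys)$index, kneedle_oracle_index(xs, ys))
  }
})

test_that("compute_threshold separates two-valued images and rejects flat ones", {
  f <- matrix(20, 20, 20)
  f[1:4, 1:5] <- 80
  f[10, 10] <- 50
  # the sparse tail is not monotone; kneedle warns but must not fail
  thr <- suppressWarnings(compute_threshold(f))
  expect_gt(thr, 20)
  expect_lte(thr, 80)
  b <- binarize(f, thr)
  expect_true(all(b[1:4, 1:5] == 1))
  expect_error(compute_threshold(matrix(7, 5, 5)), "degenerate histogram")
})

test_that("compute_threshold is invariant under affine intensity rescaling", {
  tg <- two_gaussian_frame(3)
  thr <- compute_threshold(tg$frame)
  a <- 2.5; b <- 7
  f2 <- tg$frame * a + b  # all pixels nonzero, so b applies to nonzero pixels
  thr2 <- compute_threshold(f2)
  binw <- max(tg$frame) / 256
  expect_lt(abs(thr2 - (a * thr + b)), a * 2 * binw + b / 256 + 1e-9)
  # masks agree up to pixels within one bin of the threshold
  expect_lt(mean(binarize(tg$frame, thr) != binarize(f2, thr2)), 0.002)
})

test_that("binarize uses a strict inequality", {
  f <- matrix(c(1, 5, 9), 1, 3)
  expect_equal(as.vector(binarize(f, 5)), c(0, 0, 1))
  expect_true(all(binarize(f, 0) == 1))
  expect_true(all(binarize(f, 10) == 0))
})

test_that("prune_noise applies the >=3-of-8 survival rule", {
  lone <- mask_from_points(5, 5, 3, 3)
  expect_true(all(prune_noise(lone) == 0))

  domino <- mask_from_points(5, 5, c(3, 3), c(2, 3))
  expect_true(all(prune_noise(domino) == 0))

  block <- matrix(0, 5, 5)
  block[2:4, 2:4] <- 1  # corners of a solid 3x3 have exactly 3 neighbors
  expect_identical(prune_noise(block), block)
})

test_that("prune_noise never adds pixels and reaches a fixed point", {
  set.seed(5)
  m <- matrix(rbinom(900, 1, 0.4), 30, 30)
  prev <- m
  for (i in 1:900) {
    nxt <- prune_noise(prev)
    expect_true(all(nxt <= prev))
    if (identical(nxt, prev)) break
    prev <- nxt
  }
  expect_identical(prune_noise(prev), prev)
})

test_that("clean_frame segments a noisy synthetic cell accurately", {
  mv <- render_movie(deiters_spec(seed = 4, n_frames = 1))
  f <- mv$stack$frames[[1]]
  # add 1% salt noise on top of the rendered scene
  set.seed(9)
  idx <- sample(length(f), round(0.01 * length(f)))
  f[idx] <- f[idx] + 60
  mask <- clean_frame(f, max_iterations = 2)
  truth <- (mv$truth$soma_mask + mv$truth$process_mask) > 0
  jac <- sum(mask == 1 & truth) / sum(mask == 1 | truth)
  expect_gte(jac, 0.9)
})

test_that("clean_frame honors max_iterations = 0 and is idempotent at the fixed point", {
  tg <- two_gaussian_frame(6)
  thr <- compute_threshold(tg$frame)
  raw <- clean_frame(tg$frame, max_iterations = 0)
  expect_equal(unclass(raw), binarize(tg$frame, thr), ignore_attr = TRUE)

  m1 <- clean_frame(tg$frame, max_iterations = 50)
  m2 <- clean_frame(tg$frame, max_iterations = 50, threshold = attr(m1, "threshold"))
  expect_equal(unclass(m1), unclass(m2), ignore_attr = TRUE)
  expect_identical(prune_noise(unclass(m1)), unclass(m1))
})

test_that("misclassification on well-separated two-Gaussian images is tiny", {
  tg <- two_gaussian_frame(7)
  thr <- compute_threshold(tg$frame)
  b <- binarize(tg$frame, thr)
  expect_lte(mean(b != tg$cell_mask), 0.01)
})
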