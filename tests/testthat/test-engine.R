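test_that("run_config validates its fields", {
  expect_error(run_config(alpha = 0), "alpha")
  expect_error(run_config(alpha = 1.5), "alpha")
  expect_error(run_config(check_every = 0), "check_every")
  cfg <- run_config()
  expect_equal(cfg$alpha, 0.05)
  expect_equal(cfg$check_every, 5L)
})

test_that("measure_frame averages raw intensities inside each rectangle", {
  mv <- quick_movie(seed = 2, n_frames = 1)
  lay <- build_layout(mv$stack$frames[[1]])
  const <- matrix(7, lay$canvas_shape[1], lay$canvas_shape[2])
  m <- measure_frame(const, lay)
  expect_equal(m$process, 7)
  expect_true(all(m$soma == 7))
  expect_equal(m$background, 7)

  spot <- matrix(0, lay$canvas_shape[1], lay$canvas_shape[2])
  p <- lay$rois[lay$rois$role == "process", ]
  spot[p$top:(p$top + p$height - 1), p$left:(p$left + p$width - 1)] <- 10
  m2 <- measure_frame(spot, lay)
  expect_equal(m2$process, 10)
  expect_true(all(m2$soma == 0))
  expect_equal(m2$background, 0)
})

test_that("motion_check keeps well-separated cells and reports pooled p", {
  mv <- quick_movie(seed = 3, n_frames = 1)
  lay <- build_layout(mv$stack$frames[[1]])
  rframe <- rotate_frame(mv$stack$frames[[1]], lay$orientation$angle_deg)
  mc <- motion_check(rframe, lay, alpha = 0.05)
  expect_false(as.logical(mc))
  expect_lt(attr(mc, "p_value"), 1e-10)
  expect_s3_class(attr(mc, "per_roi"), "tbl_df")
})

test_that("motion_check declares drift when cell ROIs sample the background", {
  mv <- quick_movie(seed = 4, n_frames = 1)
  lay <- build_layout(mv$stack$frames[[1]])
  set.seed(40)
  drifted <- vapply(1:100, function(i) {
    noise <- matrix(rnorm(prod(lay$canvas_shape), 15, 3),
                    lay$canvas_shape[1], lay$canvas_shape[2])
    as.logical(motion_check(pmax(noise, 0), lay, alpha = 0.05))
  }, logical(1))
  expect_gte(mean(drifted), 0.85)  # nominal level 1 - alpha = 0.95
})

test_that("motion_check treats all-zero differences as drift", {
  mv <- quick_movie(seed = 5, n_frames = 1)
  lay <- build_layout(mv$stack$frames[[1]])
  flat <- matrix(3, lay$canvas_shape[1], lay$canvas_shape[2])
  expect_true(as.logical(motion_check(flat, lay, alpha = 0.05)))
})

test_that("the exact signed-rank branch matches full sign enumeration", {
  set.seed(17)
  d <- round(rnorm(6, 0.5, 1), 3)
  ours <- polaroi:::signed_rank_test(d)
  oracle <- signed_rank_enumeration(d)
  expect_equal(ours$statistic, oracle$statistic)
  expect_equal(ours$p_value, oracle$p_value)
})

test_that("relocation preserves ROI size and shape", {
  mv <- render_movie(deiters_spec(seed = 6, n_frames = 1, theta_deg = 15))
  f <- mv$stack$frames[[1]]
  lay <- build_layout(f)
  newlay <- relocate_layout(f, lay, run_config(), frame_index = 10L)
  expect_equal(newlay$rois$height[1], lay$rois$height[1])
  expect_equal(newlay$rois$width[1], lay$rois$width[1])
  expect_equal(newlay$valid_from_frame, 10L)
})

test_that("failed relocation keeps the old layout and warns", {
  mv <- quick_movie(seed = 7, n_frames = 1)
  lay <- build_layout(mv$stack$frames[[1]])
  flat <- matrix(5, 256, 256)  # nothing to segment
  expect_warning(kept <- relocate_layout(flat, lay, run_config(), 15L),
                 "relocation failed")
  expect_true(attr(kept, "failed"))
  expect_equal(kept$rois, lay$rois)
})

test_that("a 1-frame stack yields a 1-row table without relocation", {
  mv <- quick_movie(seed = 8, n_frames = 1)
  run <- analyze_stack(mv$stack)
  expect_equal(nrow(run$traces), 1)
  expect_false(run$traces$relocated[1])
  expect_equal(run$traces$frame, 0L)
})

test_that("no-drift runs compute the layout exactly once and never relocate", {
  mv <- quick_movie(seed = 9, n_frames = 30)
  run <- analyze_stack(mv$stack)
  expect_equal(nrow(run$traces), 30)
  expect_equal(sum(run$log$event == "built"), 1)       # single segmentation pass
  expect_equal(sum(run$log$event == "relocated"), 0)
  expect_equal(length(run$layouts), 1)
  expect_false(any(run$traces$relocated))
  # motion checks ran on the cadence
  checks <- run$log$frame[run$log$event == "motion_check"]
  expect_equal(checks, seq(5L, 25L, by = 5L))
})

test_that("identical stack and config give bit-identical results", {
  mv <- quick_movie(seed = 10, n_frames = 15)
  r1 <- analyze_stack(mv$stack)
  r2 <- analyze_stack(mv$stack)
  expect_identical(r1$traces, r2$traces)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_results(r1, f1); write_results(r2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("relocated is flagged only on motion-check frames", {
  drift <- data.frame(frame = 10, drow = 15, dcol = 0)
  mv <- render_movie(deiters_spec(seed = 11, n_frames = 25, drift = drift))
  run <- analyze_stack(mv$stack)
  hits <- run$traces$frame[run$traces$relocated]
  expect_true(all(hits %% run$config$check_every == 0))
})

test_that("times fall back to the frame index when the stack has none", {
  mv <- quick_movie(seed = 12, n_frames = 5)
  stack_na <- image_stack(mv$stack$frames)
  run <- analyze_stack(stack_na)
  expect_equal(run$traces$time_s, as.numeric(0:4))
})
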