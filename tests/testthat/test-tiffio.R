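test_that("a constant single-page TIFF round-trips as an identity", {
  f <- matrix(37, 4, 4)
  path <- tempfile(fileext = ".tif")
  write_stack(image_stack(list(f)), path)
  st <- read_stack(path)
  expect_equal(length(st$frames), 1)
  expect_equal(st$shape, c(4L, 4L))
  expect_equal(st$frames[[1]], f)
  expect_null(st$times)
})

test_that("synthetic multipage stacks round-trip with their timestamps", {
  mv <- render_movie(deiters_spec(seed = 1, n_frames = 10, frame_period_s = 2.5))
  path <- tempfile(fileext = ".tif")
  write_stack(mv$stack, path)
  st <- read_stack(path)
  expect_equal(length(st$frames), 10)
  expect_equal(st$times, seq(0, by = 2.5, length.out = 10))
  # lossless at the stored (integer) depth
  for (i in c(1, 5, 10)) {
    expect_equal(st$frames[[i]], round(mv$stack$frames[[i]]))
  }
})

test_that("per-page TIFF description tags supply timestamps", {
  pages <- lapply(0:2, function(i) {
    p <- matrix(1, 2, 2)
    attr(p, "description") <- sprintf('{"time_s": %.1f}', i * 1.5)
    p
  })
  expect_equal(polaroi:::times_from_pages(pages), c(0, 1.5, 3))
  bare <- lapply(c(7, 9), function(t) {
    p <- matrix(1, 2, 2); attr(p, "description") <- as.character(t); p
  })
  expect_equal(polaroi:::times_from_pages(bare), c(7, 9))
  none <- list(matrix(1, 2, 2))
  expect_null(polaroi:::times_from_pages(none))
  junk <- lapply(1:2, function(i) {
    p <- matrix(1, 2, 2); attr(p, "description") <- "ImageJ=1.54"; p
  })
  expect_null(polaroi:::times_from_pages(junk))
})

test_that("read_stack reports I/O and format errors with the stage tag", {
  expect_error(read_stack(tempfile(fileext = ".tif")), "\\[tiffio\\]")
  bad <- tempfile(fileext = ".tif")
  writeLines("not a tiff", bad)
  expect_error(read_stack(bad), "\\[tiffio\\]")
})

test_that("image_stack enforces its invariants", {
  expect_error(image_stack(list()), "at least one frame")
  expect_error(image_stack(list(matrix(1, 2, 2), matrix(1, 3, 3))), "one shape")
  expect_error(image_stack(list(matrix(-1, 2, 2))), "non-negative")
  expect_error(image_stack(list(matrix(1, 2, 2)), times = 1:2), "one entry per frame")
})

test_that("the results CSV honors the column contract and round-trips", {
  mv <- render_movie(deiters_spec(seed = 1, n_frames = 10))
  run <- analyze_stack(mv$stack)
  path <- tempfile(fileext = ".csv")
  write_results(run, path)
  header <- strsplit(readLines(path, n = 1), ",")[[1]]
  m <- sum(grepl("^roi_soma_", names(run$traces)))
  expect_equal(header, c("frame", "time_s", "roi_process",
                         paste0("roi_soma_", seq_len(m)),
                         "roi_background", "relocated"))
  expect_equal(length(header), 5 + m)
  back <- read_results(path)
  expect_equal(nrow(back), 10)
  expect_identical(back$frame, run$traces$frame)
  expect_identical(back$relocated, run$traces$relocated)
  expect_equal(back$roi_process, run$traces$roi_process, tolerance = 1e-12)
  expect_error(write_results(run$traces[0, ], tempfile()), "empty")
})

test_that("write_overlay produces a decodable PNG with ROIs on the cell", {
  mv <- render_movie(deiters_spec(seed = 1, n_frames = 1))
  f <- mv$stack$frames[[1]]
  lay <- build_layout(f, run_config(manual_angle_deg = 0))
  path <- tempfile(fileext = ".png")
  write_overlay(f, lay, path)
  img <- png::readPNG(path)
  expect_equal(dim(img), c(dim(f), 3L))
  # at angle 0 the process ROI outline must hug the true process head:
  # red pixels appear within 1 px of the ground-truth process bounding box
  red <- img[, , 1] == 1 & img[, , 2] == 0 & img[, , 3] == 0
  stopifnot(any(red))
  pr <- which(mv$truth$process_mask == 1, arr.ind = TRUE)
  reds <- which(red, arr.ind = TRUE)
  expect_lte(max(reds[, 1]) , max(pr[, 1]) + 1)
  expect_gte(min(reds[, 1]) , min(pr[, 1]) - 1)
  expect_lte(max(reds[, 2]) , max(pr[, 2]) + 1)
})

test_that("a whole-frame ROI draws a rectangle hugging the border", {
  f <- matrix(5, 20, 20)
  lay <- structure(list(
    orientation = structure(list(angle_deg = 0, flipped = FALSE),
                            class = "polaroi_orientation"),
    rois = tibble::tibble(role = "process", order = 0L, top = 1L, left = 1L,
                          height = 20L, width = 20L),
    canvas_shape = c(20L, 20L), frame_shape = c(20L, 20L),
    valid_from_frame = 0L, threshold = 0
  ), class = "roi_layout")
  path <- tempfile(fileext = ".png")
  suppressWarnings(write_overlay(f, lay, path))
  img <- png::readPNG(path)
  red <- img[, , 1] == 1 & img[, , 2] == 0
  expect_true(any(red[1, ]) && any(red[20, ]) && any(red[, 1]) && any(red[, 20]))
})

test_that("layout JSON serialization captures angle and rectangles", {
  mv <- render_movie(deiters_spec(seed = 2, n_frames = 1))
  lay <- build_layout(mv$stack$frames[[1]])
  path <- tempfile(fileext = ".json")
  write_layout_json(lay, path)
  parsed <- jsonlite::fromJSON(path)
  expect_equal(parsed$angle_deg, lay$orientation$angle_deg)
  expect_equal(nrow(parsed$rois), nrow(lay$rois))
  expect_equal(parsed$valid_from_frame, 0)
})
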