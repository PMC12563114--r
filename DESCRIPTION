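Package: polaroi
Title: Objective Subcellular ROI Placement and Trace Extraction for
    Polarized Cells in Time-Lapse Fluorescence Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Semi-automatic analysis of single-cell fluorescence (e.g. Ca2+
    indicator) time-lapse recordings of polarized cells that carry one soma and
    one process, such as cochlear Deiters' cells or retinal photoreceptors.
    Segments the cell on the first frame by elbow-point (kneedle) histogram
    thresholding and Game-of-Life style noise pruning, levels the cell by a
    regression-line rotation, tiles equally sized regions of interest from the
    process head along the soma midline, extracts per-frame mean-intensity
    traces, detects preparation drift with a Wilcoxon signed-rank comparison
    against a background region and relocates the ROIs when the cell is lost,
    and computes background-corrected dF/F0 transient amplitudes and 50%-widths.
    Includes a parametric synthetic-movie generator with ground truth for
    validation, TIFF multipage input, CSV/JSON/PNG output, tidy accessors and
    ggplot2 visualisations, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    graphics,
    grDevices,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
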