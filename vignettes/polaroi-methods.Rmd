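---
title: "polaroi: methods and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{polaroi: methods and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polaroi)
```

## The problem

Subcellular Ca^2+^ imaging of a single labeled polarized cell — a cochlear
Deiters' cell with its phalangeal process, a photoreceptor with its outer
segment — asks where, not just whether, the intracellular signal changes.
The answer depends on the regions of interest (ROIs): their size, shape and
placement. Hand-drawn ROIs are irreproducible between analysts, and when the
preparation drifts during a long recording the ROIs silently slide off the
cell, deflating every amplitude measured afterwards.

`polaroi` makes the ROI definition objective and the drift handling explicit.
Given a multipage TIFF holding one labeled cell per field, it computes, on
the first frame only:

1. **Segmentation** (`clean_frame()`): an intensity histogram of the nonzero
   pixels (zeros are cropping artifacts) is dominated by the background; its
   mode estimates the background level and the curve strictly right of the
   mode is passed to the kneedle elbow finder. The elbow separates the
   background lobe from the flat cell tail and becomes the binarization
   threshold (strictly-above keeps a pixel). A Game-of-Life style pruning
   pass — survive with at least 3 of 8 neighbors — then removes speckle
   noise. In batch mode two pruning passes are run (or fewer if a pass
   changes nothing); interactively the user is shown the mask and asked.
2. **Leveling** (`estimate_rotation()`, `resolve_orientation()`): an OLS
   regression of foreground row on column gives the rotation that makes the
   cell horizontal; the column-profile of the leveled mask has two local
   maxima (soma hump, process hump) and if the smaller one sits left, 180° is
   added so the process always points right. The final angle is saved and
   applied verbatim to every later frame.
3. **ROI tiling** (`build_layout()`): the minimum of the profile between the
   two maxima is the soma/process boundary (the "intensity gap"); the
   foreground right of it is the process. A square ROI sized by the process
   thickness sits on the process head, and identical rectangles are tiled
   right-to-left along the soma midline — as many as fit, which is
   `floor(soma extent / ROI width)`. One more identical rectangle is placed
   in the emptiest far corner of the frame as the background reference.

Each subsequent frame is only rotated by the saved angle and averaged inside
the rectangles (`analyze_stack()`); on every fifth frame (configurable) a
Wilcoxon signed-rank comparison of cell-ROI pixels against the background ROI
checks whether the cell is still under its ROIs, and if not, the layout is
rebuilt on the current frame with the ROI size and shape unchanged.
Post-processing (`summarize_transients()`) gives background-corrected
dF/F~0~ = (F~t~ − F~0~)/F~0~ per ROI, with transient amplitude (trace
maximum) and response width (time between the 50%-of-maximum crossings on
the rising and falling phase, linearly interpolated).

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `alpha` | 0.05 | Significance level of the drift check. Drift is declared when the cell-vs-background test is **not** significant (`p >= alpha`), so a *smaller* `alpha` declares drift more readily and relocates more often. Choose by expected motion and time budget. |
| `check_every` | 5 frames | Drift-check cadence; checking every frame is safer and slower. |
| `max_clean_iterations` | 2 | Pruning passes in batch mode; each pass only removes pixels and a fixed point is reached quickly. |
| `n_bins` | auto | Histogram bins: one bin per integer level for integer images, 256 equal-width bins over (0, max] otherwise. |
| `smoothing_window`, `min_peak_separation` | 5, 10 px | Column-profile peak detection: moving-average window and the minimal distance between the two reported maxima, so small noise humps cannot impersonate the process. |
| `manual_angle_deg`, `manual_threshold` | off | Semi-automatic escape hatches that skip the regression fit or the elbow search. |
| `baseline_frames` | first 10% | dF/F~0~ baseline window. Stimulus timing is experimental metadata the program cannot infer; set this to the pre-stimulus period whenever it is known. |

## Numerical choices

* **Kneedle orientation.** The histogram tail right of the mode is decreasing
  and convex-ish by construction, so the elbow is the input point maximizing
  `(1 - y_norm) - x_norm` after min–max normalization; no sensitivity
  smoothing is applied and curve-direction auto-detection is deliberately
  out of scope. On a perfectly straight line the difference curve is
  identically zero and the first point is returned; shape violations warn
  rather than fail.
* **Ties and equalities.** Histogram-mode ties break toward the lowest
  intensity (more tail for the elbow search); pixels exactly at the
  threshold are background (conservative); profile-gap ties break toward the
  leftmost column (more soma retained for tiling); midline rows round half
  up.
* **Plateau peaks.** A strictly-greater-than-both-neighbors rule misses flat
  plateaus, and a clean horizontal process produces an exactly flat profile
  plateau; a run of equal smoothed values with strictly lower flanks is
  therefore treated as one peak at its center column.
* **Iterated leveling.** A single OLS fit underestimates steep angles on
  blobs of finite aspect ratio (regression dilution): for this cell geometry
  the one-shot error reaches ~5° at 60°. `estimate_rotation()` therefore
  iterates fit → rotate → refit; the fixed point has zero row/column
  covariance, i.e. the principal axis exactly horizontal, and the recovered
  angle is accurate to a fraction of a degree across ±60° (and converges
  even from 80°). An exactly vertical cell is a fixed point of the fit at 0°
  and is rejected downstream with the documented "process not
  distinguishable" error — a small tilt of the preparation is the remedy.
* **Rotation.** Bilinear inverse-mapping about the frame center, canvas
  grown to contain the content, zeros outside the support. Canvas growth
  preserves the center's pixel-grid phase (growth by even increments on the
  dominant axis), otherwise every near-zero rotation would shift the scene
  by half a pixel and dilute edge-row ROI means by ~10%. Masks are
  re-binarized at 0.5 after interpolation. Background ROIs are restricted to
  the rotated support so they never sample the zero-filled canvas corners.
* **Drift test pooling.** The check must produce one decision per frame.
  Concatenating every cell ROI's positional differences against the single
  background ROI reuses each background pixel once per ROI; that dependence
  makes the test anti-conservative (measured false-drift rate 34% at a
  nominal 5%). The cell ROIs are therefore averaged positionally first and
  the averaged pixels paired with the background ROI: one signed-rank test,
  correctly calibrated (measured false-drift rate ≈ 1 − α under the null).
  Zero differences are dropped; the exact null distribution is used for
  n ≤ 25 pairs and the normal approximation with continuity correction
  above that.
* **Relocation failure.** If re-segmentation fails mid-run (cell lost), the
  run keeps the stale layout, warns, and continues: partial data beats none
  on a long recording.
* **Half-maximum crossings** are linearly interpolated between the
  bracketing samples; nearest-sample widths are biased by up to a full
  sampling period. Non-uniform frame times are supported throughout.

## What the synthetic generator emulates — and what it does not

`synth_spec()` renders a single polarized cell: an elliptical soma (default
60×24 px full axes) with one thinner rectangular apical process (40×8 px)
attached at the pole, at any orientation and chirality, over a uniform
background. Intensities follow
`background + contrast × (1 + dF/F0(t))` per compartment — the fluorescence
*above background* scales with the programmed transient, so the
background-corrected dF/F~0~ recovered downstream equals the programmed peak
(0.8 for the process, 0.4 for the soma by default; the process responds more
strongly, mimicking its separate fluid compartment). Transients rise
linearly (4 frames) and decay exponentially (τ = 10 frames) from frame 40 of
120 at 1 Hz. Additive i.i.d. Gaussian noise (SD 3 against contrasts of
55–65, i.e. SNR ≈ 20) and step translations of the whole cell complete the
model. Compartment membership is evaluated in the cell's own coordinates, so
any orientation renders without interpolation; half-integer default centers
realize the nominal sizes exactly and keep the process symmetric on the soma
midline. A `cone_spec()` variant (thicker, longer process on a smaller soma)
exercises the morphology-dependent ROI count.

Deliberately absent: optical PSF blur, photobleaching, Poisson shot noise,
multiple cells, stained background structures, curved or branching
processes, rotational drift. Passing the validation suite therefore shows
the *algorithmic* contracts hold — segmentation accuracy at this contrast,
exact tiling arithmetic, calibrated drift statistics, exact trace math — not
that segmentation thresholds or drift power transfer to low-SNR laboratory
recordings with stained neighbors; on such data the interactive mode and the
manual overrides exist for a reason. A cell whose environment holds much
stray dye defeats the cleaning (the mask then follows the brightest
structure), and a vertical cell defeats the orientation stage; both
limitations are inherited from the method itself and are reproduced, not
patched, by this implementation.

Drift detectability is directional: a step *along* the cell axis mostly
keeps the (100 px long) cell under its ROIs, so the test — correctly —
does not fire; a *transverse* step of the soma's half-height or more takes
every ROI off the cell and is detected at the next check. The validation
uses a 15 px transverse step. Detection latency at exactly this step size
depends on whether one residual bright row remains under the soma ROIs, so
the first relocation may land one or three checks after the step; the
relocated layout restores the process-ROI mean to within a fraction of a
percent of its pre-drift value, while an uncorrected layout loses ~80% of
it.

## Validation sizes

The shipped test suite runs every module's contract at the following sizes
(chosen to exercise the asymptotic branches while keeping a full run around
a minute): 200 random curves against the brute-force kneedle oracle; 50
two-Gaussian images for threshold separation; all 512 3×3 neighborhoods for
the pruning rule; 26 orientation-recovery cases (13 angles × 2 chiralities);
1000 motion checks for the false-relocation level; exhaustive 2^n^ sign
enumeration for the exact Wilcoxon branch up to n = 10; and full 120-frame
end-to-end runs for drift correction, amplitude/width recovery and
determinism. `scripts/acceptance.R` recomputes the headline quantities from
scratch for any seed.

## Known limitations

One cell per field; one unbranched process; translation-only drift
correction by re-detection (no sub-pixel registration, by design — the
method trades registration machinery for a simple statistical check); ROI
rectangles are axis-aligned in the leveled frame; the CSV keeps the
first-epoch soma-ROI count if a relocation ever changes the number of ROIs
(extra ROIs are dropped, missing ones become `NA`).
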