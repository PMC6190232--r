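---
title: "Measuring cell self-rotation from microscopy video"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring cell self-rotation from microscopy video}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rotocell)
```

## The measurement problem

Certain cells spin about their own axis when suspended in a linearly
polarized AC electric field — for example in optically-induced
electrokinetic (OEK) microfluidic chips, where projected light patterns
create virtual electrodes on a photoconductive layer. The spin rate varies
with the applied frequency and bias, and this frequency response carries
information about the cell's dielectric properties (membrane capacitance,
cytoplasm conductivity), making the rotation speed a label-free readout of
cell state. Timing revolutions by eye with a stopwatch is tedious and
subjective; `rotocell` automates the measurement from an ordinary
microscopy video in which several cells may be moving at once.

The approach rests on one physical fact: a structurally inhomogeneous cell
looks different at different rotation angles. Its appearance is therefore
periodic in time with exactly the rotation period, and the similarity of an
image patch around the cell to a fixed reference patch peaks once per
revolution.

## The pipeline

Given a video at `f_fps` frames per second and a user-drawn rectangle
around the cell of interest in frame 1 (centre `(u, v)`, half-extents
`W`, `H`; kept as small as possible while covering the cell, to limit the
influence of non-cell pixels), the stages are:

1. **Background.** The pixel-wise mean of the first `N_bg` frames. A
   rotating or passing cell contributes a different appearance to each
   averaged frame, so moving structure washes out while the static scene
   stays sharp. `N_bg` must exceed the frames in one rotation cycle;
   the default is 40 frames.
2. **Segmentation.** Each frame's absolute difference from the background
   is binarized at the Otsu threshold (the smallest 8-bit level maximizing
   between-class variance of the 256-bin histogram; foreground is
   strictly greater), cleaned by morphological opening then closing with a
   flat disk of radius `R_struct` (default 3 px), and its 8-connected
   components are labelled. Each component is summarised by its rounded
   centroid, rounded maximum distance from the centroid, and pixel count.
3. **Tracking.** The component nearest the previous centre (initially the
   rectangle centre) becomes the cell's *moving region*, a square of
   half-extent `r_i`; a *search window* of half-extents `r_i + W`,
   `r_i + H` is recorded per frame. Frames segmenting to nothing carry the
   previous state forward with a warning.
4. **Reference selection.** The ROI is chained forward through the first
   `N_bg` frames by correlation matching, giving the maximum adjacent-frame
   correlations `C(i, i-1)`. Both the forward and the backward sequence
   are sorted ascending, and the frame minimizing the sum of its two
   ordinal ranks — the frame *least* like both neighbours, i.e. the most
   angle-distinctive appearance — becomes the reference.
5. **Correlation trace.** Every frame is matched against the reference
   patch: candidate centres are the pixels of that frame's moving region,
   and the patch similarity is the normalized correlation coefficient
   (mean-subtracted, variance-normalized, in `[-1, 1]`, invariant to
   illumination gain and offset). The per-frame maxima form the trace;
   the maximizing centres sample the cell's position.
6. **Peaks, sub-frame timing, speeds.** Strict local maxima of the trace
   above a threshold `lbound` mark completed revolutions. Each peak and
   its two neighbours determine a parabola whose vertex gives the peak
   time at sub-frame resolution; successive vertices give per-cycle
   speeds `n = 60 f_fps / (X_i - X_{i-1})` rpm, reported individually and
   as their arithmetic mean. The trajectory is read off the matched
   centres at the (integer) peak frames.

```{r example}
scene <- render_scene(scene_spec(
  cell_spec(center = c(60, 60), rpm = 54.76), n_frames = 158, seed = 2))
res <- run_pipeline(scene$seq, roi = c(60, 60, 17, 17), lbound = 0.85)
res
round(res$profile$speeds_rpm, 2)
```

## Parameters that matter

* `N_bg` (frames, default 40): background/reference span. Too small and
  the background retains cell structure; it must exceed one rotation
  period, so slow rotations need a larger value (the speed sweep below
  uses `period + 20` frames). It is not recomputed as the video runs.
* `R_struct` (px, default 3): structuring-element radius. Larger values
  suppress more noise but erase small or fragmented cells.
* `lbound` (default 0.5): correlation threshold separating
  once-per-revolution peaks from within-cycle ripples. Real traces have
  peaks near 1 and off-peak local maxima whose height depends on how
  self-similar the cell looks at partial rotations; the threshold is meant
  to be adjusted per experiment (see `sweep_lbound()`, which reports peak
  count versus threshold — a plateau of the count marks a robust choice).
  All synthetic experiments in this package use 0.85, which sits midway
  between the peak floor (~0.93) and the strongest off-peak maxima
  (~0.76) of the fixture family.
* `W`, `H` (px): ROI half-extents; minimal while covering the cell.

## The synthetic scene generator

No laboratory recordings ship with the package, so every claim is
validated on rendered videos with known ground truth
(`scene_spec()` / `render_scene()`). Defaults emulate the intended
conditions: 15 fps, 158 frames, cells of radius 15 px (a ~12 µm cell at
typical magnification), speeds of 10–150 rpm, additive Gaussian noise of
3 gray levels, 8-bit quantization.

Cells are textured disks rotated by a cumulative per-frame angle
(`360·rpm/(60·f_fps)` degrees) with bilinear resampling. The texture is
three soft Gaussian blobs of alternating sign clustered near the centre at
uneven bearings, over a weak smoothed random field. This shape is chosen
deliberately: features close to the centre have wide angular extent, so
the correlation peak is broad enough that even at 149 rpm and 15 fps —
where the nearest sampled frame can sit ~30° from the reference
orientation — the peak still clears the threshold; the uneven bearings and
signs leave no rotation angle at which the pattern maps onto itself, which
is the method's stated applicability condition (a rotationally symmetric
cell is unmeasurable by appearance). The cell's mean brightness (100) is
deliberately close to the background (70), with contrast carried by
internal structure, as for unstained cells in brightfield.

What the generator does *not* emulate: optics (point-spread function,
shot noise), out-of-plane tumbling, cell deformation, illumination drift,
and cell-cell contact. Passing tests therefore demonstrate the algorithm's
correctness under in-plane rotation with stationary illumination — not
robustness to every laboratory artefact.

## Numerical choices and degenerate inputs

* Rounding of reported pixel quantities is half-up (`floor(x + 0.5)`),
  so results do not depend on round-half-to-even parity.
* Pixel coordinates are 1-based `(row, column)` matrix indices; frame
  indices are 1-based. Colour frames are converted with BT.601 luma
  weights; >8-bit sources are linearly rescaled to 0–255.
* A zero-variance patch has no defined correlation; its coefficient is 0,
  so blank regions never outrank textured matches.
* Otsu on a constant image returns that constant, and the
  strictly-greater rule then yields an empty foreground.
* Argmax ties in the correlation search resolve to the first candidate in
  raster-scan order; rank-sum ties to the smallest frame index; equal
  nearest-component distances to the smaller (raster-order) label.
* Trace plateaus collapse to their first frame; endpoint frames are never
  peaks (no parabola support). Collinear parabola points return the
  integer peak position.
* Candidate centres for the correlation search are the pixels of the
  tracked *moving region*. The larger search window (moving region grown
  by the ROI half-extents) is carried in the track state, but matching
  against window-sized candidate sets admits patches dominated by static
  background, which can score ~0.7 against any template containing
  background margins (a partial-overlap artefact of normalized
  correlation) and generate spurious peaks; the moving region excludes
  them by construction.

## Tracked centres are approximate

For a cell rotating in place, the background holds the cell's own
time-averaged appearance, so the difference image within the cell is the
deviation of the texture from its rotational average — a pattern whose
thresholded centroid is generally offset from the geometric centre by a
texture-dependent bias (a few pixels; up to ~0.4 radius). The tracked
moving-region centres are therefore a coarse localization adequate for
windowing the correlation search, not a precision trajectory. The
trajectory the pipeline reports instead uses the *matched* ROI centres at
the peak frames, which realign the reference appearance and are accurate
to a pixel or two.

## The electrokinetic model

The physics module is a standalone companion (it does not feed the image
pipeline): the time-averaged dielectrophoretic force
`2πR³ε_m Re[K(ω)]∇|E_rms|²`; the real part of the Clausius–Mossotti
factor of a single-shell cell, evaluated with genuine complex arithmetic
from the relaxation times `τ_c = ε_c/σ_c`, `τ_1 = ε_m/σ_m`,
`τ_2 = C_mem R/σ_c`, `τ_2' = C_mem R/σ_m` (DC limit exactly 0.5); and the
self-rotation torque in a linearly polarized field, an odd, bounded
function of the dimensionless frequency `X = ωτ` that vanishes when the
particle/medium permittivity and conductivity ratios coincide. Default
parameters describe a ~12 µm lymphoblast-like cell in a low-conductivity
isotonic buffer (σ_m = 1.5×10⁻² S/m). Predicting a steady-state rotation
speed from the torque would require a rotational drag model, which is out
of scope.

```{r physics}
p <- cell_medium_params()
cm_real(p, 2 * pi * c(0, 75e3, 1e7))
```

## Problem sizes and design scope

The validation suite runs entirely on rendered videos of 120×120 to
120×220 px and 50–158 frames: the documented operating point (158 frames,
54.76 rpm, nine cycles), twenty replicates of a non-integer 16.43-frame
period for the sub-frame timing comparison, a five-point speed sweep over
11.1–149 rpm at 150 frames each, and a two-cell scene with a translating
target. These sizes keep every experiment deterministic and reproducible
from a single seed.

Known limitations: one cell of interest per run; in-plane rotation only
(out-of-plane tumbling breaks appearance periodicity); cells whose
appearance is rotation-invariant cannot be measured; very fast translation
(order of a cell diameter within the background span) contaminates the
background with a ghost trail and degrades tracking; and AVI/MP4
containers must be decoded to frame directories before loading.
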