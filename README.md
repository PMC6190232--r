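# rotocell

Automated measurement of the **self-rotational speed** and **motion
trajectory** of a single cell of interest in a multi-cell microscopy
video.

Some cells spin about their own axis in a linearly polarized AC electric
field (e.g. in optically-induced electrokinetic microfluidic chips), and
the spin rate versus applied frequency reflects the cell's dielectric
properties — a label-free readout of cell state. `rotocell` replaces
stopwatch timing of that spin with an image-matching pipeline, for
microfluidics and biological image-analysis practitioners.

## Method

A structurally inhomogeneous cell looks different at each rotation angle,
so its appearance is periodic with the rotation period. The pipeline:

1. **Background subtraction** — the background is the pixel-wise mean of
   the first `N_bg` frames, `f_B = (1/N) Σ f_i`; moving cells wash out.
   Each frame's difference `|f_i − f_B|` is Otsu-thresholded, cleaned by
   morphological opening/closing (disk radius `R_struct`), and its
   8-connected components give per-frame moving regions (centroid,
   radius).
2. **Tracking** — the component nearest the previously tracked centre is
   the cell of interest; only the first-frame rectangle is manual.
3. **Automatic reference frame** — the frame whose cell appearance is
   least like both temporal neighbours (minimum rank-sum of adjacent
   normalized correlations) becomes the matching template.
4. **Correlation trace and speed** — the per-frame maximum normalized
   correlation coefficient against the reference peaks once per
   revolution. Each peak is refined to sub-frame time by a three-point
   parabolic fit; per-cycle speed is `n = 60 f_fps / (X_i − X_{i−1})` rpm.
   The matched centres at the peak frames give the trajectory.

A standalone physics module provides the time-averaged DEP force
`⟨F⟩ = 2πR³ε_m Re[K(ω)] ∇|E_rms|²`, the real part of the single-shell
Clausius–Mossotti factor `K(ω)`, and the self-rotation torque in a
linearly polarized field. A seeded synthetic-video generator renders
ground-truth-annotated rotating cells so every stage is testable.

## Worked example

```r
library(rotocell)

# a synthetic 158-frame video at 15 fps: one cell rotating at 54.76 rpm,
# noise sigma 3 gray levels
scene <- render_scene(scene_spec(
  cell_spec(center = c(60, 60), rpm = 54.76), n_frames = 158, seed = 2))

res <- run_pipeline(scene$seq, roi = c(60, 60, 17, 17), lbound = 0.85)
res
#> <rotocell_result>
#>   frames: 158 at 15 fps; reference frame: 5
#>   peaks: 10, cycles: 9
#>   mean speed: 54.76 rpm
round(res$profile$speeds_rpm, 2)
#> [1] 54.83 54.72 54.78 54.65 54.90 54.61 54.88 54.82 54.61
```

The ten trace peaks bound nine complete revolutions; the per-cycle
speeds scatter by well under 1% around the true 54.76 rpm, and their mean
is the reported speed. `res$profile$trajectory` holds the cell's position
at each peak frame, and `write_results()` saves `cycles.csv`,
`trajectory.csv` and `summary.json`.

A command-line front end is installed at `inst/cli/rotocell`
(subcommands `extract`, `simulate`, `sweep-lbound`, `dielectric`):

```sh
Rscript inst/cli/rotocell simulate --rpm 54.76 --frames 158 --out demo
Rscript inst/cli/rotocell extract --input demo --fps 15 \
    --roi 60,60,17,17 --lbound 0.85 --out demo-results
```

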