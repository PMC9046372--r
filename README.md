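# pfesim

Simulation-based assessment of **pupil foreshortening error (PFE)** in
head-mounted eye tracking.

Pupillometry needs pupil-size measurements that do not depend on where the
subject is looking. In head-mounted trackers a near-eye camera films the eye
from close up, and as the eye rotates away from the camera the apparent 2D
pupil shrinks and becomes elliptical — through perspective, pupil tilt, and
refraction at the cornea. The resulting gaze-dependent bias is comparable to
the few-percent pupil responses that experiments try to measure.

`pfesim` raytraces labeled images of schematic (LeGrand-model) eyes with
corneal refraction and quantifies the gaze-angle dependency of three
per-frame pupil-size measures:

| method | output | idea |
|--------|--------|------|
| `2D-0p` | px | major axis of the ellipse fitted to the 2D pupil |
| `3D-1p` | mm | refraction-unaware 3D eye-model fit: the pupil ellipse is unprojected to a 3D circle and scaled along its viewing cone until tangent to an eye sphere of radius 12 mm, located beforehand by least-squares intersection of the per-frame gaze lines |
| `3D-4p` | mm | refraction-aware: a degree-3 polynomial correction, trained on raytraced (measured, truth) tuples of an average eye, applied to the `3D-1p` outputs |

Gaze-angle dependency is summarised by the field's circularity-binned
statistic: per recording, relative pupil sizes (value / baseline median) are
averaged in ten circularity bins (circularity `C` = minor/major axis of the
pupil ellipse, a gaze-angle proxy) with confidence weights and normalized by
the top bin `C` in [0.9, 1.0]; the population level is the mean ± sd of
those curves over recordings.

## Worked example

Sixty simulated recordings (random physiology from the configured normal
distributions, random eyeball position, one constant pupil radius each, 100
random gaze angles per recording, corneal refraction on), measured with all
three methods and aggregated:

```r
library(pfesim)

cfg   <- pfe_config(resolution = 200, n_frames = 100)
model <- train_correction_model(pfe_config(resolution = 200, n_frames = 40),
                                n_runs = 200, seed = 90001)
ex    <- run_pfe_experiment(cfg, n_runs = 60, seed = 1, model = model)

for (m in names(ex$population)) {
  p <- ex$population[[m]]
  cat(sprintf("%-6s", m), sprintf("%6.2f", (p$mean - 1) * 100), "\n")
}
```

```
2D-0p      NA     NA     NA  -1.59  -3.46  -4.81  -5.59  -4.55  -2.53   0.00
3D-1p      NA     NA     NA  11.10   6.97   4.53   3.07   1.78   0.86   0.00
3D-4p      NA     NA     NA   3.20   0.50  -0.04  -0.04  -0.02   0.01   0.00
```

Each row is the percent deviation of the population-mean normalized relative
pupil size from 1, per circularity bin (bin lower edges 0.0 … 0.9; `NA`
bins are not reached under these viewing geometries). Reading the `C` in
[0.4, 0.5) column: the major axis **underestimates** pupil size by 3.5 %,
the uncorrected model fit **overestimates** it by 7.0 %, and the
refraction-corrected fit stays within 0.5 % of the reference — i.e. only
the refraction-aware method is gaze-angle independent at the population
level. On held-out recordings the correction also reduces the radius RMSE
from 0.20 mm to 0.02 mm and the eye-sphere depth bias from −2.8 mm to
−0.05 mm (`analysis/02_train_correction.R`).

The numbered scripts under `analysis/` run the full study as a narrative:
apparent-area demonstration (`01`), correction training (`02`), the
noiseless population study (`03`), and the pupil-size-noise robustness
check plus the 0–60° error sweep (`04`). Outputs land under `results/`.

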