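# gazefilter

Stable video-based gaze estimation from infrared eye imagery.

In a pupil-corneal-reflection (PCCR) gaze tracker, an eye camera images a
dark pupil and the bright corneal reflection (Purkinje glint) of an infrared
illuminator. The per-frame feature is the PCR vector
**v** = **p**<sub>pupil</sub> − **p**<sub>glint</sub> (pixels), mapped to an
on-screen point of regard (POR) by a second-order polynomial calibrated on a
3×3 grid:

    s_x = c₀ + c₁ vx + c₂ vy + c₃ vx·vy + c₄ vx² + c₅ vy²   (and likewise s_y)

Because the map amplifies sub-pixel PCR noise into tens of screen pixels,
the estimated POR fluctuates even during steady fixation. `gazefilter`
implements a complete, hardware-free pipeline to study and suppress that
fluctuation:

- **Synthetic eye scenes** — supersampled rendering of pupil ellipse, iris,
  glints, eyelid occlusion and sensor noise, with exact per-frame ground
  truth (`render_eye_frame()`, `render_sequence()`).
- **Pupil localization** — first-frame dark-blob detection, then kernelized
  correlation-filter (KCF) tracking with grayscale features: ridge
  regression over all cyclic shifts of the template, solved in the Fourier
  domain via circulant-matrix diagonalization
  (`detect_pupil()`, `kcf_init()`, `kcf_track()`, `track_sequence()`).
- **Pupil/glint parameters** — low-threshold segmentation with morphological
  glint-hole closing; star-ray edge selection restricted to the left/right
  pupil flanks (angle windows [−70°, 60°] and [120°, 250°]), so eyelid edges
  stay out of the direct least-squares ellipse fit; intensity-weighted glint
  centroiding (`segment_pupil()`, `star_ray_edges()`, `fit_ellipse()`,
  `glint_center()`).
- **Gaze mapping** — 9-point polynomial calibration and POR evaluation
  (`calibrate_mapping()`, `map_por()`).
- **Adaptive Kalman filtering** — constant-velocity (CV) and
  constant-acceleration (CA) filters on the PCR vector whose
  measurement-noise covariance R rises with a gaze-speed proxy (eye-image
  difference, logistic gate, gaze-point displacement) and decays
  geometrically when the gaze settles; blink frames advance by prediction
  only (`kf_model()`, `filter_sequence()`, `update_R()`).
- **Evaluation tasks** — the nine-point fixation task and the
  smooth-pursuit polyline with dwells, reporting per-point mean POR error,
  error variance, POR covering circles, tracking precision curves and
  post-saccade transient amplitudes (`run_gaze_task()`,
  `run_saccade_task()`, `precision_curve()`).

The package is aimed at eye-tracking researchers and engineers who want a
reproducible, fully observable testbed for gaze-filtering behavior.

## Worked example

Simulate the nine-point fixation protocol at observation level (a perfect
extractor with i.i.d. PCR noise and a constant headset-slippage offset
between calibration and task), then compare raw, CV-filtered and CA-filtered
PORs:

```r
library(gazefilter)

report <- run_gaze_task(run_config(task_frames_per_point = 200, seed = 42),
                        render = FALSE)
print(report)
#> eval_report: gaze task (seed 42, parameter-level)
#> overall error statistics (screen px / px^2):
#>  variant mean_error  variance
#>   kal_ca   53.83017  76.19359
#>   kal_cv   53.66794  46.60371
#>      raw   54.11955 119.86474
```

The mean POR error (~54 screen px) is dominated by the slippage offset and
barely moves under filtering — smoothing cannot fix a calibration bias. The
*variance* of the per-frame errors drops from ~120 px² (raw) to ~47 px²
with the CV filter and ~76 px² with the CA filter: filtering stabilizes the
POR cloud, and the stiffer CV model stabilizes it most during fixation. The
same run reports per-point tables (`report$per_point`) and the minimum
covering circle of each POR cloud (`report$circles`).

The same pipeline runs end to end on rendered imagery — detection, KCF
tracking, star-ray ellipse fitting, glint centroiding, calibration,
filtering — with `run_gaze_task(run_config(seed = 1), render = TRUE)`
(a few minutes for 270 rendered 640×480 frames).

A command-line interface wrapping these functions ships with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","gazefilter.R",package="gazefilter"))')" \
    run-all --task gaze --seed 1 --out out/
```

with subcommands `simulate`, `track`, `extract`, `calibrate`, `filter`,
`evaluate` and `run-all` operating on the documented PNG/CSV/JSON artifacts.

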