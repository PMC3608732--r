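# ivtrace

Analysis of tumor vascular response in intravital window-chamber
time-lapse fluorescence microscopy.

Experiments of this kind inject a fluorescently labeled dextran into a
mouse carrying a dorsal window chamber and image the tumor vasculature for
an hour: every 20 s for 2 min, a 20 s pause in which the treatment
(electroporation, EP, or electrochemotherapy, ECT) is delivered, another
2 min at 20 s intervals, then every 2 min for 58 min. `ivtrace` turns such
a stack into quantitative readouts, for experimentalists quantifying
vascular-targeted interventions:

* **Registration** - integer-translation alignment of all frames to the
  first (pre-treatment) frame.
* **Segmentation** - Otsu threshold + opening + small-component removal on
  a maximum-intensity projection, with explicit hand-correction mask
  inputs; compartments: vessels (intravascular) vs. tumor ROI minus
  vessels (extravascular).
* **Morphometry** - per-timepoint perfused-vessel calls and, from the
  skeleton of the perfused mask: vascular length `L_V`, vascular area
  `A_V`, tumor area `A_T`, functional vascular density
  `FVD = L_V / A_T` (um^-1) and length-weighted perfused diameter
  `D_V = A_V / L_V` (um).
* **Kinetics** - compartment mean-intensity curves normalized to their
  maximum (Imax = 100%); filling time, vascular-lock duration (with
  censoring) and extravascular leakage onset.
* **Statistics** - Shapiro-Wilk screen, t test / one-way ANOVA, all-pairs
  Holm-Sidak adjusted comparisons, SEM reporting.
* **Synthetic scenes** - a seeded generator (vessel networks, tracer
  pharmacokinetics, perfusion scenarios, noise, stage drift) with exact
  analytic ground truth, used to validate every stage.

## Worked example

Simulate a control scene under the study conditions and analyze it:

```r
library(ivtrace)
cfg <- default_config("control")
scene <- simulate_run(cfg, seed = 1, out_dir = "demo")
res <- analyze_run("demo/stack.tif", cfg, out_dir = "demo-analysis")
str(res$readouts)
```

```
List of 7
 $ filling_time_s     : num 120
 $ filling_fraction   : num 80
 $ baseline_FVD_per_um: num 0.00643
 $ lock_duration_s    : num 0
 $ lock_censored      : logi FALSE
 $ leakage_onset_s    : num 730
 $ Imax               : num 20101
```

The tracer reaches 80% of Imax 120 s after injection (the generator's
filling time constant is `120/log(5)` s, i.e. 80% at 2 min by
construction); there is no vascular lock in a control scene
(`lock_duration_s = 0`). The `leakage_onset_s` value on this no-leakage
scene is a false alarm of the 2-sigma excursion detector on an extremely
low-noise series - reported onsets should always be read together with the
extravascular curve (see the vignette's limitations section).

```r
m <- res$morphometry
head(m[m$time_s >= 80, ], 4)
```

```
  time_s L_V_um A_V_um2 A_T_um2 FVD_per_um D_V_um
5     80   1189   24327  184754   0.006434  20.46
6    100   1189   24327  184754   0.006434  20.46
7    120   1189   24327  184754   0.006434  20.46
8    140   1189   24327  184754   0.006434  20.46
```

The scene's ground truth is `FVD = 0.00663 um^-1`, `D_V = 20 um`
(calibrated): the pipeline reads `0.00643 um^-1` and `20.46 um` - within a
few percent, the raster/skeleton bias discussed in the vignette. An EP
scene (`default_config("EP")`) locks all vessels for 600 s and then
re-perfuses half of them; `analyze_run` then reports a
`lock_duration_s` of ~600 and `lock_censored = FALSE`, while an ECT scene
keeps `FVD = 0` for the whole hour and is censored.

A thin command-line front end is installed with the package
(`system.file("cli", "ivtrace", package = "ivtrace")`) with subcommands
`simulate`, `analyze` and `compare`; example YAML configurations are in
`inst/extdata/`.

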