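# nucstack

Quantifying cell migration and homing in fibrous 3D scaffolds from
fluorescence z-stacks of stained nuclei.

## The problem

Electrospun nonwoven mats are widely used as tissue-engineering scaffolds:
cells seeded on top of the mat divide, migrate along and between the fibres,
and colonise the material's depth. Whether a candidate material supports that
colonisation is usually judged from confocal z-stacks of a nuclear stain
(e.g. Hoechst), scanned layer by layer through the mat. Turning such stacks
into numbers is awkward for two reasons:

1. **A nucleus is visible in several focal planes.** Counting detections per
   layer over-counts every cell once per plane it bleeds into; each physical
   nucleus must be assigned to exactly one layer — the one where it is in
   focus.
2. **Raw per-layer counts are hard to compare across materials and days.**
   A summary statistic is needed that separates "cells sitting on the
   surface" from "cell mass actually penetrating the depth".

`nucstack` implements a complete pipeline for this, aimed at biomaterials
groups who profile cell infiltration in scaffolds:

* per-layer nucleus segmentation (deterministic classical path —
  threshold, hole filling, watershed, area filter — plus an optional
  trainable segmenter), with tiling for large fields;
* focus scoring (variance of Laplacian or Tenengrad) and SSIM comparison of
  candidate duplicates across layers, so each nucleus is counted once, in
  its sharpest layer;
* nuclear morphometrics (areas, major/minor axis ratios, log-normal fits,
  Tukey/Friedman group comparisons);
* depth-kinetics summaries, described next;
* a seeded synthetic-stack generator with exact ground truth, used to
  validate all of the above end to end.

## The statistic

Let `C_z` be the number of nuclei assigned to the layer at depth `z`
(z-step 7 µm by default) and `C_summ` their total. The **conversion value**

    alpha(z) = sum_{z' <= z} C_z' / C_summ

is the cumulative fraction of cells at or above depth `z` — an analogue of
conversion curves in reaction kinetics. Its shape distinguishes colonisation
regimes, fitted by least squares:

* `alpha(z) = 1 − exp(−kz)` — cells settle at the seeding surface;
* `alpha(z) = max(0, 1 − exp(−k(z − z0)))` — the mass has shifted below
  depth `z0`;
* `alpha(z) = z^n / (K^n + z^n)` — a Hill form: sigmoidal colonisation with
  half-depth `K` and cooperativity `n`.

The **migration activity** combines depth penetration with proliferation.
For `alpha` in {0.1, …, 0.9}, depth `z(alpha)` is read off the conversion
curve by monotone interpolation and each step is scored as

    activity(alpha) = (alpha / z(alpha)^2) * (C_summ / t_d)

where `C_summ / t_d` is the proliferation rate (cells/day over the
observation interval). A linear fit of activity against `alpha` gives the
migration-activity tangent `(1/z^2)(C_summ/t_d)`; fast, deep colonisation
by a proliferating culture shows up as large activity at high `alpha`.
`activity_share()` reports what fraction of total activity the shallowest
given fraction of cells accounts for.

## Worked example

```r
library(nucstack)

params  <- stack_params(n_layers = 14, width_px = 512, height_px = 512,
                        n_nuclei = 60, seed = 42)
sim     <- generate_stack(params)                  # stack + ground truth
masks   <- segment_stack(sim$stack, seg_config())  # one pooled Otsu threshold
records <- link_and_assign(sim$stack, masks, link_config())
profile <- build_count_profile(records, 14, day = 1)
print(profile)
#> count_profile: 14 layers, C_summ = 60, day 1
#>   C_z: 0 5 1 7 8 4 9 7 4 1 4 3 2 5

fit <- fit_conversion_model(conversion_curve(profile), "best")
print(fit)
#> kinetic_fit: hill (converged), RSS = 0.006959
#>         n         K
#>  2.923335 44.274146
```

The 60 simulated nuclei were placed with a Hill depth profile
(`n = 3, K = 40 µm`); model selection picks the Hill form and recovers the
parameters from the counts alone. The activity transform then summarises the
depth kinetics:

```r
activity <- migration_activity_curve(conversion_curve(profile),
                                     rate = profile$C_summ / 1)  # t_d = 1 day
print(activity)
#> migration_activity: rate 60 cells/day, slope -0.009845
#>   alpha     z_um    activity
#> 1   0.1 21.00000 0.013605442
#> ...
#> 9   0.9 87.50000 0.007053061
activity_share(activity, 0.5)
#> [1] 0.576
```

Here the shallowest half of the cells carries 57.6% of the migration
activity — close to uniform, as expected for a culture whose mass sits at
mid-depth. Against the generator's ground truth, every nucleus was assigned
to its true layer with no duplicates (`evaluate_against_truth()`).

`run_pipeline(run_config(...))` chains all stages and writes `nuclei.csv`,
`profile.csv`, `fits.json`, `activity.csv`, plots and a log. A thin CLI with
verbs `simulate`, `segment`, `profile`, `kinetics` and `run-all` is installed
under `inst/scripts/nucstack`.

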