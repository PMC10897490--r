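# mitoquant

Quantification of mitochondrial dynamics from microscopy: network
morphology, tethering kinetics, ER contact sites, and matrix-mixing
fusion assays.

## What it is for

Mitochondria continuously fuse and divide, and experiments probing that
balance lean on a small set of standard image-based readouts:

* **Shape and network morphology.** Cells are segmented into individual
  mitochondria; each object gets an **aspect ratio** AR = a/b, the
  major/minor axis ratio of the ellipse with the same second central
  moments as the object (AR = 1 for a round mitochondrion, larger for
  tubules). Whole cells are classified into the classical categories —
  *Elongated* (> 90% tubular objects), *Fragmented* (> 90% round),
  *Hyperfused* (one reticular component dominating the network),
  *Collapsed* (area clumped around the perinuclear centroid) — with
  explicit, reproducible decision rules instead of by-eye calls.
* **Tethering kinetics.** In two-channel time-lapses, fluorescent
  tethering foci are detected, linked into tracks, and scored as
  tethering events while a focus joins two mitochondria. Events strictly
  longer than 15 s are kept (excluding kiss-and-run contacts), each ends
  in *fused*, *separated*, or *censored*, and conditions are compared by
  mean dwell time (Welch t-test delegated to `stats::t.test`).
* **ER–mitochondria contact sites.** From traced outlines in physical nm
  coordinates, ER regions within 60 nm of the nearest mitochondrial
  surface become contact sites with an arc length and a GAP distance
  (binned 0–15 / 15–30 / 30–60 nm), plus per-cell contacts per
  mitochondrion and percent of mitochondrial perimeter covered.
* **PA-GFP fusion assay.** Photoactivated matrix GFP spreads through
  fused networks; the GFP-positive area at 0, 5, 10 min is normalized to
  the initially photoactivated area.

Because such studies rarely ship raw images, every modality has a
**ground-truthed synthetic generator** (`gen_morphology_image`,
`gen_timelapse`, `gen_em_scene`, `gen_pagfp_series`): deterministic under
a seed, returning the rendered data *and* the true object table, so each
analysis stage is verifiable end to end without a microscope.

## Worked example

Simulate eight cells (two per morphology class), segment, and classify:

```r
library(mitoquant)
cfg <- default_config(seed = 7)
out <- file.path(tempdir(), "demo")
run_pipeline(cfg, stages = c("simulate", "segment", "classify"), out_dir = out)
read.csv(file.path(out, "classes.csv"), comment.char = "#")[,
  c("cell_id", "class", "tubular_fraction", "mean_ar")]
#>    cell_id      class tubular_fraction mean_ar
#> 1 cell_001  Elongated                1   10.18
#> 2 cell_002  Elongated                1   11.19
#> 3 cell_003 Fragmented                0    1.03
#> 4 cell_004 Fragmented                0    1.03
#> 5 cell_005 Hyperfused                0    1.28
#> 6 cell_006 Hyperfused                0    1.10
#> 7 cell_007  Collapsed                0    1.03
#> 8 cell_008  Collapsed                0    1.03
```

All eight recovered classes match the generator's ground truth
(`cells_truth.csv`); tubular cells average AR ≈ 10–11, round ones ≈ 1.
Every CSV carries the configuration hash, and rerunning with the same
config and seed reproduces byte-identical files.

Tethering kinetics on a synthetic time-lapse (3 s frame interval,
dwell times 20 + Exp(20) s):

```r
tl <- gen_timelapse(timelapse_spec(n_events = 6,
        dwell_dist = list(name = "shifted_exp", shift = 20, mean = 20),
        p_fusion = 0.6, seed = 2))
ev <- track_tethering(tl$foci, tl$mito)
tether_stats(ev)$summary
#>   condition n_events n_censored mean_duration_s sem_duration_s fruitful unfruitful
#> 1       all        6          0            32.5            5.1        4          2
```

Six of six programmed events are recovered; durations are multiples of
the 3 s frame interval and all exceed the strict 15 s filter; "fruitful"
counts events that ended in fusion.

A thin command-line wrapper over the same functions lives at
`inst/cli/mitoquant.R`:

```sh
Rscript inst/cli/mitoquant.R simulate segment classify --out results_dir --seed 7
```

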