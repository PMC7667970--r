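# mucometry

Quantification of intestinal mucus barrier function from microbead-probed
measurements, for researchers running (or simulating) the classic
explant assay: live mucosal tissue mounted in a perfusion chamber, 1 µm
fluorescent beads sedimented onto the mucus surface, two-channel confocal
z-stacks of tissue and beads, and micromanipulator thickness readings taken
every 15 minutes to follow mucus growth.

The package implements:

* **Normalized penetrability** — the per-stack statistic
  `AUC = ∫ f(x) dx`, where `f` is the bead frequency distribution over
  tissue-to-bead z distance, normalized to its maximum, re-anchored at the
  mucus surface (the maximum-frequency bin), and cropped above the surface.
  `x` is depth below the mucus surface in µm; an impenetrable layer scores
  0, deeper bead penetration scores higher. Bead-derived thickness is the
  mean tissue-to-bead distance; per-mouse values are medians across stacks.
* **Stack analysis** — tissue-surface extraction (topmost supra-threshold
  voxel per column), 3D connected-component bead detection with
  intensity-weighted centroids, and surface-interpolated bead distances.
* **Mucus growth kinetics** — pooled OLS of thickness on time
  (rate in µm/min, SE, r²).
* **Cohort statistics** — HOMA-IR (`glucose × insulin / 22.5`), the
  D'Agostino–Pearson normality gate, normality-dispatched two-group tests
  (unpaired t vs Mann–Whitney U with an exact small-sample path) and
  correlations (Pearson vs Spearman, regression line only when
  significant), and >14.5 mM diabetes labelling.
* **A ground-truthed generator** — tissue surfaces, bead populations with a
  configurable penetration fraction and depth law, rendered two-channel
  TIFF stacks, thickness time series, and full lean/obese or
  normoglycemic/diabetic cohorts with separated vs co-housed scenarios —
  plus a closed-form expectation of the penetrability statistic
  (`expected_penetrability()`) to validate the whole pipeline against.

See the methods vignette (`vignettes/mucometry-methods.Rmd`) for the models,
conventions and design choices.

## Worked example

Simulate the reference lean vs ob/ob cohort (10 mice per genotype, three
stacks of 300 beads each, thickness series at 5 locations × 4 time points)
and run the full analysis:

```r
library(mucometry)
rep <- run_pipeline(cohort_config_obob("separated"), seed = 7)
rep$per_mouse[c(1, 11), c("mouse", "group", "body_weight_g", "homa_ir",
                          "auc_um", "thickness_um", "rate_um_per_min")]
#> # A tibble: 2 × 7
#>   mouse    group body_weight_g homa_ir auc_um thickness_um rate_um_per_min
#> 1 lean_01  lean           32.5    7.67   2.99         76.8            1.69
#> 2 ob_ob_01 ob/ob          57.2   26.1   14.0          38.6            1.15

rep$tests[, c("variable", "mean1", "mean2", "method", "p_value")]
#> # A tibble: 7 × 5
#>   variable              mean1  mean2 method                      p_value
#> 1 auc_um                 3.02 13.5   t_test                     2.03e-17
#> 2 rate_um_per_min        1.95  0.939 t_test                     5.80e- 8
#> 3 thickness_um          76.3  39.2   t_test                     8.38e-29
#> 4 body_weight_g         30.9  53.0   mann_whitney_normal_approx 1.83e- 4
#> 5 fasting_glucose_mM     8.10 10.2   t_test                     2.46e- 3
#> 6 fasting_insulin_uU_ml 18.9  70.2   t_test                     2.34e-13
#> 7 homa_ir                6.68 31.7   t_test                     2.56e-11
```

The obese group shows the expected phenotype: ~4-fold higher normalized
penetrability (beads reach deeper into the layer), a thinner bead-derived
layer, and a halved growth rate, alongside the metabolic contrast. Rerunning
with `cohort_config_obob("cohoused")` abrogates the three mucus contrasts
while the metabolic ones remain.

The image route works the same way from a rendered stack:

```r
m     <- mucus_model(thickness = 80, penetration = 0.3)
surf  <- simulate_tissue_surface(64, 64, pixel_size = 1.25, mean_z = 20,
                                 amplitude = 3, seed = 1)
beads <- simulate_beads(surf, m, 40, seed = 2, min_spacing = 8)
st    <- render_stack(surf, beads, z_step = 2)
d     <- bead_distances(detect_beads(st), extract_tissue_surface(st))
penetrability(data.frame(mouse = "demo", stack = 1, d_um = d$d_um))
#> # A tibble: 1 × 8
#>   mouse stack auc_um thickness_um n_beads n_cropped_above n_below_tissue ...
#> 1 demo      1   6.09         63.4      40               0              0
```

All 40 beads are recovered and the AUC sits near its analytic expectation
for this model (`expected_penetrability(m, 5)` = 4.58 µm; single-stack
values scatter around it at n = 40 beads).

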