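# mguard

Does mate-guarding cost a male energy? In many primates the top-ranking
males monopolise females by following them closely for days at a time —
yet often less than they theoretically could, suggesting a hidden cost.
`mguard` is an R package for answering that question from standard field
data on group-living primates: minute-resolution focal scans, GPS
tracklogs, monthly fruit-phenology surveys, and urinary C-peptide (UCP)
assays, a non-invasive physiological index of energy balance (ng
C-peptide per mg creatinine; higher = better energetic status). It was
built around a study of wild long-tailed macaques (*Macaca fascicularis*)
at Ketambe, Sumatra — three groups, the alpha and beta male of each,
2,088 focal hours over 584 male-days — and implements that study's full
analysis pipeline as tested, reusable code.

## What it computes

**Mate-guarding segmentation.** A male is mate-guarding (MG) when he
follows a female for more than five consecutive minutes at ≤ 10 m; if she
moves beyond 10 m and he does not re-follow within 2 minutes, the episode
has ended (back-dated to the last qualifying minute). `segment_episodes()`
applies these rules on the one-minute scan grid; days where MG exceeds
50 % of observation time are *extensive* MG days, and runs of consecutive
extensive days form *MG periods* (`daily_mg_summary()`, `mg_periods()`).

**Daily energetics metrics.** Activity budgets with feeding precedence,
diet composition over feeding scans, and *restlessness* — the fraction of
adjacent minutes with a locomotion/position change, 0–1
(`daily_activity()`). Horizontal travel from GPS fixes subsampled at
15 ± 5 min, which cuts apparent stationary travel due to ~10 m canopy fix
error from 600 to 40 m/h, with the daily rate
`Σ 4·D_i / n` (`subsample_fixes()`, `hourly_distance()`,
`expected_error_path()`). Vertical travel from canopy-height categories
via their band midpoints, e.g. 7.5 m for category 2 (`vertical_rate()`,
`height_from_category()`). Monthly percent-of-trees-fruiting indices
assigned to the days each survey covers (`fruit_index()`,
`assign_index()`). Creatinine-indexed UCP with assay-sensitivity and
storage-duration filters (`ucp_index()`, `filter_storage()`). I&SI linear
dominance orders from bared-teeth matrices (`isi_rank()`).

**Inference.** For each response (% time feeding, % fruit in diet, height
climbed/h, distance travelled/h, restlessness, and UCP), a Gaussian
linear mixed model fitted by ML with random intercepts for group and
male, z-standardized predictors, a Gaussian-kernel temporal
autocorrelation covariate built from null-model residuals (kernel width
selected from {0.5, 1, 2, 4, 8, 16} days by likelihood), a full-vs-null
likelihood ratio test on the mate-guarding term, and VIF collinearity
checks (`fit_model()`, `lrt()`, `vif_table()`, `mg_model_specs()`).

**Synthetic studies.** `generate_study()` emits a complete raw-data
bundle — scans, GPS, phenology, rainfall, urine, interaction matrices —
with known ground truth (planted MG minutes, effect sizes, hierarchies),
structured like the original study; `simulate_model_table()` generates
model tables directly for calibration/power work. See the methods
vignette (`vignettes/mate-guarding-energetics.Rmd`) for every modelling
choice and default.

## Worked example

The packaged demo simulates a 120-day study (three groups, six focal
males, ≈ 320 usable male-days) with the study-sized effects planted —
mate-guarding depresses feeding, fruit intake and climbing; no effect on
distance, restlessness or UCP — then runs segmentation, metrics, table
assembly and all seven model fits:

```r
library(mguard)
cfg <- yaml::read_yaml(system.file("extdata", "demo_config.yaml", package = "mguard"))
res <- run_pipeline(cfg)   # ~1 min; outputs under cfg$out_dir
res$lrt_summary
```

```
              model n_males n_obs df  chisq         p
1       pct_feeding       6   315  1 489.34 1.98e-108
2 pct_fruit_in_diet       6   315  1 227.92  1.69e-51
3 hourly_vertical_m       6   315  1 186.62  1.74e-42
4 hourly_distance_m       6   262  1   7.19  7.34e-03
5      restlessness       6   315  1   0.40  5.28e-01
6            ucp_mg       6    86  1   0.05  8.27e-01
7          ucp_rank      12   240  1   0.35  5.53e-01
```

The three planted effects are recovered decisively; restlessness and both
UCP models are null as planted. Distance travelled — also a planted null —
happens to cross 0.05 at this seed, a useful reminder of what a p-value
is. Each fit carries the full detail:

```r
res$fits$pct_feeding
```

```
Mixed model: pct_feeding ~ mg_pct + fruit_index + rainfall_mm + ac_term + (1 | group_id) + (1 | male_id)
n = 315 rows, 6 males; ML logLik = 712.97; AC kernel sigma = 16 days
Full vs null LRT: chisq = 489.34, df = 1, p = 1.983e-108
         term  estimate      se      t
1 (Intercept)  0.305509 0.00511  59.83
2      mg_pct -0.051575 0.00150 -34.39
3 fruit_index -0.030268 0.00145 -20.86
4 rainfall_mm  0.000354 0.00142   0.25
5     ac_term -0.518729 0.12795  -4.05
```

Here `mg_pct` is standardized, so −0.052 means: one SD more time spent
mate-guarding costs about 5 percentage points of daily feeding time.
`scripts/pipeline.R` wraps the same pipeline for the shell.

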