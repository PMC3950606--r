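---
title: "Mate-guarding energetics: models, metrics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mate-guarding energetics: models, metrics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`mguard` operationalises a field-endocrinology question: does mate-guarding
(MG) — a male following a female closely and persistently to exclude rival
males — carry an energetic cost? The answer is assembled from four data
streams collected on wild long-tailed macaques (*Macaca fascicularis*):
minute-resolution focal scans, GPS tracklogs, monthly fruit-phenology
surveys and urinary C-peptide (UCP) assays, a non-invasive index of
energetic status (higher UCP = more positive energy balance). This vignette
documents the models, every tunable parameter that matters, what the
synthetic-data generator does and does not emulate, and the design choices
made where the field protocol left the computation under-determined.

## Mate-guarding segmentation

A minute *qualifies* for female F when the scan records the male following
F at a distance of at most 10 m. The segmentation rules are:

* an episode opens at the first minute of a run of at least `min_run = 6`
  consecutive qualifying minutes — a strict reading of "more than five
  consecutive minutes";
* within an open episode, up to `grace = 2` consecutive non-qualifying
  minutes do not close it; a third closes it, and the end is back-dated to
  the last qualifying minute ("did not follow her for more than 2 min"
  implies retrospective truncation);
* minutes with a missing distance flag, and unobserved minutes, count as
  non-qualifying grace minutes inside an open episode. This is the
  conservative choice: missing information never extends mate-guarding;
* a switch of guarded female closes the current episode under the same
  grace rule; the new female's episode opens only once she satisfies the
  6-minute opening run herself.

Episode duration includes bridged grace minutes (an 8 + 2 + 8 pattern is
one 18-minute episode). Daily MG minutes, however, are counted over
*observed* minutes covered by episodes, so the MG fraction can never
exceed 1. `segment_episodes()` implements these rules as a single
forward automaton; the test suite checks it against an independent
run-merging reference scanner on 10^4 randomised days.

**Observation time.** The field protocol does not state whether
out-of-sight minutes counted toward "observation time". By default they do
not (`include_out_of_sight = FALSE` in `daily_mg_summary()`): a minute in
which the animal could not be coded carries no behavioural information.
The alternative convention is one flag away.

**Extensive days and periods.** A male-day is an *extensive* MG day when
the MG fraction strictly exceeds 0.5 of observation time (so exactly 50 %
is not extensive). An MG period is a maximal run of consecutive extensive
days. Because groups were followed only every other day for part of the
study, strict calendar adjacency would make multi-day periods nearly
unobservable; `mg_periods()` therefore treats an unobserved calendar day
between two extensive days as non-breaking, while only observed extensive
days count toward the period length. An observed non-extensive day always
breaks a period.

## Activity, diet and restlessness

Activity budgets are proportions of *coded* focal minutes (not clock
time), the scan-sampling convention. Feeding takes precedence over any
concurrent state (grooming, travelling): the study's focus is energetics,
so a minute of food handling is a feeding minute. Diet composition is the
distribution of food items over feeding scans. Restlessness is the
fraction of calendar-adjacent coded minute pairs in which
locomotion/position changes (0 = none, 1 = a change every minute); pairs
spanning observation gaps are excluded, because a change across a gap is
unobservable rather than observed-absent. The first minute of each
contiguous block contributes no pair (undefined predecessor).

Male-days with fewer than 60 coded focal minutes are excluded from every
downstream table (`min_coded_min`), the study's "at least 1 h of focal
data" filter.

## Movement

**Horizontal.** Per-fix GPS error under rainforest canopy (~10 m) makes
minute-resolution path lengths mostly noise: a stationary animal logged
every minute with a 10 m mean spurious step accumulates 600 m/h of
apparent travel; at 15-minute fixes this falls to 40 m/h
(`expected_error_path()`, with a Monte-Carlo mode that must agree with the
analytic value within 2 %). Fixes are therefore subsampled at 15 ± 5
minutes (`subsample_fixes()`), greedily and deterministically: the next
fix is the eligible fix nearest the 15-minute target, ties to the earlier
fix, windows without an eligible fix are skipped and start a new segment
chain. Only fixes with focal behaviour at that exact minute are eligible
(the observer directly below the animal). The daily rate is
$\sum_i 4 D_i / n$ — four times the mean quarter-hour displacement.

**Vertical.** Canopy height categories code 5-m bands; the band centre is
the height estimate (0, 3, 7.5, 12.5, 17.5, 22.5 m). The open top category
(">25 m") is assigned 27.5 m, continuing the 5-m band width; since
emergent trees reach higher, `cat6_height` is exposed as a sensitivity
flag. The vertical metric sums |Δheight| over adjacent coded minutes —
total vertical path, up plus down — divided by coded hours. The field
description alternates between "height difference" and "height climbed",
so an ascent-only mode (`ascent_only = TRUE`) and a per-minute variant
(`per = "minute"`) are both available; the models use the per-hour total.

## Phenology and rainfall

Each territory's 120 surveyed trees are scored monthly on the ordinal
log-abundance scale 0–5; score ≥ 1 ("any fruit") defines a fruiting tree,
and the territory index is the percentage of trees fruiting — used instead
of the mean score because the two are strongly rank-correlated and the
percentage has a direct interpretation. Surveys run in the last three days
of a month and are dated to the month end; the survey of month *m* covers
observation days from the 16th of *m* to the 15th of *m*+1 (that month-end
survey is the nearest record for exactly those days). Daily rainfall
enters the behavioural models untransformed (as a z-standardized control).

## Urinary C-peptide

UCP is indexed to creatinine (ng C-peptide / mg creatinine), which cancels
urine-concentration differences — including deliberate reconstitution of
lyophilised samples in a smaller volume than the original urine. Samples
with creatinine below the creatinine assay sensitivity of 0.1 mg/ml are
excluded with a QC flag (an index against an unmeasurable denominator is
meaningless), and samples stored frozen for more than 8 months before
lyophilisation are excluded because C-peptide degrades in long storage;
exactly 8 months is retained (the rule is strictly "longer than"). The two
filters commute.

## Dominance

Bared-teeth displays are unidirectional submission signals: the giver is
the subordinate, so the wins matrix is the transpose of the display-count
matrix. `isi_rank()` minimises the number of inconsistencies I (dyads in
which the lower-ranked male dominates the higher-ranked one), then their
summed rank distance SI, via a randomised swap descent with restarts under
a fixed seed; unknown (0–0) and tied dyads contribute to neither I nor SI.
On matrices up to 8 individuals the heuristic attains the exhaustive
optimum (verified against a full permutation search in the tests). Ranks
1–2 (alpha, beta) form the "high" rank class — the males that mate-guard
intensively — and all others "low".

## The mixed models

Seven model fits are predefined (`mg_model_specs()`): five behavioural
daily responses — % time feeding, % fruit in diet, height climbed per
hour, distance travelled per hour, restlessness — each with MG time as the
test predictor and fruit availability and rainfall as controls; and two
UCP models at the urine-sample level (the MG model, adding height climbed,
feeding time, collection time and storage length as controls; and the rank
model, with the high/low rank class as test predictor). All models are
Gaussian linear mixed models fitted by maximum likelihood with random
intercepts for group and male (nested via globally unique male ids), and
all continuous predictors are z-standardized. Inference is hierarchical: a
full-versus-null likelihood ratio test (the null dropping only the test
predictor) gates any interpretation of individual coefficients. The
MG × fruit interaction is dropped by default (in the study it was never
significant); `interaction = "test"` reproduces the fit-then-drop path.

**Temporal autocorrelation.** Day-to-day dependence unexplained by the
fixed effects is absorbed by an autocorrelation covariate: for each row,
the Gaussian-kernel-weighted mean of the *other* same-male residuals,
weights $\exp(-\Delta d^2 / 2\sigma^2)$ in days. The published description
of this residual-based approach leaves three things open, which we fixed
by simulation:

* *Residual source.* Residuals come from the **null** model fitted
  without the AC term. Using full-model residuals (or omitting the term)
  leaves the test badly anti-conservative under AR(1) residuals with
  temporally clustered MG (type-I error ≈ 0.13 at nominal 0.05 in our
  calibration runs), because nothing then absorbs the autocorrelation
  that the clustered test predictor can masquerade as.
* *Kernel width.* σ is selected from the fixed grid
  {0.5, 1, 2, 4, 8, 16} days by maximising the full-model likelihood;
  the grid spans sub-daily to multi-week behavioural correlation scales.
* *Placement.* The same AC covariate enters full and null models, so the
  LRT degrees of freedom equal the number of dropped test terms.

With these choices the full-versus-null LRT is approximately calibrated
(type-I error ≈ 0.03 across 1,000 null simulations at study scale in the
acceptance suite) and errs slightly conservative — the AC covariate,
built from residuals that share the test predictor's temporal clustering,
absorbs a little of the noise component a spurious MG effect would ride
on. The flip side is mild attenuation: because the null-model residuals
still contain the MG effect, the AC covariate absorbs a small part of it
too, and a planted standardized effect of −2 is recovered at about −1.89
on average. We accept this bias-for-calibration trade; it is inherent to
the residual-based AC approach. The variant is isolated behind
`build_ac_term()` + `fit_model(ac_resid=)` so alternatives can be swapped.

**Small clusters.** Three groups is very few levels for a random
intercept. The fits proceed as specified, but every fit with fewer than
five levels in any grouping factor emits a
`mg_small_cluster_warning`: the group variance component is honest but
poorly identified, and the fixed-effect conclusions should not lean on it.

**p-values.** Per-term MCMC-based p-values from the original toolchain are
deprecated and under-specified; the package reports the full-versus-null
LRT as the primary test and per-term Wald t statistics descriptively,
preserving the original gating hierarchy.

**VIF.** Collinearity is checked on a fixed-effects-only linear model,
VIF = 1/(1−R²) per predictor, flagged at 5.

## The synthetic study generator

`generate_study()` emits a complete raw-data bundle with known ground
truth. Its defaults *are* the study conditions: 3 groups, alpha and beta
focal males per group (plus two low-ranking urine "controls"), a 220-day
mating period followed on an alternate-day schedule with 90 % completion,
giving ≈ 580 usable male-days of 6–11 coded hours each; per-male extensive
MG-day prevalences spread over 0.08–0.62 so realised overall MG time spans
roughly 8–54 %; MG-day persistence 0.85, making observed MG periods
average a few days; 10 m GPS error; ~25 % baseline tree-fruiting with
seasonal amplitude 0.12; UCP ≈ 3 ng/mg lognormal. The planted MG effect
sizes default to the fitted study estimates on the standardized scale
(feeding −2.16, fruit in diet −2.97, vertical locomotion −1.76) and a null
effect on UCP, distance and restlessness.

Responses are generated on the standardized scale with additive AR(1)
(ρ = 0.4) day effects plus male and group intercepts — exactly the
inference model's assumptions — and then mapped onto scan counts
(deterministic feeding counts, so measured budgets equal the latent
targets up to rounding), a height-category chain whose step rate matches
the vertical target, and a persistent-heading walk whose subsampled
displacement matches the travel target. MG minutes are laid out as
episodes of ≥ 6 qualifying minutes separated by ≥ 3 non-qualifying
minutes, with decoy sub-threshold following runs kept ≥ 3 minutes clear of
real episodes, so ground-truth MG minutes equal segmentation output
*exactly* on every generated day — the generator plants the rules the
segmenter must recover.

What the generator does **not** emulate: demographic change and male
migration between groups, female fertile-phase timing, observer effects,
heteroscedastic or non-Gaussian residuals (a misspecified mode is left to
future work), GPS dropouts under canopy, and diurnal activity rhythms.
Passing tests therefore demonstrate correctness of the pipeline's
arithmetic and calibration of its inference under the stated model — not
robustness to every way real field data deviate from it.

`simulate_model_table()` generates the assembled model table directly
(no raw-data layer) for the calibration and recovery simulations: 6 males
in 3 groups, 97 observation days each (≈ 580 rows), zero-inflated
clustered MG time, seasonal fruit, intermittent rainfall.

## Numerical and reproducibility choices

* All randomness flows from one seed; `generate_study()` and `isi_rank()`
  restore the caller's RNG state.
* The demo pipeline (`inst/extdata/demo_config.yaml`, 120-day study,
  ≈ 320 male-days, all seven models with grid AC selection) runs in about
  a minute on one CPU and reruns byte-identically: no timestamps are
  written, CSV/JSON formatting is fixed.
* Simulation sizes in the test suite — 10^4 random days for the
  segmentation oracle, 100 six-male matrices for I&SI, 1,000 null fits
  and 100 recovery fits at 580 rows — were chosen so the full suite runs
  in a few minutes while leaving Monte-Carlo error well below the margins
  being asserted.
* Degenerate inputs signal rather than guess: zero coded minutes, no
  feeding scans, fewer than two adjacent coded pairs, zero-variance
  predictors and sub-sensitivity creatinine all return NA/NULL or raise
  a named error.
* lme4 fits use `calc.derivs = FALSE` (speed) and flag rather than hide
  convergence or singularity issues.

## Known limitations

Group-level variance components from three groups are barely identified
(hence the standing warning). The AC-term variant trades a small downward
bias in the test predictor for type-I calibration, as quantified above.
Travel distances assume the planar local projection is exact (fine below
a few km). The I&SI search is heuristic beyond n = 8, where exhaustive
verification becomes impractical — restarts make failures unlikely but
not impossible. And the package reproduces the study's *procedures*, not
its data: the original field records are not public, so numerical targets
are limited to the study's self-contained worked quantities.
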