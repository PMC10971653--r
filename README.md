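# hwdensity

Body-composition densitometry by hydrostatic (underwater) weighing, with a
full method-agreement analysis between weighing protocols and a
forward-simulating synthetic-cohort generator for verification by parameter
recovery.

## The problem

Conventional hydrostatic weighing requires full submersion at residual
volume (RV) — exhale completely, go under, hold still — which many people
find uncomfortable enough to refuse. A more comfortable protocol keeps the
head above water (HAW) at total lung capacity (TLC), replacing the head's
displaced volume with an anthropometric prediction from head girth, face
girth and dry mass. Validating that protocol requires a measurement
pipeline (girth QC, predicted head and lung volumes, trial selection,
density inversion) and a method-agreement analysis between the weighing
conditions. `hwdensity` implements both, for exercise-physiology and
body-composition researchers working with tank systems that log per-trial
in-water masses or raw load-cell streams.

## The model

From Archimedes' principle, whole-body density in a submerged (HBW)
condition is

    Db = MA / ((MA − MW) / DW − V_L − 0.1)

and with the head above water (HAW)

    Db = MA / ((MA − MW) / DW + HV_pred − V_L − 0.1)

where MA is dry mass (kg), MW the in-water mass (kg), DW the water density
(kg/L, from temperature via Kell's polynomial), V_L the lung gas volume
held during the trial (TLC or RV, litres, predicted from height/age/sex),
HV_pred the predicted head volume (litres), and 0.1 L the gastrointestinal
gas allowance. Percent body fat follows by the Brozek transform
`PBF = (4.570 / Db − 4.142) · 100`.

Conditions `HAW_TLC`, `HBW_TLC` and `HBW_RV` are compared pairwise with
paired t-tests, Bland-Altman 95% limits of agreement, a proportional-bias
regression (difference on pair mean), and Lin's concordance correlation
coefficient, overall and stratified by self-reported sex.

## Worked example

Simulate a small cohort with two injected prediction errors — true lung
gas 0.8 L below the predicted TLC and a head-volume prediction 0.3 L above
truth — then run the pipeline and the three-way comparison:

```r
library(hwdensity)

cfg <- cohort_config(n_male = 12, n_female = 12, seed = 42,
                     tlc_offset_l = -0.8, hv_bias_l = -0.3)
co     <- generate_cohort(cfg)
trials <- simulate_weighing(co$participants, co$truth, cfg)
res    <- compute_cohort(co$participants, co$girths, trials)
rep    <- run_comparisons(res, co$participants)
as.data.frame(rep[rep$stratum == "combined",
                  c("comparison", "n", "mean_diff", "loa_low", "loa_high",
                    "p_paired", "lccc")])
#>          comparison  n mean_diff loa_low loa_high p_paired  lccc
#> 1 HBW@TLC - HAW@TLC 24     -1.68  -3.182   -0.183 1.84e-10 0.947
#> 2  HBW@RV - HBW@TLC 24      4.67   2.916    6.418 2.11e-18 0.729
#> 3  HBW@RV - HAW@TLC 24      2.99   0.896    5.074 1.46e-12 0.863
```

Read: the head-volume overshoot makes HAW@TLC read about 1.7 percentage
points *higher* than HBW@TLC (hence the negative HBW − HAW difference),
and the TLC overshoot makes TLC conditions read lower than HBW@RV by about
4.7 points. Both match the analytic propagation `457 · δ / MA` of a
volume error δ through the density equations. With all offsets and noise
at zero, every mean difference is 0 and every CCC is 1 to machine
precision, because the simulator is the exact inverse of the pipeline.

Individual building blocks are exported and vectorised:

```r
predict_head_volume("male", hg_cm = 58.3, fg_cm = 67.7, ma_kg = 90.6)
#> [1] 4.31595
body_density("HBW_RV", ma_kg = 80, mw_kg = 3.0, dw_kg_l = 1.0000,
             lung_volume_l = 1.7)
#> [1] 1.06383
percent_body_fat(80 / 75.2)
#> [1] 15.38
```

`autoplot()` on an `agreement_stats()` object draws the Bland-Altman plot;
on a `run_comparisons()` report it draws the full 3 × 3 grid. `tidy()` and
`glance()` return the statistics as tibbles. CSV-level I/O (`hw_run()`,
`hw_simulate()`) reads `participants.csv` / `girths.csv` / `trials.csv`
(or raw `samples.csv` streams) and writes `results.csv`,
`agreement_report.csv`, `bland_altman_points.csv` and a run log.

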