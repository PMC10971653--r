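---
title: "Hydrostatic weighing densitometry: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hydrostatic weighing densitometry: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hwdensity)
library(dplyr)
```

## The measurement model

Hydrostatic (underwater) weighing estimates whole-body density from
Archimedes' principle: a body immersed in water is buoyed by the weight of
the water it displaces, so the difference between dry mass in air (MA, kg)
and mass measured in water (MW, kg) divided by the water density (DW, kg/L)
is the displaced volume in litres. Not all of that volume is tissue. The
lungs hold gas during the trial -- total lung capacity (TLC) after a
maximal inhale, or residual volume (RV) after a maximal exhale -- and a
conventional 0.1 L allowance covers gastrointestinal gas. With the head
fully submerged (HBW),

$$D_b = \frac{MA}{(MA - MW)/D_W - V_L - 0.1}$$

where $V_L$ is the lung gas volume (TLC or RV, litres). When the head stays
above the surface (HAW) its volume never displaces water, so a predicted
head volume $HV_{pred}$ is added back into the denominator:

$$D_b = \frac{MA}{(MA - MW)/D_W + HV_{pred} - V_L - 0.1}.$$

Percent body fat follows from density by the Brozek transform,
$PBF = (4.570/D_b - 4.142) \cdot 100$, implemented in
`percent_body_fat()` with its exact inverse in `pbf_to_density()`.

A consequence worth noting: because $PBF$ is linear in $1/D_b$ and
$1/D_b$ is linear in the denominator volume, any volume error $\delta$
(litres) in the denominator propagates *exactly* as
$\Delta PBF = 457 \cdot \delta / MA$ percentage points. This makes the
package's injected-bias tests sharp: the shift a lung- or head-volume
prediction error produces in a comparison is predicted analytically, not
just directionally.

The three supported weighing conditions are `HAW_TLC` (head above water at
total lung capacity -- the comfortable protocol), `HBW_TLC` (submerged at
TLC), and `HBW_RV` (submerged at residual volume -- the conventional
reference protocol).

## Predicted volumes

**Head volume** (`predict_head_volume()`) is a sex-specific linear
regression on head girth (HG), face girth (FG) and dry mass:

* males: $HV = 0.1294\,HG + 0.0299\,FG + 0.0055\,MA - 5.7506$
* females: $HV = 0.1314\,HG + 0.0504\,FG + 0.0094\,MA - 7.3181$

The source of these coefficients does not state units; this package adopts
girths in **centimetres** and mass in **kilograms**, which yields head
volumes of about 3.9--4.3 L at typical adult inputs -- the anatomically
plausible scale (an adult head is roughly 4 L). Girths are stored in
millimetres throughout (tape resolution is 1 mm) and converted to cm only
at equation entry. Predictions outside 2--7 L raise a warning.

**Lung volumes** (`predict_tlc()`, `predict_rv()`) are sex-specific linear
reference equations in standing height (metres; accepted as cm at the I/O
boundary) and, for RV, age in years:

* male TLC $= 7.99\,h - 7.08$; female TLC $= 6.60\,h - 5.79$
* male RV $= 1.31\,h + 0.022\,a - 1.232$; female RV
  $= 1.812\,h + 0.016\,a - 2.003$

Preconditions restrict heights to (1, 2.5) m and ages to 18--100 years: the
equations are adult reference fits and are not extrapolated to children.
Within realistic adult statures (1.2 m and up) TLC always exceeds RV; the
linear forms do cross below about 1.11 m at high ages, which is one reason
the range is enforced.

**Water density** (`water_density()`) uses Kell's polynomial for air-free
water, giving 0.99997 kg/L at 4 °C and 0.99470 at 33 °C. Tanks run warm
(31--34 °C), where assuming 1.000 kg/L would bias displaced volume by about
0.5%. The default analysis temperature is 32.5 °C, the midpoint of the
operating band; both the temperature and a direct density override are
config parameters.

## Measurement quality control

**Girths** (`qc_girth()`): two technicians each measure once; a third
measurement is taken when the first two differ by more than 5 mm, and a
fourth on the rare occasion that no two agree. The value carried forward is
the mean of the closest agreeing pair. Where several pairs qualify, the
smallest absolute difference wins and ties break to the earliest pair in
acquisition order -- a deterministic reading of "the average of two
measurements within 5 mm" consistent with reporting first and second
*consistent* trials. Four measurements with no agreeing pair is a QC
failure (a result, not an exception); it blocks only the head-above-water
condition, which needs the head-volume prediction.

**Trials** (`select_consistent_trials()`): a condition's weight is the mean
of three trials agreeing within 100 g, out of at most 7 trials for TLC
conditions and 5 at RV. All 3-subsets are enumerated; the smallest range
within tolerance wins, ties breaking lexicographically. When no triple
qualifies the search repeats over pairs (quality `"pair"`); participants
with only a consistent pair are **retained by default** with the quality
tier recorded, matching field practice where a substantial minority of
participants never achieve a third consistent trial. `hw_config(strict_quality
= TRUE)` excludes them instead. With no consistent pair the condition is
dropped for that participant (quality `"none"`).

**Sample windows** (`select_sample_window()`): when raw load-cell streams
are supplied instead of per-trial weights, the trial weight is the mean of
the contiguous window of 100 ± 2 samples with the smallest within-window
standard deviation (ties: longer window, then earlier start) -- an explicit,
reproducible version of the operator's "select the samples that best
represent the steady weight".

All three tolerances (5 mm, 100 g, 100 ± 2) are `hw_config()` parameters
defaulting to the printed protocol.

## The agreement analysis

`run_comparisons()` compares percent body fat between the three conditions
in the orientation of the standard report table:

1. `HBW@TLC - HAW@TLC` -- head position at constant lung volume,
2. `HBW@RV - HBW@TLC` -- lung volume with the head submerged,
3. `HBW@RV - HAW@TLC` -- the comfortable protocol against the reference.

Each comparison is run for the combined cohort and separately by
self-reported sex, on its own pairwise-complete participants: a missing
condition removes a participant only from the comparisons that involve it.
Strata with fewer than 3 complete pairs are skipped with a warning.

Per comparison the package reports a paired t-test (`paired_t()`),
Bland-Altman mean difference and 95% limits of agreement
(`bland_altman()`; the multiplier defaults to 1.96 and is configurable), a
proportional-bias regression of difference on pair mean
(`proportional_bias()`, OLS with a two-sided slope test at α = 0.05), and
Lin's concordance correlation coefficient (`lin_ccc()`).

Two conventions the literature leaves implicit are fixed explicitly here:
the limits of agreement use the **n − 1** standard deviation of the
differences, while Lin's CCC uses **1/n** (biased) moments, the original
convention, so `lin_ccc(a, b)` equals
$2 s_{ab} / (s_a^2 + s_b^2 + (\bar a - \bar b)^2)$ with 1/n moment sums.
The proportional-bias regression is difference on **mean** (the standard
Bland-Altman regressor), not difference on either method alone.
`loo_sensitivity()` recomputes the slope p-value leaving each pair out in
turn, the generalisation of checking whether a significant proportional
bias is driven by a single outlying participant.

Degenerate inputs are signalled rather than silently propagated:
zero-variance differences yield a flagged p of 0 (nonzero mean) or 1
(identical series); two constant series make the CCC undefined (error);
constant pair means make the proportional-bias slope unidentifiable
(error). With a perfect linear fit (zero residual variance) the slope
p-value is reported as 0 for a nonzero slope and 1 for a zero slope, since
the OLS t-statistic is 0/0 in floating point.

## The synthetic cohort: what it emulates and what it does not

Because raw study data of this kind are not publicly deposited, the package
ships a forward simulator (`generate_cohort()`, `simulate_weighing()`,
`make_study_fixture()`) so that the full pipeline is testable by parameter
recovery. The generator emulates:

* **Cohort structure** -- 64 males and 58 females by default, with
  sex-specific height (182.1 ± 7.9 / 168.7 ± 6.2 cm), mass (90.6 ± 14.7 /
  68.5 ± 12.1 kg), age (25.3 ± 10.7 / 22.9 ± 8.4 yr, truncated to 18--70)
  and head/face girth (58.3 ± 1.6, 67.7 ± 2.1 / 56.2 ± 1.6, 63.0 ± 2.1 cm)
  marginals, recorded at instrument resolution (0.1 cm, 0.1 kg, whole
  years, whole mm).
* **Latent truth** -- true percent body fat per sex (defaults: male
  N(18, 6), female N(28, 7), truncated to 3--50%; generator conveniences,
  config-exposed, not literature values), converted to density by the
  exact Brozek inverse so truth is internally consistent; true lung
  volumes equal to the reference predictions plus configurable offsets
  (`tlc_offset_l`, `rv_offset_l`, default 0: *true = predicted + offset*);
  true head volume equal to the girth-based prediction plus a configurable
  bias and N(0, `hv_sd_l`) scatter. The scatter default of 0.15 L
  represents realistic prediction error of an anthropometric head-volume
  equation; it is set to 0 in recovery tests, which probe measurement
  noise, not model misspecification.
* **Measurement noise** -- iid technician error per girth measurement
  (default 2 mm, with the sequential third/fourth-measurement protocol
  simulated and measurements rounded to the mm) and iid per-trial noise on
  in-water masses (default 30 g; the consistency criterion is 100 g, and
  no tighter noise figure is published, so 30 g -- comfortably passing QC
  while visible in the output -- is an assumption). Optionally, raw
  load-cell streams per trial with iid sample noise.

In-water masses are simulated by the exact inverse of the density
equations, e.g. $MW_{HBW} = MA - D_W (V_{body} + V_L^{true} + 0.1)$ with
$V_{body} = MA / D_b^{true}$, so with all noise and offsets at zero the
pipeline recovers every participant's true PBF to floating-point precision
in all three conditions -- the package's strongest end-to-end invariant.
Negative in-water masses (buoyant participants at TLC) are legitimate and
pass through.

The generator deliberately does **not** emulate: posture and wave
perturbation, breath-hold failure or air leakage, learning effects across
trials, belt-position artefacts, non-Gaussian technician error, or any
correlation between body fatness and measurement difficulty. Passing
recovery tests therefore demonstrates that the *computational* chain is an
exact inverse of the stated measurement model under stated noise -- not
that the physical protocol achieves any particular accuracy in real
cohorts. Disagreement between conditions is never present by default;
effect knobs (`hv_bias_l`, `tlc_offset_l`, `rv_offset_l`) must be set
explicitly, so recovery and agreement tests are not circular.

By construction a *negative* `tlc_offset_l` (true lung gas below the
predicted TLC -- equivalently, a prediction overshoot) lowers
TLC-condition PBF and drives the RV − TLC comparison positive, and a
*negative* `hv_bias_l` (head-volume prediction overshoot) raises HAW PBF
and drives the HBW − HAW comparison negative; both shifts equal
$457 \cdot \delta / MA$ per participant exactly, which the test suite and
acceptance script verify against the simulated comparisons.

## Numerical and design notes

* The density equations for the submerged conditions are implemented with
  the condition's own in-water mass; the head-above-water mass enters only
  the HAW equation (the symbol reuse seen in some write-ups of these
  formulas is treated as typographical).
* The 2.1 kg belt worn during TLC trials is assumed tared by the
  acquisition system. For systems that do not tare it,
  `hw_config(belt_mass_kg = 2.1, belt_density_kg_l = 7.8)` subtracts the
  belt's net in-water weight $m_{belt}(1 - D_W/\rho_{belt})$ from
  TLC-condition readings; the default is off.
* A non-positive body-volume denominator (displaced volume swallowed by the
  assumed gas volumes) is a computation error naming the offending volumes,
  not an NaN.
* Seeds: `generate_cohort()` runs under `config$seed` and
  `simulate_weighing()` under `config$seed + 1`, so a fixture bundle is a
  pure function of its configuration; `hw_simulate(..., seed =)` overrides
  the config seed.
* Problem sizes used by the shipped tests and the acceptance script --
  50 participants for exact-inversion checks, 200 for noisy recovery,
  5,000 replicates for t-test and slope-p calibration, 10,000 differences
  for limits-of-agreement coverage, full enumeration over 4-point (trial)
  and 5-point (girth) grids for oracle equivalence -- were chosen to give
  Monte-Carlo standard errors well inside the asserted bands.

## Known limitations

* The head-volume and lung-volume equations are taken as printed; their
  original derivation cohorts (and hence applicability outside young,
  mostly White adults) are not re-validated here.
* Only binary male/female equations exist in this measurement tradition;
  the package requires one of the two labels and stratifies by
  self-reported sex.
* `quality = "pair"` weights rest on two trials and are intrinsically less
  reliable; the default retains them (flagged) because excluding them
  discards a quarter of typical cohorts, but sensitivity to this choice
  should be checked with `strict_quality = TRUE`.
* The per-participant exclusion rule is per-condition: a participant
  missing one condition still contributes elsewhere. Global exclusion, if
  wanted, is a one-line filter on the results table.
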