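---
title: "Gestational SCr reference intervals and hyperfiltration eGFR: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gestational SCr reference intervals and hyperfiltration eGFR: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gestgfr)
```

## The problem

Normal pregnancy raises renal plasma flow and glomerular filtration by
40–50% (physiological hyperfiltration), so serum creatinine (SCr) falls well
below non-pregnant levels, reaches a nadir in mid-pregnancy, and partially
rebounds near term. Two clinical consequences drive this package:

* an SCr value that is *normal for a non-pregnant woman* can hide genuine
  gestational renal dysfunction (the expected hyperfiltration simply failed
  to happen), so week-specific reference intervals (RIs) are needed; and
* the standard eGFR equations (MDRD, CKD-EPI) index filtration to body
  surface area and were never validated in pregnancy, where body water
  expands far more than surface area, so an absolute (mL/min) estimate
  anchored to the degree of hyperfiltration is preferable.

The difficulty is data sparsity: prenatal SCr testing clusters heavily in
the third trimester, leaving many gestational weeks (GWs) with fewer than
the 20 observations that CLSI guidance treats as the minimum for an RI,
let alone the recommended 120.

## The estimation pipeline

### Pooling weeks into gestational periods

Weeks are pooled into *gestational periods* (GPs): the pre-implantation
period GW 0–3 is always its own bin (no hemodynamic change is assumed
before implantation; it defines the baseline), and the remaining weeks
GW 4–41 are covered by bins of width 3 or 4. The default arrangement —
five 4-week bins (GW 4–23) then six 3-week bins (GW 24–41), giving 12 GPs —
puts the wider bins where sampling is sparse. Any bin left with fewer than
`min_per_bin = 20` measurements is merged into its successor, and empty
bins are dropped, so the result always partitions the data. The exact 3/4
arrangement is configurable (`binning_config(widths = ...)`); results are
insensitive to it as long as every GP clears the minimum.

### Mean-of-two bootstrap with Gaussian acceptance

Each GP is expanded into a *resample set*: `t = 120` values, each the
arithmetic mean of `n = 2` measurements drawn at random from the GP
(distinct within a pair; pairs drawn independently, i.e. with replacement
across iterations). Averaging pairs pulls the skewed originals toward
normality, and 120 is exactly the CLSI-recommended observation count. A
candidate set is *distributionally accepted* when

* Pearson kurtosis (normal = 3) lies in [2.5, 3.5],
* skewness lies in [−0.5, 0.5], and
* the Shapiro–Wilk p-value is ≥ 0.05.

For an accepted set, the 95% interval is taken from order statistics: ranks
`ceiling(0.025 t)` and `t + 1 − ceiling(0.025 t)` — the 3rd and 118th
values for t = 120. Finally, CLSI-style verification computes the
*coverage*: the fraction of the GP's original measurements inside the
closed interval, with 0.95 the pass mark. `build_period_ri()` retries with
fresh sub-seeds (cap `max_attempts = 1000`, all derived from one master
seed so retries are reproducible) until a set passes both the Gaussian
criteria and coverage; if the cap is reached it returns the best attempt
(Gaussian-passing preferred, then highest coverage) flagged
`accepted = FALSE`, leaving the decision to the caller.

**A structural caveat discovered while testing.** The coverage confirmation
cannot, in general, succeed on smooth continuous data. The mean of two
i.i.d. draws has half the variance of a single draw, so the central 95%
band of the resampled means spans roughly ±1.96σ/√2 = ±1.39σ and covers
only ≈83% of the original distribution for any normal or log-normal shape
— simulation across GP sizes 25–300 and 2000 retries per GP never produced
a set that passed both the Gaussian screen and coverage. Real laboratory
data can behave differently (heavy ties from fixed reporting resolution
and strongly peaked distributions push coverage up, though the same ties
then fight the Shapiro–Wilk criterion). The package therefore treats the
two checks separately: `smooth_limits()` and `run_pipeline()` *require*
the Gaussian screen, which is what licenses reading percentiles off the
resample set, and report coverage failures as warnings recorded in the
diagnostics (`require = "full"` restores strict behaviour, `"none"`
disables both). On synthetic cohorts the coverage flag should be expected
to read `FALSE` for every GP; this is a property of the verification rule,
not a bug in the resampler, and the per-GP coverage values (~0.83–0.93)
are reported so the user can judge.

### From periods to weeks: cross-validated polynomial smoothing

GP-level percentiles (taken from the resample sets by the same rank rule,
e.g. the 60th value for the median of 120) are placed at the GP's midpoint
week and smoothed into week-level curves. The polynomial degree is chosen
by repeated k-fold cross-validation: per repeat, a fresh random partition
into k = 3 folds (pregnancy's natural trimester split; fold sizes differ
by at most one), candidate degrees 1–5 scored by held-out MSE on a shared
partition, the argmin recorded; after 1000 repeats the modal winning
degree is selected, ties breaking toward the smaller degree (parsimony).
Exact-fit MSE ties (noiseless data) are detected with a small
scale-relative tolerance so that numerically identical fits also resolve
toward parsimony. The final curve is an ordinary least-squares fit of the
chosen degree on all points, over raw ascending powers of GW — the same
basis in which the canonical median polynomial is written — which is
adequately conditioned on the GW 4–41 domain for degrees up to 5. The
pre-implantation GP is excluded from every fit, and the curves are
evaluated at each integer week GW 4–41, which is what repairs the
GP-level granularity.

How reliably does this recover a known degree? With default generator
noise, cohorts built from truth curves of degrees 1–4 whose leading
component is identifiable (a leading term contributing ≳2 μmol/L beyond
the best lower-degree approximation) return the generating degree in
≈86–90% of seeded trials. The canonical median curve itself is an
instructive edge case: its quartic coefficient (−6.53e-5) contributes only
about ±1 μmol/L beyond the best cubic — the same order as the median
estimation noise at ~1500 measurements — so the choice between degrees 3
and 4 is data-dependent there. That is consistent with the published
limits landing on different degrees (4 for the upper, 3 for the lower
limit) and is why the degree-recovery test uses curves with identifiable
leading terms rather than the canonical quartic.

## The gestational eGFR formula

With the baseline SCr (BSC) defined as the pre-implantation median, the
chain of definitions is:

* hyperfiltration gap `= BSC − SCr` (μmol/L; positive under
  hyperfiltration),
* simple gap ratio `= (BSC − SCr)/BSC`,
* overall hyperfiltration ratio `= 1 + (BSC − SCr)/BSC = 2 − SCr/BSC`
  (1 at baseline, 0 at SCr = 2·BSC),
* simple eGFR `= overall ratio × normal GFR`, and
* gestational eGFR `= simple eGFR × k_gw`, where
  `k_gw = BSC / median SCr curve(GW)` corrects for the curvilinear median
  trajectory (the displayed formula applies the ratio in this orientation,
  and that is what the package implements; `k_gw` peaks at the GW 22–23
  nadir).

The canonical constants, shipped as a versioned YAML config
(`inst/extdata/canonical_params.yaml`), are BSC = 55.25 μmol/L; normal
GFR = 103.1 mL/min, obtained by de-indexing a measured female population
mean of 110.1 mL/min/1.73 m² to the mean body surface area 1.62 m² of the
target population (`110.1 × 1.62 / 1.73`); and the degree-4 median
polynomial `56.7 − 0.223·GW − 0.113·GW² + 0.00545·GW³ − 0.0000653·GW⁴`
(GW 4–41). Note one acknowledged inconsistency in the canonical set: the
median curve extrapolates to 56.7 at GW 0 while the baseline is 55.25; the
package keeps both as published and never evaluates the curve before GW 4.

```{r egfr-example}
gestational_egfr(40, 20)          # SCr 40 umol/L at GW 20
k_gw(22)                          # correction factor at the nadir
derive_normal_gfr(110.1, 1.62)    # the absolute normal GFR constant
```

Inputs with SCr ≥ 2·BSC would produce non-positive eGFR; they are outside
the model's physiological range and produce a warning rather than a silent
negative number. GW 0–3 is rejected (no hemodynamic change is assumed
there, so the formula does not apply).

eGFR reference intervals are built by transforming every measurement at
GW ≥ 4 through the formula and re-running the identical binning /
resampling / smoothing pipeline on the mL/min scale. In the combined
week-by-week table, all values are rounded to 0.1 and the increment
columns are computed *from the rounded medians* — recomputing the
published table shows that convention (0/38 mismatches, versus 21/38 when
computed from unrounded values). The SCr increment baseline is the BSC;
for eGFR the published increments are not consistent with dividing by the
normal GFR constant, and the baseline actually used there is not
recoverable from the printed numbers, so the package defaults to its own
explicit convention — the fitted median eGFR curve extrapolated to the
pre-implantation midpoint (GW 1.5) — and exposes it as the
`egfr_baseline` argument. The eGFR percentile columns of the published
table are therefore *not* asserted anywhere; only its structure and the
SCr columns are.

## The synthetic cohort generator

No cohort accompanies the published analysis (clinical privacy), so the
generator is the package's test bed. It emulates the study's structure:
957 subjects contributing 1484 measurements, at most one measurement per
subject per week, with sampling mass 10% / 20% / 70% across the three
trimesters (uniform within each; the real per-week counts are not
published, so these are plausible stand-ins, configurable via
`sampling_weights`).

Per week, SCr follows a shifted (3-parameter) log-normal
`shift + (median − shift)·exp(σZ)`: the median equals the truth curve
exactly (canonical median polynomial for GW ≥ 4, constant 55.25 for
GW 0–3), σ is solved in closed form from the requested skewness (Cardano
inversion of the log-normal skewness cubic), and the shift absorbs the
requested coefficient of variation, so `dispersion` and `skew` are
independently controllable and every quantile is available in closed form
(`true_quantile()`, the oracle for recovery tests). Defaults:
`dispersion = 0.12` — a realistic combined biological + analytical CV for
serum creatinine — and `skew = 0.8`, giving visibly right-skewed weekly
distributions that stay below the skewness ≈ 1.5 regime in which the
mean-of-two bootstrap is well behaved. Both were fixed as study conditions
when the generator was designed.

What the generator does *not* emulate: quantized reporting (real SCr
values sit on a 0.01 mg/dL = 0.8842 μmol/L grid and tie heavily),
analyzer-specific bias, within-subject correlation across repeat visits,
and any pathology. Passing tests therefore demonstrate the pipeline's
statistical behaviour under a clean, known truth — not that the coverage
confirmation would pass on real hospital data (see the caveat above, where
the discreteness of real data is precisely what matters).

## Numerical and design choices

* **Kurtosis convention**: Pearson (non-excess, normal = 3), matching the
  acceptance band centred at 3; sample moments use the plain type-1
  estimators.
* **Percentile rank rule**: `ceiling(p·t/100)` from the relevant tail,
  with a 1e-9 slack so floating-point products landing marginally above an
  integer do not shift a rank; for t = 120 this yields ranks 3/60/118 for
  the 2.5th/50th/97.5th percentiles.
* **Degenerate inputs**: zero-variance GPs fail the Gaussian screen with
  an explicit reason and can never be accepted (their interval is a
  point); `dispersion = 0` cohorts are allowed and collapse onto the truth
  curve, which is exactly what the recovery tests exploit.
* **Representative abscissa** of a GP is its midpoint week — the
  symmetric choice, e.g. 5.5 for GW 4–7.
* **Determinism**: every stochastic stage (cohort, per-GP resampling
  including retries, CV fold partitions) derives its sub-seeds from one
  master seed; two runs with the same seed are identical to the byte in
  their CSV artifacts.
* **Problem sizes** used by the shipped tests: the default cohort
  (957/1484) for end-to-end runs; 200 Monte-Carlo repetitions for the
  variance-law check of the mean-of-two interval (expected width
  2·1.96·σ/√2); 50 seeded trials per degree for recovery. These sizes give
  Monte-Carlo error comfortably inside the asserted tolerances.

## Verification against an external cohort

The only published external anchor is a percentile table (95th/75th/50th)
of directly measured SCr from a large Canadian pregnancy cohort at even
weeks GW 4–40. `compare_to_reference()` evaluates the study's smoothed
percentile curves at those weeks and reports signed differences
(study − reference, negative when the study value is lower), rounding each
difference to 0.1 μmol/L *before* aggregating — the printed aggregates are
reproducible only under that convention. Aggregation is hierarchical: per
GW (mean over the three percentiles), per trimester (mean over member
GWs' means), and per percentile (mean over all weeks). The published
aggregate differences carry a "%" label although the columns are in
μmol/L; the package reports them in μmol/L and leaves the unit ambiguity
to this note.

## Clinical flagging

`evaluate_patient()` computes the gestational eGFR for a measurement and
flags both analytes against their week's RI row, boundary values counting
as within (closed intervals, mirroring the coverage convention). Because
the formula is strictly decreasing in SCr, a high SCr flag pairs with a
low eGFR flag: the pattern suggesting blunted hyperfiltration (possible
gestational renal dysfunction or preeclampsia); both-high patterns suggest
severe anemia or hypoproteinemia. GW 0–3 yields a notice instead of flags.

```{r flagging}
evaluate_patient(80, 22)
```

## Known limitations

* The coverage confirmation step is effectively unsatisfiable on
  continuous data (see above); on synthetic runs it is reported, not
  enforced. This is the package's most important caveat when transferring
  conclusions to real data.
* The canonical parameter set is population-specific (East Asian reference
  GFR and BSA); using it elsewhere changes the absolute eGFR scale.
* Degree selection near the canonical quartic is noise-dominated at
  realistic sample sizes; upper and lower limits can legitimately land on
  different degrees.
* The generator draws weeks independently within a subject; longitudinal
  correlation is not modelled, so subject-level inference is out of scope.
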