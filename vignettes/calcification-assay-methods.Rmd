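---
title: "Methods: drift-assay kinetics, matrix proteomics, and the synthetic-data model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: drift-assay kinetics, matrix proteomics, and the synthetic-data model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(carbomatrix)
```

## The assay model

The pH-drift calcification assay rests on the stoichiometry
Ca²⁺ + HCO₃⁻ → CaCO₃ + H⁺: in an unbuffered well, every mole of mineral
formed releases a proton, so acidification proxies precipitation. The
readout chain is

1. **Calibration.** Thymol blue absorbs at 594 nm with an approximately
   linear pH response over its transition range (≈ pH 7.6–9.0). Standard
   wells at fixed pH (7.6 to 9.0 in 0.2 steps) are averaged over the whole
   time course — first within a well over time, then across replicate wells
   of the same pH — and a first-order polynomial A = a + b·pH is fitted by
   ordinary least squares (`fit_standard_curve()`). Averaging over the full
   course, rather than the first reads, makes the calibration insensitive
   to slow drift in lamp intensity or dye bleaching, under the assumption
   that standards are chemically static.
2. **Inversion and transformation.** Sample absorbance is inverted through
   the curve (`absorbance_to_ph()`); pH values outside the indicator's
   reliable span are flagged, never clipped, because a clipped series would
   bias the total-increase estimate silently. pH is then mapped to
   [H⁺] = 10^(−pH) (`ph_to_hplus()`). This is a formal re-scaling that
   removes the logarithmic compression of pH — not a thermodynamic activity
   claim; no activity coefficients are applied anywhere in the analysis
   layer.
3. **Kinetics.** Per well (`nucleation_time()`, `calcification_rate()`):
   * baseline: median of the first `baseline_points` (default 10) readings;
   * peak: maximum of the series smoothed with a `smooth_points` (default
     5) rolling median;
   * total increase ΔH = peak − baseline;
   * nucleation time: first crossing of baseline + 10% ΔH, linearly
     interpolated between the bracketing samples;
   * calcification rate: OLS slope of raw [H⁺] on time over the readings
     whose *smoothed* value lies in [baseline + 20% ΔH, baseline + 60% ΔH].
4. **Normalization.** Both metrics are divided by the mean of the defined
   no-protein control wells on the same plate (`normalize_to_controls()`).
   Division by the control mean removes plate-wide systematic shifts
   (temperature, dye lot, buffer batch); by construction the control
   group's normalized mean is 1.

`drift_fit()` wires the chain together and returns a classed object with
`print`, `summary`, `coef`, `plot` and `fitted` methods.

### Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `threshold_frac` | 0.10 | fraction of ΔH | the assay's operative definition of nucleation |
| `window` | (0.20, 0.60) | fraction of ΔH | the near-linear growth phase; below 20% nucleation stochasticity dominates, above 60% substrate depletion bends the curve |
| `baseline_points` | 10 | readings | 10 × 30 s = the first 5 min, before any plausible nucleation |
| `smooth_points` | 5 | readings | rejects single-reading spikes without shifting a sigmoid's crossing materially |
| `min_delta_h_mad` | 3 | multiples of baseline MAD | wells whose total rise is within 3 robust SDs of baseline noise are flagged `no_precipitation` rather than given meaningless metrics |
| `indicator_range` | (7.6, 9.0) | pH | thymol blue's transition span |
| `crossing_on` | `"smoothed"` | — | threshold detection on the smoothed series resists noise; the raw option is retained because the choice is not dictated by the assay definition |

Two definitional choices deserve emphasis. *Total increase* is
(smoothed max − early-baseline median), not (global max − global min):
a single noisy sample should not set the denominator of every threshold.
And the membership of the rate window is decided on the smoothed series
while the regression is fitted on raw values at those times — smoothing
selects, but never manufactures, data.

The minimum-ΔH criterion deliberately errs toward flagging: wells where
precipitation genuinely failed (which happens at strongly inhibiting
doses) must be excluded from group means rather than entered as
near-infinite nucleation times.

## pH-stat analogue

The pH-stat assay holds pH constant by titrating NaOH, so cumulative base
mirrors cumulative mineral. `phstat_metrics()` mirrors the drift
definitions: nucleation is the interpolated 10% crossing of the total base
added, and the rate is the *maximum* over sliding-window (default 2 min)
OLS slopes — a maximum rather than a band regression because pH-stat
events complete within minutes and the instantaneous peak is the
informative summary. The window default reflects that minutes-scale
dynamics; both threshold and window are reconstructions of an
under-documented convention and are exposed as arguments.

## Statistical treatment

Normalized nucleation times are ln-transformed and normalized rates get
ln(x + 1) (`kinetics_transforms()`); variance homogeneity of the transformed
values is checked by the Brown–Forsythe test (one-way ANOVA on absolute
deviations from group medians, `brown_forsythe()`); group differences by
one-way ANOVA from explicit sums of squares (`one_way_anova()`); and each
dose is compared with the control by a two-sided pooled-variance t test
using the ANOVA within-group mean square, with Holm–Šidák step-down
adjustment over the m dose comparisons (`dunnett_style_vs_control()`,
`holm_sidak()`). The pooled-variance t is the standard post-ANOVA choice
when only the adjustment, not the comparison statistic, is prescribed;
"two-sided" is interpreted as two-sided comparisons. The step-down
formula, with enforced monotonicity down the sorted p-values, controls the
family-wise error rate at α under independence and is conservative under
the positive dependence induced by a shared control; the test suite
verifies FWER control empirically on 10,000 simulated global-null
replicates (5 groups of n = 6).

## Proteomics

**Percentile ranks.** Within each sample, proteins are ranked ascending by
spectral count with average ranks for ties, rescaled as
(rank − 1)/(n − 1) × 100 over the union protein list, so the extremes sit
at exactly 0 and 100. Proteins not detected in a sample (SpC = 0) are
assigned percentile 0 and marked, rather than dropped — matrix-only
proteins are a central observation, and dropping them would erase exactly
the signal of interest. Ranking over the union list (not per-sample
detected lists) keeps percentiles comparable across samples; the
alternative is one ranking convention away and was not adopted because it
makes the 0-percentile ambiguous. Group summaries report mean ± SEM
(sd/√n, n−1 denominator) and the matrix-minus-fluid rank difference.

**Isoelectric points.** Net charge is the Henderson–Hasselbalch sum over
ionizable groups (D, E, C, Y and the C-terminus negative; H, K, R and the
N-terminus positive; X ignored), with the EMBOSS pKa set as default and
Lehninger / IPC_protein alternatives selectable — published pI values
depend on the pKa table used, so the table is a visible parameter, not a
constant. Z(pH) is strictly decreasing, so bisection on [0, 14] to 0.001
pH finds the unique root. Sequences whose ionizable groups are all of one
sign have no interior root; the pI is reported at the bracket edge.

**Acidic regions.** A window (default 39 residues) slides in steps of 1;
window pI is computed *excluding* terminal groups, because an internal
segment has no free termini and a 39-mer's pI would otherwise be dominated
by them. Maximal runs of windows under the threshold (default pI 4.0) are
merged, reporting the minimum window pI and the region's D/E fraction.
Region boundaries are therefore window-resolution objects: a planted
39-residue insert is covered by, not identical to, the reported region.

## Mineral composition

mol% MgCO₃ = Mg/(Mg + Ca) × 100 treats carbonate as the only Mg/Ca host
phase. Atomic ratios (not weight ratios) are used, the standard convention
for Mg-calcite. The measure is invariant to the overall normalization of
the inputs, so vendor atomic fractions and proportional raw-count proxies
are equally acceptable; raw-spectrum quantification (peak fitting,
k-factors, ZAF) is out of scope. Readings are averaged per sample
(conventionally 3 at random positions), and per-sample means feed the dose
summaries.

## The synthetic-data model

The generator is two-tier by design:

* the **phenomenological tier** (`simulate_drift_plate()`,
  `simulate_phstat()`) plants exact truth: a logistic
  H(t) = H₀ + ΔH/(1 + e^(−(t−t₅₀)/s)) with s = ΔH/(4·R_max) and t₅₀
  positioned so the noiseless 10% crossing equals the planted nucleation
  time. Gaussian noise is added on the *absorbance* channel (instrument
  noise lives there, not on pH). This tier backs all parameter-recovery
  claims, because recovery must not depend on invented chemistry.
* the **mechanistic tier** (`solve_carbonate_ph()`,
  `step_precipitation()`, `simulate_mechanistic_plate()`,
  `simulate_eds()`) solves the closed carbonate system — bisection of the
  alkalinity balance alk = [HCO₃⁻] + 2[CO₃²⁻] + [OH⁻] − [H⁺] on pH ∈
  [2, 12] with K1 = 10^−6.35, K2 = 10^−10.33, Kw = 10^−14,
  Ksp(calcite) = 10^−8.48 — and integrates a rate law
  r = f(c)·k·(Ω − 1)² with sub-stepping capped at 5% of the tightest pool.
  Per unit precipitated, Ca and DIC fall by 1 and alkalinity by 2; Mg
  leaves at D(c)·(Mg/Ca)·r.

Dose dependence enters through two invented but mechanistically shaped
functions: the biphasic rate factor
f(c) = (1 + a·c/(c + K_p))/(1 + (c/K_i)^h) (defaults a = 2, K_p = 0.1,
K_i = 2 µg/ml, h = 3), giving promotion at low dose and inhibition at
high dose, and the Mg partition D(c) = D₀/(1 + c/K_m) (defaults
D₀ = 0.11, K_m = 1 µg/ml), giving monotonically Mg-poorer mineral with
dose. The buffer defaults (Ca 10 mM, DIC 10 mM, Mg 50 mM, alkalinity
10 meq/L) are placeholder assay-buffer values chosen to start the system
near pH 8.3 inside the indicator range with a Mg:Ca of 5 mimicking
intestinal fluid; D₀ and the in-vivo-like effective dose (0.7 µg/ml in
`simulate_eds()`) were calibrated by closed form so the zero-dose mineral
sits near the top of the observed in vitro Mg range and the in-vivo-like
condition reproduces field-collected precipitate composition. Freshwater
constants are used because the assay buffer is not seawater; they and all
dose-response parameters are arguments, not constants.

What the generators deliberately do **not** emulate: nucleation
stochasticity and induction barriers (the mechanistic rate law starts
precipitating immediately once Ω > 1, so its absolute lag times are
shorter than real assays — only normalized, between-dose comparisons are
meaningful there); CaCO₃ turbidity at 594 nm; evaporation under plate
seals; titrator control-loop dynamics; activity corrections and ion
pairing (a Pitzer/Davies treatment is out of scope); and
peptide-to-protein inference in the count tables (counts are drawn
per protein, negative-binomially, with planted fold-enrichment and
matrix-only zeros). Passing tests on synthetic data therefore validate
the estimators' correctness and calibration, not the chemistry of any
particular buffer.

## Numerical choices

* Threshold crossings are linearly interpolated between samples, giving
  continuous-valued times from discrete schedules.
* Rolling medians use `stats::runmed` with median end-rules; monotone
  series are left monotone with unchanged interior values.
* Bisection tolerances: 0.001 pH (pI), 10⁻⁷ pH (carbonate solver, checked
  against a 10⁻⁴-step grid scan).
* OLS is computed by the closed two-moment form; tests verify agreement
  with `lm()` and hand formulas to 10⁻⁹ relative or better.
* Degenerate inputs are flagged, not guessed at: flat wells are
  `no_precipitation`, empty rate windows `rate_window_empty`, an
  all-identical ANOVA is `F_undefined`, and a Brown–Forsythe on groups
  with identical spreads reports F = 0, p = 1.
* Ties in spectral counts take average ranks; single-protein tables take
  percentile 0 by convention.

## Problem sizes

The test suite and the acceptance script run: 6-replicate plates at 3
doses on the full 295-point sampling schedule (30 s × 30 min, then
5 min × 19.5 h) with absorbance noise SD 0.005; 1,000 random sequences of
length 10–500 for the pI oracle check; 10,000 global-null replicates
(5 groups × n = 6) for the family-wise-error calibration; and 25 seeds for
planted-enrichment recovery, sizes chosen to make Monte-Carlo error small
relative to the tolerances being checked.

## Known limitations

* The drift metrics assume an eventually sigmoid (or at least saturating)
  [H⁺] course; wells still accelerating at the end of the assay will have
  their ΔH, and hence both metrics, underestimated.
* Normalization divides by the control *mean*; with very few controls a
  single aberrant control well propagates into every normalized value
  (flagging on the control wells mitigates this).
* The pI model ignores post-translational modifications (phosphorylation,
  glycosylation) that make real matrix proteins more acidic than their
  sequence predicts; computed pIs are upper bounds in that sense.
* Percentile ranks compress extreme abundance differences; a protein 100×
  and one 2× more abundant than the next can carry the same rank
  difference.
* The mechanistic simulator is a property-testing instrument, not a
  geochemical model: no activity corrections, no Mg inhibition of calcite
  growth, no surface-area dependence.
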