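---
title: "Modelling dynamic-SILAC protein turnover: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling dynamic-SILAC protein turnover: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(silacturnover)
```

## The kinetic model

After a light-to-heavy medium switch at t = 0, the pre-existing light pool
of a protein decays first-order, `P_L(t) = P_TOT e^{-kt}`, and under steady
state (constant total amount, synthesis and degradation; cells at
confluence; no amino-acid recycling; one kinetic compartment) the heavy
pool is the complement, `P_H = P_TOT - P_L`. The observable is the
heavy/light ratio

$$r(t) = \frac{P_H}{P_L} = \frac{1 - e^{-kt}}{e^{-kt}} = e^{kt} - 1,
\qquad \ln(r + 1) = k\,t .$$

The log-transformed ratio is therefore *exactly* linear in time with no
intercept: the label fraction is zero at the switch. `fit_k_wls()` and the
batch `fit_turnover()` fit this line through the origin by weighted least
squares,

$$\hat k = \frac{\sum_i w_i t_i y_i}{\sum_i w_i t_i^2},\qquad
\mathrm{se}(\hat k) = \Big(\sum_i w_i t_i^2\Big)^{-1/2},\qquad
y_i = \ln(r_i + 1),$$

and report the half-life `T½ = ln 2 / k` together with the estimate CV
`100·se/|k|`, the package's reliability metric.

Assumptions worth stating plainly: no intercept (an intercept would absorb
label-uptake lag, which the mono-compartmental model excludes); no
cell-division dilution term (the design is at confluence); ratios below
detection are *missing*, never zero (an absent heavy signal carries no
slope information).

## The technical-variability model and the weights

The spread of replicate ratio measurements is neither constant in SD nor
constant in CV: the SD grows and the CV falls with r. Both one-parameter
alternatives are rejected by `constant_model_diagnostic()` (one-sided
Spearman tests on binned medians at the 0.05 level), which motivates the
two-parameter form

$$\mathrm{SD}(r) = \sqrt{\alpha^2 + \beta^2 r^2},$$

an additive floor α (ratio units, dominant at small r) plus a
proportional term β (the asymptotic relative error). The pipeline default
fixes (α, β) = (0.02, 0.1); `pipeline_config(fit_noise = TRUE)`
recalibrates from the data instead.

Weights for the kinetic fit come from the delta method:
`Var(ln(r+1)) = SD(r)² / (1+r)²`, so `w = (1+r)²/SD(r)²`. They are treated
as *absolute* inverse variances: with 2–3 points per fit, rescaling by the
residual chi-square would be far noisier than the calibrated noise model
itself, so `se(k̂)` uses the a-priori weight matrix. The weights use the
noise law evaluated at the protein-level r, not the observed per-protein
peptide SD — individual peptide SDs at n = 2–15 are too unstable to weight
with.

### Calibration procedure and its operating range

`bin_ratios()` tiles the observed r range into 0.05-wide bins, merging any
bin under 10 members rightward (a trailing under-filled bin is kept with
weight n/10), and records the median of member across-peptide SDs.
`fit_noise_model()` then minimises the sum of squared deviations in SD
space — the measured and plotted quantity — with non-negativity enforced
by optimising over α², β² (Levenberg–Marquardt with box constraints).

Two numerical points matter. First, α is identified only by bins at small
r, but the measurement-CV filter (below) removes measurements whose
across-peptide CV exceeds 50%, and the *model* CV exceeds 50% for
r ≲ 0.04; calibrating on data concentrated below that point would truncate
the SD distribution and bias α down. The calibration experiments in the
tests and the acceptance script therefore place true ratios log-uniformly
on [0.05, 1.5] with 12 replicates — dense low-r coverage above the filter
horizon. Second, the median of n-replicate sample SDs underestimates the
true SD by ≈ 4% at n = 12 (chi distribution median); this is within the
10% recovery tolerance and is accepted rather than corrected, matching
the plain-median procedure.

## Filters and their order

The stage order is fixed (and `run_pipeline()` does not allow
reordering, to keep provenance unambiguous):

1. **Aggregation**: protein-level r per (protein, subject, time) is the
   *median* of peptide ratios; sample SD and CV (%) over the same set.
   Single-peptide measurements get SD = 0, CV = 0 and a `single_peptide`
   flag: the CV filter targets multi-peptide disagreement, which a
   singleton cannot show, so they are retained but transparently marked.
2. **Measurement-CV filter**: protein measurements with across-peptide CV
   strictly above 50% are excluded (a value exactly at 50% stays).
3. **Time-coverage filter**: a (protein, subject) pair enters the kinetic
   fit only with a measurement at 24 h *and* at least one of 4/7.5 h. The
   late point anchors the slope for long-lived proteins whose ratio grows
   slowly; a lone late point cannot distinguish fast from slow decay.
4. **Fit-CV filter**: fits with estimate CV above 50% — or with k ≤ 0 —
   are dropped from cohort statistics. With non-negative ratios,
   `k̂ = Σwty/Σwt² ≥ 0` structurally; k = 0 (no label uptake observed at
   all) is the degenerate boundary and is flagged invalid rather than
   given an infinite half-life.

Every filter attaches its exclusions as an attribute, and the pipeline
manifest accounts for each row in and out, because count-based reporting
is how this kind of analysis is audited.

## Relative abundance and the steady-state diagnostic

Per (subject, time) sample — with multiple runs merged at the peptide
level first — a protein's relative abundance is
`(Σ peptide intensity / n observed peptides) / (total sample intensity)`,
which is invariant to global intensity rescaling of a run. "Observed
peptides" counts distinct peptide identifiers, not spectra. Under steady
state the per-time values are averaged arithmetically and reported with
their log2.

`steady_state_check()` tests the premise on the data: per protein and
subject, the variance of abundance across time points is compared with
the technical variance (median across times of the across-peptide
variance of peptide-level relative intensity in the same sample). In a
stationary cohort the temporal variance should not exceed the technical
one for most proteins; an abundance ramp injected across time points
makes the flagged ratio explode, which the tests use as a positive
control.

## Cohort statistics

Cross-subject summaries keep proteins quantified in ≥ 2 of the 10
subjects. Two-group comparisons (diabetic controls vs nephropathic)
require ≥ 2 subjects per group and use the pooled-variance Student t-test,
two-tailed — not Welch, matching the unpaired-Student convention of the
analysis this package implements; a Shapiro–Wilk flag on pooled
within-group residuals (0.05 level) travels with each test but does not
block it. Benjamini–Hochberg adjusted p-values are reported alongside raw
ones (BH chosen as the field default; at n = 5 vs 5 little is expected to
survive adjustment). Abundance fold changes are signed ratios of group
means: ratios below 1 are reported as the negative reciprocal, so sign
encodes direction and |FC| ≥ 1 always.

Half-life summaries are binned into nine left-closed intervals
(<20, [20,30), …, [80,90), ≥90 h) and log2 abundances into eight
(<5.0, [5.0,6.0), [6.0,6.5), …, ≥9.0); ties at an edge go right
(into the higher bin), and the same closed-upper rule applies to the
quadrant classification of the (abundance, k) plane. No universal
quadrant thresholds exist — they are explicit arguments, typically set
near the cohort medians.

`complex_vs_random()` quantifies half-life coherence of a protein
complex: the dispersion (SD, IQR) of the members' mean half-lives is
compared against 10 random same-size sets drawn without replacement from
the full table under a caller-supplied seed; the fraction of random sets
with larger dispersion is the coherence score. Under the null (a random
"complex") that fraction is roughly uniform, which the tests verify.

## The synthetic-data generator

`simulate_cohort()` emulates the targeted study design: 2 groups × 5
subjects, times {4, 7.5, 24} h, ~1,000 proteins with 2–15 peptides, true
half-lives log-uniform on [3, 600] h, true abundance log-uniform over
four orders of magnitude, ratio noise per the (0.02, 0.1) law placed
directly on r (truncated at zero by resampling, since the law models the
SD of r itself). Where the design leaves parameters open, they were fixed
once at values a proteomics practitioner would call realistic and not
revisited: between-subject biological CV 10% on k and abundance
(lognormal — half-lives are positive and right-skewed), peptide
ionization factors lognormal with sdlog = 1 fixed per peptide across time
(so abundance is time-stationary by construction), 20% multiplicative
intensity measurement noise, 10% missing-completely-at-random dropout per
(protein, subject, time), and a 5% fraction of (protein, subject) pairs
whose 24 h point is removed outright so the coverage filter has a known
ground-truth exclusion set. Group effects multiply the half-life of a
designated protein subset in the nephropathic group (default experiments
use ×1.23, the scale of the changes the method is meant to detect).

What the generator does *not* emulate: spectral detectability bias,
charge states and retention time, shared peptides, label conversion
artifacts, batch effects between runs. Passing tests therefore show the
*estimator chain* is correct under the stated model, not that the model
captures every property of real LC-MS/MS data.

## Problem sizes and numerical choices

The validation suite uses cohorts of 300–1,000 proteins and calibration
sets of ~4,000 replicate groups — large enough for the binomial and rank
tests to have power, small enough to run interactively. Determinism is a
contract: a seed fully determines generator output, and the complex
resampling restores the RNG state afterwards. Noiseless-limit tests
demand machine-precision recovery (the closed-form estimator is exact);
stochastic recovery tests assert the documented tolerances (median bias
of k̂ under 2%, ≥ 90% coverage of k within ±2 se for T½ ≤ 200 h, noise
parameters within 10%). Estimate CVs degrade with true half-life — at
24 h a protein with T½ = 600 h has r ≈ 0.028, barely above the noise
floor — which is why coverage is quoted for T½ ≤ 200 h and why the late
time point is mandatory.

## Known limitations

- Very long-lived proteins (T½ ≫ 200 h) are at the edge of what a 24 h
  course can measure; their estimates carry large CVs and are often
  filtered, so cohort summaries under-represent them.
- The a-priori se(k̂) ignores residual lack-of-fit; it is honest only to
  the extent the noise model is correct at the protein level (the median
  over peptides makes it conservative in the tests).
- The pooled t-test at n = 5 vs 5 has modest power; the package reports
  BH-adjusted values but analyses at this scale are screening, not
  confirmation.
- Abundance is relative within-cohort only; no absolute (iBAQ-style)
  calibration is attempted.
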