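# silacturnover

Protein turnover analysis for dynamic-SILAC (pulsed-SILAC) time courses in R.

In a dynamic-SILAC experiment, cells are switched from light to heavy
(isotope-labelled) medium at t = 0 and sampled over a short time course.
The heavy/light peptide ratio r tracks label incorporation: under
steady-state conditions (constant total protein, constant synthesis and
degradation, no amino-acid recycling, mono-compartmental kinetics) the
pre-existing light pool decays as P_L = P_TOT·e^(−kt), the heavy pool is
P_H = P_TOT − P_L, and

    r(t) = P_H / P_L = (1 − e^(−kt)) / e^(−kt) = e^(kt) − 1,

so **ln(r + 1) = k·t** is linear through the origin. `silacturnover`
estimates the degradation rate constant k per protein and subject by
weighted least squares on this line, with weights from a calibrated
technical-variability model of the ratio,

    SD(r) = sqrt(alpha^2 + beta^2 · r^2)      (defaults alpha = 0.02, beta = 0.1),

propagated to ln(r + 1) by the delta method. Half-lives follow as
T½ = ln 2 / k. The package also computes intensity-based relative protein
abundance (summed peptide intensity / peptide count, normalised by the run
total, averaged over time points under steady state), two-group cohort
comparisons (pooled t-test, Shapiro–Wilk normality flag, BH-adjusted p,
signed fold change), half-life/abundance interval binning, quadrant
classification of the turnover-abundance plane, and a coherence test of
macromolecular-complex half-lives against random same-size protein sets.
A synthetic-cohort generator with known ground truth (two groups of five
subjects, times 4/7.5/24 h, log-uniform half-lives 3–600 h, abundance over
four orders of magnitude, 2–15 peptides per protein, the noise law above,
realistic missingness) makes every stage testable end to end.

## Worked example

```r
library(silacturnover)
library(dplyr)

cfg <- synthetic_config(
  n_proteins = 300, seed = 7,
  group_effect = list(proteins = sprintf("P%04d", 1:20),
                      halflife_ratio = 1.23))
sim <- simulate_cohort(cfg)
res <- run_pipeline(sim$measurements)

res$manifest
#> # A tibble: 5 × 4
#>   stage                  n_in n_out n_excluded
#>   <chr>                 <int> <int>      <int>
#> 1 aggregate             65682  7956      57726
#> 2 measurement_cv_filter  7956  6353       1603
#> 3 time_coverage_filter   6353  5343       1010
#> 4 kinetic_fit            5343  2034       3309
#> 5 fit_cv_filter          2034  2025          9
```

65,682 peptide observations collapse to 7,956 protein-level ratio
measurements (median over peptides); 1,603 are discarded for
across-peptide CV above 50%; 1,010 rows belong to (protein, subject)
pairs lacking the mandatory 24 h point plus one earlier point; the
remaining rows yield 2,034 per-subject rate fits, of which 2,025 have an
estimate CV at or below 50% and count as reliable.

```r
res$fits_reliable |> select(protein_id, subject_id, k, se_k, cv_k, half_life_h) |> head(3)
#> # A tibble: 3 × 6
#>   protein_id subject_id      k    se_k  cv_k half_life_h
#>   <chr>      <chr>       <dbl>   <dbl> <dbl>       <dbl>
#> 1 P0002      D01        0.0277 0.00166  5.99        25.0
#> 2 P0002      D05        0.0247 0.00157  6.34        28.0
#> 3 P0002      N01        0.0263 0.00162  6.17        26.4

res$comparison_halflife |> arrange(p_value) |>
  select(protein_id, variable, mean_a, sd_a, n_a, mean_b, sd_b, n_b, p_value, fdr_bh) |> head(3)
#> # A tibble: 3 × 10
#>   protein_id variable  mean_a  sd_a   n_a mean_b  sd_b   n_b p_value fdr_bh
#>   <chr>      <chr>      <dbl> <dbl> <int>  <dbl> <dbl> <int>   <dbl>  <dbl>
#> 1 P0004      half_life   4.38 0.329     5   5.57 0.466     5 0.00162  0.288
#> 2 P0017      half_life  57.7  2.06      5  70.5  5.89      4 0.00253  0.288
#> 3 P0018      half_life   2.74 0.341     3   3.78 0.197     4 0.00365  0.288
```

The proteins with the smallest p-values are drawn from the subset whose
half-life was lengthened by 23% in the nephropathic group — the injected
effect is recovered, while (as expected at n = 5 vs 5) little survives
FDR correction. `k` is in h⁻¹, `half_life_h` in hours; `mean_a`/`mean_b`
are the per-group mean half-lives.

Plots: `autoplot(noise_model_fit)`, `plot_halflife_distribution()`,
`plot_steady_state()`, `plot_turnover_quadrants()`.

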