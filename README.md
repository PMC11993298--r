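# cocktailpk

Population-pharmacokinetic analysis of a five-drug microdose cocktail used
to probe drug transporter and enzyme (DMET) activity in end-stage renal
disease (ESRD). The cocktail pairs each probe with the pathway that
rate-limits it — midazolam (MDZ, 10 µg) for CYP3A, dabigatran etexilate
(DAB, 375 µg) for intestinal P-gp, pitavastatin (PTV, 10 µg) for OATP1B,
rosuvastatin (RSV, 50 µg) for OATP1B/BCRP and atorvastatin (ATV, 100 µg)
as a mixed substrate — so group differences in apparent clearance between
healthy volunteers (HV) and ESRD patients translate into DMET activity
changes.

The package is aimed at pharmacometricians and clinical-pharmacology
researchers who want the full analysis chain as reusable, tested R
functions operating on tidy data frames:

* **Structural model.** Closed-form two-compartment oral model
  (CL/F, V~c~/F, V~p~/F, Q/F, k~a~), tri-exponential solution with
  superposition, analytic handling of absorption/disposition rate ties,
  and `AUC_inf = dose/(CL/F)` as an exact oracle.
* **Final covariate models** for all five drugs, e.g.
  `CL/F_DAB = 146 · e^0.225 · (1 + DIS_DAB)` with `DIS_DAB = −0.869`, and
  `CL/F_PTV = 16.5 · e^0.096 · exp(−0.677·Veil/1.08) · (1 + DIS_PTV)` where
  `Veil` is the genus *Veillonella* relative abundance (%).
* **Synthetic cohorts** emulating the study arms (14 HV / 10 ESRD,
  published mean/CV% covariates, CKD-EPI eGFR eligibility, genus abundance
  ranges, CPIC-style transporter phenotypes) — the stand-in for the
  unreleased clinical dataset.
* **NCA**: linear-up/log-down AUC, geometric-mean summaries, ESRD/HV
  exposure ratios with Welch-on-logs inference, unbound-exposure
  adjustment, stratified summaries.
* **Mixed-effects estimation**: MAP Bayes individual estimates, Laplace
  (FOCE-like) population refitting with a compiled inner Newton engine,
  stratified subject-level bootstrap, visual predictive checks.
* **DMET activity translation**: closed forms for the OATP1B decrease
  (−38% direct ESRD effect, up to −75% at the largest Veillonella
  abundance), the intestinal P-gp decrease from the dabigatran
  filtration mass balance (29–44%), and the coproporphyrin-I cross-check
  (47% remaining OATP1B function).
* **Covariate machine learning**: correlation screening (Spearman,
  p < 0.05) and LASSO at λ-min with leave-one-out CV, plus the five
  published regression model cards.

## Worked example

```r
library(cocktailpk)

subjects <- simulate_cohort(n_hv = 14, n_esrd = 10, seed = 1)
records  <- simulate_trial(subjects, seed = 2)
nca_df   <- nca(records)
dplyr::filter(exposure_ratio_table(nca_df), metric == "auc_last")
#> # A tibble: 5 × 7
#>   drug   gm_hv gm_esrd ratio  lo95  hi95        p
#>   <chr>  <dbl>   <dbl> <dbl> <dbl> <dbl>    <dbl>
#> 1 ATV    124.     81.5 0.655 0.284 1.51  3.04e- 1
#> 2 DAB   2368.   7738.  3.27  2.72  3.93  4.39e-11
#> 3 MDZ     71.3    19.7 0.276 0.141 0.540 1.62e- 3
#> 4 PTV    580.    936.  1.61  1.18  2.20  4.32e- 3
#> 5 RSV    866.    448.  0.517 0.274 0.973 4.25e- 2
```

One synthetic trial of 24 subjects reproduces the qualitative pattern the
cocktail is designed to expose: dabigatran exposure rises ≈3-fold in ESRD
(P-gp impairment), pitavastatin rises significantly (OATP1B impairment),
midazolam falls by ≈70% (apparent CYP3A gain, confounded by unbound
fraction), while rosuvastatin and atorvastatin move less because opposing
pathways compensate. The activity report turns the model constants into
DMET statements:

```r
dmet_activity_report(veil = max(subjects$Veillonella))
#> # A tibble: 5 × 4
#>   dmet           quantity                                   value
#> 1 OATP1B         activity decrease, direct ESRD effect (%)     38
#> 2 OATP1B         activity decrease at Veillonella 1.16% (%)    70
#> 3 Pgp_intestinal activity decrease, Rf = 0.85 (%)              29
#> 4 Pgp_intestinal activity decrease, Rf = 0.80 (%)              43
#> 5 OATP1B         remaining function, CP-I mass balance (%)     47
```

(The OATP1B row depends on the largest Veillonella abundance in the
generated cohort — 1.16% here; at the study's observed maximum of 1.42% it
evaluates to 75%.)

`run_pipeline(run_config(seed = 1))` chains cohort → trial → NCA → MAP
Bayes clearances → activity report → correlation/LASSO screen and writes
one stamped CSV per stage. See `vignette("cocktailpk-methods")` for the
model assumptions, estimation details and design decisions.

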