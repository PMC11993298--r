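---
title: "Methods: microdose-cocktail population PK and DMET activity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: microdose-cocktail population PK and DMET activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cocktailpk)
```

## What the package models

A microdose cocktail study gives five probe substrates simultaneously at
sub-pharmacological doses — 10 µg midazolam (MDZ, CYP3A), 375 µg dabigatran
etexilate (absorbed as the prodrug, measured as dabigatran, DAB; intestinal
P-gp), 10 µg pitavastatin (PTV, OATP1B), 50 µg rosuvastatin (RSV,
OATP1B/BCRP) and 100 µg atorvastatin (ATV, mixed) — to healthy volunteers
(HV) and end-stage renal disease (ESRD) patients on dialysis. Because each
probe is rate-limited by one transporter or enzyme family, changes in its
apparent clearance translate into activity changes of that DMET
(drug-metabolizing enzyme or transporter).

The package provides the full quantitative chain at desk scale: a synthetic
cohort generator standing in for the unreleased clinical dataset, the
structural and covariate PK models, non-compartmental analysis (NCA),
nonlinear mixed-effects estimation, and the closed-form translation of model
parameters into DMET activity statements, plus the correlation/LASSO
covariate-selection stage.

## Structural model

All drugs use a two-compartment model with first-order absorption and
first-order elimination, parameterized as apparent clearances/volumes
(CL/F, V~c~/F, V~p~/F, Q/F, k~a~). Internally the package works in hours,
pg, litres and pg/mL; dose amounts enter in micrograms and are converted at
the boundary (1 µg = 10^6^ pg). The concentration solution is the standard
tri-exponential closed form obtained from the micro-constants
k~10~ = CL/V~c~, k~12~ = Q/V~c~, k~21~ = Q/V~p~ and the disposition
exponents α > β > 0 (roots of s² − (k~10~+k~12~+k~21~)s + k~10~k~21~).
Numerical choices:

* when k~a~ is within a relative 10^-8^ of α or β the 0/0 form is replaced
  by its analytic L'Hôpital limit (a t·e^−αt^ term), so tied rates never
  produce NaN;
* a zero peripheral volume or inter-compartmental clearance is rejected
  explicitly rather than silently collapsing to one compartment;
* multiple doses superpose linearly; lag time is fixed at zero.

The administered DABE mass (375 µg) is used directly as the DAB dose; the
mass conversion from prodrug to metabolite is absorbed into apparent
bioavailability, consistent with modelling measured DAB concentrations.

## Final covariate models

Typical values, covariate effects, and inter-individual variability (IIV)
for the five drugs are shipped in `default_models()`. Covariate effects use
three forms:

* **proportional shift** `1 + θ·DIS` for the ESRD disease indicator
  (θ = −0.381 PTV, −0.869 DAB, +0.94 MDZ — the positive midazolam effect is
  taken at face value: ESRD nearly doubles apparent clearance, with the
  unbound-fraction caveat handled at the activity-translation step);
* **scaled exponential** `exp(θ·X/1.08)` for genus relative abundances
  (θ = −0.677 for Veillonella on PTV clearance, −3.26 for Clostridium_XIVb
  on RSV clearance). The printed equations are typographically ambiguous
  about this form; the scaled exponential is adopted because it reproduces
  the published "up to 75%" OATP1B decrease at the largest observed
  Veillonella abundance (1.42%), which a power-of-median form does not. The
  same 1.08 scaling constant is applied to both genera, as printed;
* **power of normalized covariate** `(ALB/42.1)^−6.42` for serum albumin on
  the RSV central volume (42.1 g/L is the patient-group mean albumin).

IIV percentages are interpreted as 100·ω with ω the log-normal SD
(`parameter_i = typical × e^η`, η ~ N(0, ω²)), matching the e^0.225^-style
factors in the published equations. Absorption constants printed without
uncertainty (PTV 18 h^−1^, MDZ 13 h^−1^) are treated as fixed a priori and
are not re-estimated.

The residual-error model is unreported in the source; the package default
is a combined model with proportional SD 0.20 and an additive floor of
1 pg/mL. This is a documented fixture, configurable per run.

## Synthetic cohorts

The generator emulates the study conditions rather than any individual
data:

* arm sizes default to 14 HV / 10 ESRD with sex ratios 5M/9F and 7M/3F
  scaled to the requested sizes;
* every numeric covariate is log-normal with the published group mean and
  CV% (all published quantities are positive); covariates the printed
  regression equations need but the demographic table does not report
  (urea, triglycerides, platelets, creatine kinase-MB, height) carry
  plausible fixture values flagged `fixture = TRUE` in
  `covariate_stats()`;
* lab-lab correlations default to zero — marginals, not joint structure,
  are what the published summaries constrain;
* eGFR is computed from creatinine, age and sex with the 2009 CKD-EPI
  creatinine equation (race coefficient omitted for a single-ethnicity
  cohort); ages are kept inside the 18-65 year eligibility window, and
  creatinine is redrawn until the arm's eligibility bound (HV ≥ 90,
  ESRD ≤ 15 mL/min/1.73 m²) holds;
* genus abundances are log-uniform within per-genus ranges; Veillonella
  (0.015-1.42%) and Phascolarctobacterium (0.005-37%) use published ranges,
  the remaining genera use fixture ranges;
* genotypes are drawn under Hardy-Weinberg equilibrium at East-Asian-
  plausible fixture frequencies and mapped to CPIC-style phenotypes
  (CYP3A5 from rs776746; OATP1B1 from rs4149056/rs2306283; BCRP from
  rs2231142);
* unbound fractions are per-drug/per-group fixtures anchored to the
  reported 62% f~u~ increase of midazolam in ESRD.

Sampling schedules follow the trial: HV 0-24 h at eight points, ESRD
pre-dose, 1, 4, 24 h (pre-dialysis) and 28 h (post-dialysis). Observations
below the LLOQ (default 5 pg/mL) are retained but flagged BLQ and excluded
from analysis (M1-style); the NCA anchors each curve at the dose time with
concentration zero.

What the generator does **not** emulate: compositional microbiome
structure (abundances are independent ranged draws), lab-lab correlation,
dialysis pharmacokinetics (simulated profiles are explicitly
dialysis-free, which is what makes the 28-h predicted-vs-measured
comparison informative), and any real genotype-phenotype frequencies.
Passing tests therefore demonstrate correctness of the machinery under
these idealized conditions, not fidelity to any individual patient data.

## NCA conventions

AUC to the last quantifiable sample uses the linear trapezoid on ascending,
flat or zero-bounded segments and the log trapezoid
(c₁−c₂)/ln(c₁/c₂)·Δt on strictly descending positive segments. T~max~ ties
resolve to the earliest time. Group summaries are geometric means with
t-based 95% CIs on the log scale; ESRD/HV ratios carry both 90% and 95%
intervals, and the p-value comes from a Welch two-sample t test of the
log values — the published comparison does not name its test, so this is a
documented package choice. Unbound exposures multiply the metrics by f~u~.

## Estimation

Individual (MAP Bayes) estimates maximize the product of the residual
likelihood and the N(0, ω²) prior by a damped Newton iteration with
Gauss-Newton curvature, started from η = 0 plus four jittered starts.
With proportional error and interaction, the posterior mode for perfect
noise-free data sits O(σ²) away from zero (the log-variance term trades
off against residuals) — about 4% at σ~p~ = 0.2; this is a property of the
objective, not a defect, and the tests bound it accordingly.

Population fitting maximizes a Laplace approximation of the marginal
likelihood over log typical values, covariate coefficients, log ω and
(optionally) log σ~p~, using `nlminb`. Per subject the inner mode is found
by the same Newton iteration, always started from the origin so that the
outer objective is a pure function of the parameters (warm-started inner
modes make the objective history-dependent and stall the outer optimizer).
The curvature term uses the Gauss-Newton (FOCE-like) approximation
J'V^−1^J + Ω^−1^. Equivalence with reference NONMEM FOCE-I is claimed only
at the parameter-recovery level, never at the objective-function value.

The parameter-recovery experiment exercised by the test suite simulates
200 subjects per drug (100 HV + 100 ESRD covariates) from the shipped
final models on a rich ten-point design to 48 h and refits from start
values jittered by up to ±25% (±30% on ω, covariate coefficients shrunk
toward zero where feasibility requires it). Three deliberate design
choices: the design includes 0.25-h samples because atorvastatin's
absorption peaks near 0.3 h and the clinical 0.5-h first sample leaves a
flat k~a~-V~c~ ridge; it extends to 48 h because the 24-h clinical window
cannot identify rosuvastatin's ≈85-h terminal phase; and the recovery data
are drawn from exactly the assumed Gaussian residual model — no BLQ
censoring (dropping censored records biases clearance for the
low-concentration drugs) and no non-negativity clamping (clamping the
simulated noise at zero, while physical, is a different data-generating
process than the likelihood assumes and leaves a visible tail bias in the
peripheral parameters of midazolam). A simulate-then-refit experiment
probes the estimator, so generator and likelihood must agree. One
component sits at the edge of identifiability regardless: the 7.6% IIV on
the pitavastatin inter-compartmental clearance is estimated with a
standard deviation of roughly 40% of its own value at this scale, so its
recovery error in any single experiment can exceed the tolerances that
hold for every other parameter. Bootstrap resampling is subject-level with
replacement, stratified by arm so every replicate retains both groups, and
each replicate refits from the full-data estimates (standard refitting
practice). VPCs compare observed 5th/50th/95th percentiles per arm and
time point with 95% bands of the same percentiles across simulated
replicates of the design; the quantification limit is applied identically
to observed and simulated values, since censoring only the observed side
would push the bands systematically below the data.

## DMET activity translation

All activity statements are pure closed forms over fitted quantities:

* **OATP1B** (pitavastatin): activity multiplier
  (1 + θ~DIS~)·exp(θ~Veil~·Veil/1.08) against a covariate-neutral healthy
  reference; at Veil = 0 this is the direct disease effect (≈ −38%), at the
  largest observed abundance 1.42% it reaches ≈ −75%.
* **Intestinal P-gp** (dabigatran): the clearance partition
  CL-ratio = R~nf~ + R~f~·eGFR~ESRD~/eGFR~HV~ (filtration fraction R~f~
  0.80-0.85) with the fitted apparent-clearance decrease (0.87) yields the
  bioavailability ratio; the bridge assumption — stated explicitly because
  the source leaves it implicit — is that oral bioavailability is inversely
  proportional to intestinal efflux activity, giving a 29-44% decrease.
* **CP-I cross-check**: with constant synthesis, a steady-state plasma
  level is inversely proportional to total elimination; a 2.5-fold CP-I
  increase with a 15% urinary fraction abolished leaves
  100·(1/2.5)/(1−0.15) ≈ 47% of hepatic OATP1B function.
* **BCRP / CYP3A**: directional verdicts only. BCRP is flagged possibly
  upregulated when the RSV clearance change exceeds the OATP1B-predicted
  decrease; the MDZ clearance increase is divided by the f~u~ ratio before
  any CYP3A statement. No magnitudes are produced, matching the source's
  own restraint.

Integer percents are rounded half-away-from-zero; the upper P-gp bound
computes to 43.48% and is printed as 44% in the source, a 1-point rounding
difference the tests tolerate explicitly. The published 35% lower OATP1B
bound is not forced: the default covariate form gives ≈39% at the smallest
observed abundance, and the package reports what the model implies.

## Covariate screening and LASSO

The screen correlates each candidate with individual clearance (Spearman by
default — robust at n = 10; Pearson selectable; screening against exposure
is supported but clearance is the default response) and keeps p < 0.05.
The LASSO stage standardizes predictors internally, runs coordinate descent
(glmnet) over 100 log-spaced penalties spanning four decades down from the
smallest all-zero penalty, picks λ by minimum cross-validated MSE with
leave-one-out folds by default, and reports coefficients on the original
scale. The five published regression equations ship as model cards
(`mlr_cards()`) for direct prediction.

## Problem sizes and reproducibility

Every stochastic function takes an explicit seed, and the pipeline
(`run_pipeline()`) derives per-stage seeds from one global seed, echoing it
with a configuration hash into every artifact. The test suite uses desk
scales chosen to balance statistical resolution against runtime: 10^4^
subjects for distributional checks, 200 subjects per drug for population
recovery, 100-150 replicates for VPC bands, single-digit bootstrap
replicates where only degeneracy or coverage direction is being checked.

## Known limitations

No inter-occasion variability and no covariance between random effects
(none are reported); BLQ handling is M1 only; the Laplace objective is not
numerically identical to NONMEM's FOCE-I; covariates are generated
marginally independent; genotype frequencies, residual-error magnitudes,
some genus ranges and all f~u~ values are fixtures, clearly flagged, and
any conclusion that depends on them is a statement about the synthetic
conditions, not about patients.
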