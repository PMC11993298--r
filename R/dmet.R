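#' Round half away from zero
#'
#' Integer-percent rounding used in the activity reports (base `round()`
#' rounds half to even, which does not reproduce printed bounds).
#'
#' @param x Numeric.
#' @param digits Decimal places (default 0).
#' @return Rounded value.
#' @export
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' OATP1B activity decrease from the pitavastatin covariate model
#'
#' The hepatic uptake activity probed by pitavastatin clearance is the
#' product of the ESRD disease-state multiplier `(1 + dis_effect)` and the
#' Veillonella abundance factor `exp(theta_veil * veil / normalizer)`,
#' relative to a covariate-neutral healthy reference. Returns the percent
#' decrease `100 * (1 - multiplier)`.
#'
#' @param dis_effect Disease-state effect on CL/F (default -0.381).
#' @param theta_veil Veillonella coefficient (default -0.677).
#' @param veil Veillonella relative abundance, percent (>= 0).
#' @param normalizer Abundance scaling constant (default 1.08).
#' @return Percent decrease in OATP1B activity.
#' @examples
#' oatp1b_activity(veil = 0)     # direct disease effect, ~38%
#' oatp1b_activity(veil = 1.42)  # maximum observed abundance, ~75%
#' @export
oatp1b_activity <- function(dis_effect = -0.381, theta_veil = -0.677,
                            veil = 0, normalizer = 1.08) {
  if (any(veil < 0)) stop("abundance must be >= 0", call. = FALSE)
  mult <- (1 + dis_effect) * exp(theta_veil * veil / normalizer)
  if (any(mult <= 0)) stop("activity multiplier must be positive", call. = FALSE)
  100 * (1 - mult)
}

#' Intestinal P-gp activity decrease from the dabigatran mass balance
#'
#' Dabigatran is eliminated by glomerular filtration (fraction `r_f`,
#' 0.80-0.85) and non-filtration routes (`r_nf`), so the true clearance
#' ratio between ESRD and healthy subjects is
#' `CLr = r_nf + r_f * egfr_esrd / egfr_hv`. The model sees only apparent
#' clearance `CL/F`, reduced by `effect_esrd` (0.87), hence the
#' bioavailability ratio is `Fr = CLr / (1 - effect_esrd)`. Under the
#' bridge assumption that oral bioavailability is inversely proportional to
#' intestinal efflux activity, the efflux activity change is
#' `100 * (1 - 1/Fr)`.
#'
#' @param effect_esrd Fractional decrease of apparent clearance in ESRD
#'   (0 < effect < 1).
#' @param egfr_esrd,egfr_hv Mean eGFR of the two groups,
#'   mL/min/1.73 m2 (defaults 4 and 106.6).
#' @param r_nf,r_f Non-filtration and filtration elimination fractions;
#'   must sum to 1.
#' @return Percent decrease in intestinal P-gp activity.
#' @examples
#' pgp_activity_change(0.87, r_nf = 0.15, r_f = 0.85) # ~29%
#' pgp_activity_change(0.87, r_nf = 0.20, r_f = 0.80) # ~44%
#' @export
pgp_activity_change <- function(effect_esrd, egfr_esrd = 4, egfr_hv = 106.6,
                                r_nf = 0.15, r_f = 0.85) {
  if (abs(r_nf + r_f - 1) > 1e-9) stop("r_nf + r_f must equal 1", call. = FALSE)
  if (effect_esrd < 0 || effect_esrd >= 1) {
    stop("effect_esrd must lie in [0, 1)", call. = FALSE)
  }
  cl_ratio <- r_nf + r_f * egfr_esrd / egfr_hv
  f_ratio <- cl_ratio / (1 - effect_esrd)
  100 * (1 - 1 / f_ratio)
}

#' Remaining OATP1B function implied by coproporphyrin-I
#'
#' Steady-state mass balance for the endogenous biomarker CP-I with
#' constant synthesis: plasma level is inversely proportional to total
#' elimination. If ESRD raises CP-I `fold_increase`-fold while abolishing a
#' urinary excretion fraction `urinary_fraction`, the remaining hepatic
#' (OATP1B-mediated) share of healthy function is
#' `100 * (1 / fold_increase) / (1 - urinary_fraction)`.
#'
#' @param fold_increase Fold increase of plasma CP-I in ESRD (> 0).
#' @param urinary_fraction Healthy urinary excretion fraction, in `[0, 1)`.
#' @return Remaining OATP1B function, percent of healthy.
#' @examples
#' cp1_remaining_oatp1b(2.5, 0.15) # ~47%
#' @export
cp1_remaining_oatp1b <- function(fold_increase, urinary_fraction) {
  if (fold_increase <= 0) stop("fold_increase must be > 0", call. = FALSE)
  if (urinary_fraction < 0 || urinary_fraction >= 1) {
    stop("urinary_fraction must lie in [0, 1)", call. = FALSE)
  }
  100 * (1 / fold_increase) / (1 - urinary_fraction)
}

#' Directional verdicts for BCRP and CYP3A
#'
#' BCRP: rosuvastatin is cleared by both OATP1B (uptake) and BCRP
#' (efflux); if the observed RSV clearance change exceeds what the
#' OATP1B decrease alone would predict, BCRP is flagged as possibly
#' upregulated. CYP3A: the midazolam clearance increase is attenuated by
#' the unbound-fraction ratio before any verdict (unbound clearance is the
#' activity-relevant quantity).
#'
#' @param rsv_cl_change Fractional RSV CL/F change in ESRD (e.g. -0.09 for
#'   a 9% decrease).
#' @param oatp1b_decrease Expected OATP1B-driven fractional decrease
#'   (positive, e.g. 0.38).
#' @param mdz_cl_change Fractional MDZ CL/F change (e.g. +0.94).
#' @param fu_ratio ESRD/HV unbound-fraction ratio for MDZ (e.g. 1.62).
#' @return Tibble with one row per DMET: `dmet`, `verdict`,
#'   `magnitude` (unbound-corrected multiplier where applicable).
#' @export
qualitative_flags <- function(rsv_cl_change = 0, oatp1b_decrease = 0,
                              mdz_cl_change = 0, fu_ratio = 1) {
  bcrp_excess <- rsv_cl_change - (-oatp1b_decrease)
  bcrp <- if (bcrp_excess > 0) "possibly upregulated" else "no evidence"
  mdz_unbound <- (1 + mdz_cl_change) / fu_ratio
  cyp3a <- if (mdz_unbound > 1) "possibly upregulated (f_u-corrected)"
           else if (mdz_cl_change > 0) "confounded by f_u increase"
           else "no evidence"
  tibble::tibble(
    dmet = c("BCRP", "CYP3A"),
    verdict = c(bcrp, cyp3a),
    magnitude = c(bcrp_excess, mdz_unbound)
  )
}

#' Per-DMET activity report
#'
#' Combines the closed-form activity estimates into one tidy report:
#' OATP1B at a given Veillonella abundance (plus the covariate-neutral
#' direct effect), intestinal P-gp at both published filtration-fraction
#' bounds, the CP-I cross-check, and the qualitative BCRP/CYP3A verdicts.
#' Integer percents use round-half-away-from-zero.
#'
#' @param veil Veillonella relative abundance (percent) at which to
#'   evaluate OATP1B activity (default: the maximum observed, 1.42).
#' @param dis_effect,theta_veil,normalizer Passed to [oatp1b_activity()].
#' @param effect_esrd Passed to [pgp_activity_change()] (default 0.87).
#' @param egfr Named vector `c(HV=, ESRD=)`, see [egfr_group_means()].
#' @param cp1_fold,cp1_urinary Passed to [cp1_remaining_oatp1b()].
#' @return Tibble with `dmet`, `quantity`, `value` (percent), `assumptions`.
#' @export
dmet_activity_report <- function(veil = 1.42, dis_effect = -0.381,
                                 theta_veil = -0.677, normalizer = 1.08,
                                 effect_esrd = 0.87, egfr = egfr_group_means(),
                                 cp1_fold = 2.5, cp1_urinary = 0.15) {
  tibble::tibble(
    dmet = c("OATP1B", "OATP1B", "Pgp_intestinal", "Pgp_intestinal", "OATP1B"),
    quantity = c("activity decrease, direct ESRD effect (%)",
                 sprintf("activity decrease at Veillonella %.3g%% (%%)", veil),
                 "activity decrease, Rf = 0.85 (%)",
                 "activity decrease, Rf = 0.80 (%)",
                 "remaining function, CP-I mass balance (%)"),
    value = round_half_away(c(
      oatp1b_activity(dis_effect, theta_veil, 0, normalizer),
      oatp1b_activity(dis_effect, theta_veil, veil, normalizer),
      pgp_activity_change(effect_esrd, egfr[["ESRD"]], egfr[["HV"]], 0.15, 0.85),
      pgp_activity_change(effect_esrd, egfr[["ESRD"]], egfr[["HV"]], 0.20, 0.80),
      cp1_remaining_oatp1b(cp1_fold, cp1_urinary))),
    assumptions = c("covariate-neutral HV reference",
                    "covariate-neutral HV reference",
                    "F inversely proportional to intestinal efflux activity",
                    "F inversely proportional to intestinal efflux activity",
                    "constant CP-I synthesis; urinary route abolished in ESRD")
  )
}
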