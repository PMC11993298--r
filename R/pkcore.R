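#' Structural parameters of a two-compartment oral model
#'
#' Bundles the apparent disposition constants of a two-compartment model
#' with first-order absorption and first-order elimination: absorption rate
#' constant `ka` (1/hour), apparent clearance `cl_f` (L/hour), central and
#' peripheral volumes `vc_f`, `vp_f` (L), and inter-compartmental clearance
#' `q_f` (L/hour). All parameters are apparent (scaled by bioavailability F).
#'
#' Internal units are fixed throughout the package: time in hours, amounts
#' in pg, volumes in L, concentrations in pg/mL.
#'
#' @param ka Absorption rate constant, 1/hour.
#' @param cl_f Apparent clearance CL/F, L/hour.
#' @param vc_f Apparent central volume Vc/F, L.
#' @param vp_f Apparent peripheral volume Vp/F, L.
#' @param q_f Apparent inter-compartmental clearance Q/F, L/hour.
#' @return An object of class `pk_params` (named list).
#' @examples
#' structural_params(ka = 18, cl_f = 16.5, vc_f = 25.2, vp_f = 76.1, q_f = 8.01)
#' @export
structural_params <- function(ka, cl_f, vc_f, vp_f, q_f) {
  p <- list(ka = ka, cl_f = cl_f, vc_f = vc_f, vp_f = vp_f, q_f = q_f)
  bad <- names(p)[!vapply(p, function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x > 0, logical(1))]
  if (length(bad)) {
    if (any(c("vp_f", "q_f") %in% bad) &&
        all(vapply(p[c("ka", "cl_f", "vc_f")], function(x) isTRUE(is.finite(x) && x > 0), logical(1)))) {
      stop("vp_f and q_f must be > 0; a zero peripheral compartment degenerates ",
           "to a one-compartment model (not handled here)", call. = FALSE)
    }
    stop("structural parameters must be single positive finite numbers; offending: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(p, class = "pk_params")
}

#' @export
print.pk_params <- function(x, ...) {
  cat(sprintf(
    "<pk_params> ka=%.4g /h, CL/F=%.4g L/h, Vc/F=%.4g L, Vp/F=%.4g L, Q/F=%.4g L/h\n",
    x$ka, x$cl_f, x$vc_f, x$vp_f, x$q_f))
  invisible(x)
}

#' Micro-constants of the two-compartment model
#'
#' Reparameterizes clearances/volumes into first-order micro rate constants
#' and the disposition exponents: `k10 = CL/Vc`, `k12 = Q/Vc`, `k21 = Q/Vp`;
#' `alpha` and `beta` are the roots of
#' `s^2 - (k10 + k12 + k21) s + k10 k21 = 0` with `alpha > beta > 0`.
#'
#' @param p A [structural_params()] object.
#' @return Named list with `k10`, `k12`, `k21`, `alpha`, `beta` (all 1/hour).
#' @examples
#' macro_to_micro(structural_params(18, 16.5, 25.2, 76.1, 8.01))$k10 # 0.6548
#' @export
macro_to_micro <- function(p) {
  stopifnot(inherits(p, "pk_params"))
  k10 <- p$cl_f / p$vc_f
  k12 <- p$q_f / p$vc_f
  k21 <- p$q_f / p$vp_f
  s <- k10 + k12 + k21
  # discriminant is always > 0 for positive rates: (s^2 - 4 k10 k21) =
  # (k10 + k12 - k21)^2 + 4 k12 k21 > 0, so alpha > beta strictly
  disc <- sqrt(s^2 - 4 * k10 * k21)
  alpha <- (s + disc) / 2
  beta  <- (s - disc) / 2
  list(k10 = k10, k12 = k12, k21 = k21, alpha = alpha, beta = beta)
}

# Fast kernel: concentration (pg/mL) at tau >= 0 hours after an oral dose of
# amt_ug micrograms, from raw parameter values (no class checks; used in the
# estimation inner loops). Vectorized over tau. The ka == alpha (or beta) tie
# is handled by the analytic L'Hopital limit to avoid 0/0.
conc_raw <- function(ka, cl, vc, vp, q, amt_ug, tau) {
  k10 <- cl / vc; k12 <- q / vc; k21 <- q / vp
  s <- k10 + k12 + k21
  disc <- sqrt(s^2 - 4 * k10 * k21)
  a <- (s + disc) / 2
  b <- (s - disc) / 2
  dose_pg <- amt_ug * 1e6
  scale <- dose_pg * ka / (vc * 1000) # central volume L -> mL
  out <- numeric(length(tau))
  pos <- tau > 0
  if (!any(pos)) return(out)
  tt <- tau[pos]
  tol <- 1e-8 * ka
  if (abs(ka - a) < tol) {
    # ka -> alpha limit: A e^{-a t} + C e^{-ka t} collapses to a t e^{-a t} term
    B <- (k21 - b) / (a - b)^2
    lim <- exp(-a * tt) / (b - a) * (1 + tt * (k21 - a) - (k21 - a) / (b - a))
    bracket <- lim + B * exp(-b * tt)
  } else if (abs(ka - b) < tol) {
    A <- (k21 - a) / (b - a)^2
    lim <- exp(-b * tt) / (a - b) * (1 + tt * (k21 - b) - (k21 - b) / (a - b))
    bracket <- lim + A * exp(-a * tt)
  } else {
    A <- (k21 - a) / ((ka - a) * (b - a))
    B <- (k21 - b) / ((ka - b) * (a - b))
    C <- (k21 - ka) / ((a - ka) * (b - ka))
    bracket <- A * exp(-a * tt) + B * exp(-b * tt) + C * exp(-ka * tt)
  }
  out[pos] <- scale * bracket
  # clamp tiny negative round-off near tau = 0
  out[out < 0 & out > -1e-9] <- 0
  out
}

conc_single_dose <- function(p, amt_ug, tau) {
  conc_raw(p$ka, p$cl_f, p$vc_f, p$vp_f, p$q_f, amt_ug, tau)
}

#' Closed-form concentration of the two-compartment oral model
#'
#' Tri-exponential solution for one or more first-order oral dose events,
#' with superposition over doses (linear pharmacokinetics). Concentration is
#' the amount in the central compartment divided by `vc_f` (reported in
#' pg/mL; dose amounts are in micrograms, 1 ug = 1e6 pg).
#'
#' @param p A [structural_params()] object.
#' @param dose_amt Dose amount(s), micrograms. Recycled against `dose_time`.
#' @param dose_time Dose time(s), hours.
#' @param t Evaluation times, hours (vectorized).
#' @return Numeric vector of concentrations, pg/mL (0 before the first dose).
#' @examples
#' p <- structural_params(18, 16.5, 25.2, 76.1, 8.01)
#' conc_2cmt_oral(p, 10, 0, c(0, 0.5, 1, 2, 4, 8, 12, 24))
#' @export
conc_2cmt_oral <- function(p, dose_amt, dose_time = 0, t) {
  stopifnot(inherits(p, "pk_params"))
  n <- max(length(dose_amt), length(dose_time))
  dose_amt <- rep_len(dose_amt, n)
  dose_time <- rep_len(dose_time, n)
  if (any(dose_amt < 0)) stop("dose amounts must be >= 0", call. = FALSE)
  if (any(dose_time < 0)) stop("dose times must be >= 0", call. = FALSE)
  out <- numeric(length(t))
  for (i in seq_len(n)) {
    if (dose_amt[i] == 0) next
    out <- out + conc_single_dose(p, dose_amt[i], t - dose_time[i])
  }
  out
}

#' Analytic AUC from zero to infinity
#'
#' For linear pharmacokinetics the total exposure is `dose / (CL/F)`
#' regardless of distribution; returned in hour*pg/mL (dose in micrograms).
#' Serves as the exact oracle for non-compartmental extrapolation checks.
#'
#' @param p A [structural_params()] object.
#' @param dose_amt Total dose, micrograms.
#' @return AUC(0, Inf) in hour*pg/mL.
#' @export
auc_inf_analytic <- function(p, dose_amt) {
  stopifnot(inherits(p, "pk_params"))
  if (any(dose_amt < 0)) stop("dose amounts must be >= 0", call. = FALSE)
  dose_amt * 1e6 / (p$cl_f * 1000)
}
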