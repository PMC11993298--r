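#' Covariate effect on a structural parameter
#'
#' Three functional forms are supported, covering the covariate algebra of
#' the final models:
#' * `proportional_shift`: multiplier `1 + theta * x` (used for the ESRD
#'   disease-state indicator; requires `1 + theta * x > 0`),
#' * `exp_linear_scaled`: multiplier `exp(theta * x / scale)` (used for
#'   genus relative abundances, scale constant 1.08),
#' * `power_median`: multiplier `(x / scale)^theta` (used for serum albumin
#'   on the rosuvastatin central volume, scale = group-mean albumin 42.1 g/L).
#'
#' @param param Target structural parameter: one of `"ka","cl","vc","vp","q"`.
#' @param covariate Covariate column name on the subject table.
#' @param form One of `"proportional_shift"`, `"exp_linear_scaled"`,
#'   `"power_median"`.
#' @param theta Effect coefficient.
#' @param scale Scaling constant (normalizer); ignored by
#'   `proportional_shift`.
#' @return An object of class `pk_effect`.
#' @export
covariate_effect <- function(param, covariate, form, theta, scale = 1) {
  param <- match.arg(param, c("ka", "cl", "vc", "vp", "q"))
  form <- match.arg(form, c("proportional_shift", "exp_linear_scaled", "power_median"))
  stopifnot(is.numeric(theta), length(theta) == 1L, is.finite(theta),
            is.numeric(scale), length(scale) == 1L, scale > 0)
  structure(list(param = param, covariate = covariate, form = form,
                 theta = theta, scale = scale),
            class = "pk_effect")
}

# Multiplier contributed by one effect, vectorized over subjects.
effect_multiplier <- function(eff, subjects) {
  if (!eff$covariate %in% names(subjects)) {
    stop("covariate '", eff$covariate, "' required by the model is missing ",
         "from the subject table", call. = FALSE)
  }
  x <- subjects[[eff$covariate]]
  mult <- switch(eff$form,
    proportional_shift = 1 + eff$theta * x,
    exp_linear_scaled = {
      # missing abundance falls back to the covariate-neutral reference
      x <- ifelse(is.na(x), 0, x)
      exp(eff$theta * x / eff$scale)
    },
    power_median = (x / eff$scale)^eff$theta
  )
  if (anyNA(mult)) {
    stop("covariate '", eff$covariate, "' has missing values", call. = FALSE)
  }
  if (any(mult <= 0)) {
    stop("covariate effect on '", eff$param, "' produces a non-positive ",
         "multiplier (covariate '", eff$covariate, "')", call. = FALSE)
  }
  mult
}

#' Population pharmacokinetic model for one drug
#'
#' A two-compartment oral model with typical values, covariate effects on
#' the typical values, log-normal inter-individual variability (IIV) and a
#' combined proportional + additive residual-error model.
#'
#' @param drug Drug code (e.g. `"PTV"`).
#' @param typicals Named list/vector of typical values: `ka` (1/h), `cl`
#'   (L/h), `vc` (L), `vp` (L), `q` (L/h).
#' @param effects List of [covariate_effect()] objects.
#' @param omega Named numeric vector of log-scale IIV standard deviations;
#'   parameters not named have no random effect. An IIV printed as 22.5%
#'   corresponds to `omega = 0.225`.
#' @param sigma Residual error: list with `prop` (proportional SD, fraction)
#'   and `add` (additive SD, pg/mL).
#' @param fixed Character vector of typical-value names held fixed (not
#'   estimated) by [fit_population()], e.g. an absorption constant fixed a
#'   priori.
#' @return An object of class `pk_popmodel`.
#' @export
population_model <- function(drug, typicals, effects = list(),
                             omega = c(cl = 0), sigma = list(prop = 0.2, add = 1),
                             fixed = character()) {
  typ <- unlist(typicals)[c("ka", "cl", "vc", "vp", "q")]
  if (anyNA(typ)) stop("typicals must name ka, cl, vc, vp, q", call. = FALSE)
  if (any(typ <= 0)) stop("typical values must be positive", call. = FALSE)
  omega <- omega[omega > 0 | names(omega) %in% character(0)]
  if (any(omega < 0)) stop("omega must be >= 0", call. = FALSE)
  if (sigma$prop < 0 || sigma$add < 0) stop("sigma must be >= 0", call. = FALSE)
  stopifnot(all(names(omega) %in% names(typ)),
            all(vapply(effects, inherits, logical(1), "pk_effect")),
            all(fixed %in% names(typ)))
  structure(list(drug = drug, typ = typ, effects = effects, omega = omega,
                 sigma = sigma, fixed = fixed),
            class = "pk_popmodel")
}

#' @export
print.pk_popmodel <- function(x, ...) {
  cat(sprintf("<pk_popmodel> %s: ka=%.3g, CL/F=%.3g, Vc/F=%.3g, Vp/F=%.3g, Q/F=%.3g\n",
              x$drug, x$typ["ka"], x$typ["cl"], x$typ["vc"], x$typ["vp"], x$typ["q"]))
  for (e in x$effects) {
    cat(sprintf("  %s on %s: %s, theta=%.3g (scale %.3g)\n",
                e$covariate, e$param, e$form, e$theta, e$scale))
  }
  if (length(x$omega)) {
    cat("  IIV (omega): ", paste(sprintf("%s=%.3g", names(x$omega), x$omega),
                                 collapse = ", "), "\n", sep = "")
  }
  cat(sprintf("  residual: prop %.3g, add %.3g pg/mL\n", x$sigma$prop, x$sigma$add))
  invisible(x)
}

#' Final population models of the five probe drugs
#'
#' The published final covariate models: typical values, covariate effects
#' (ESRD disease state on clearance of pitavastatin, dabigatran and
#' midazolam; Veillonella abundance on pitavastatin clearance; genus
#' Clostridium_XIVb abundance on rosuvastatin clearance; serum albumin on
#' the rosuvastatin central volume), log-normal IIV, and a combined
#' residual-error default (proportional SD 0.20, additive 1 pg/mL; the
#' residual model is a package fixture, unreported in the source tables).
#'
#' @return Named list of [population_model()] objects
#'   (`PTV`, `DAB`, `RSV`, `MDZ`, `ATV`).
#' @examples
#' typical_cl(default_models()$ATV, tibble::tibble(dis = 0)) # 363 L/h
#' @export
default_models <- function() {
  list(
    PTV = population_model(
      "PTV",
      typicals = c(ka = 18, cl = 16.5, vc = 25.2, vp = 76.1, q = 8.01),
      effects = list(
        covariate_effect("cl", "dis", "proportional_shift", -0.381),
        covariate_effect("cl", "Veillonella", "exp_linear_scaled", -0.677, scale = 1.08)
      ),
      omega = c(cl = 0.096, q = 0.076),
      fixed = "ka"
    ),
    DAB = population_model(
      "DAB",
      typicals = c(ka = 1.22, cl = 146, vc = 794, vp = 429, q = 92.5),
      effects = list(
        covariate_effect("cl", "dis", "proportional_shift", -0.869)
      ),
      omega = c(ka = 0.215, cl = 0.225, vc = 0.259, vp = 0.86)
    ),
    RSV = population_model(
      "RSV",
      typicals = c(ka = 0.30, cl = 43.1, vc = 289, vp = 2740, q = 48.6),
      effects = list(
        covariate_effect("cl", "Clostridium_XIVb", "exp_linear_scaled", -3.26, scale = 1.08),
        covariate_effect("vc", "albumin", "power_median", -6.42, scale = 42.1)
      ),
      omega = c(cl = 0.508, vc = 0.224)
    ),
    MDZ = population_model(
      "MDZ",
      typicals = c(ka = 13, cl = 67.6, vc = 195, vp = 333, q = 34.7),
      effects = list(
        covariate_effect("cl", "dis", "proportional_shift", 0.94)
      ),
      omega = c(cl = 0.379, vc = 0.421),
      fixed = "ka"
    ),
    ATV = population_model(
      "ATV",
      typicals = c(ka = 7.53, cl = 363, vc = 835, vp = 5830, q = 3920),
      omega = c(cl = 0.48, vc = 0.993, vp = 0.626, q = 0.302)
    )
  )
}

# Matrix of covariate-adjusted typical parameters, one row per subject,
# columns ka, cl, vc, vp, q.
typical_param_matrix <- function(model, subjects) {
  n <- nrow(subjects)
  mat <- matrix(rep(model$typ, each = n), nrow = n,
                dimnames = list(NULL, names(model$typ)))
  for (eff in model$effects) {
    mat[, eff$param] <- mat[, eff$param] * effect_multiplier(eff, subjects)
  }
  mat
}

#' Covariate-adjusted typical clearance and central volume
#'
#' Evaluates the typical (population) value of CL/F or Vc/F for each row of
#' a subject table after applying the model's covariate effects. Subjects
#' with a missing genus abundance fall back to the covariate-neutral
#' reference (multiplier 1).
#'
#' @param model A [population_model()].
#' @param subjects Data frame with the covariate columns the model needs
#'   (e.g. `dis` 0/1, genus abundance in percent, `albumin` g/L).
#' @return Numeric vector, L/hour for `typical_cl`; L for `typical_vc`.
#' @examples
#' m <- default_models()$DAB
#' typical_cl(m, tibble::tibble(dis = 1)) # 146 * (1 - 0.869)
#' @export
typical_cl <- function(model, subjects) {
  unname(typical_param_matrix(model, subjects)[, "cl"])
}

#' @rdname typical_cl
#' @export
typical_vc <- function(model, subjects) {
  unname(typical_param_matrix(model, subjects)[, "vc"])
}

#' Draw individual parameters from the population model
#'
#' Each subject's parameter is `typical * exp(eta)` with independent
#' `eta ~ Normal(0, omega^2)` on the parameters carrying IIV; parameters
#' without reported IIV are fixed at their covariate-adjusted typical value.
#'
#' @param model A [population_model()].
#' @param subjects Subject/covariate table (one row per subject; a column
#'   `id` is carried through when present).
#' @param seed Optional integer seed for reproducibility.
#' @return Tibble with columns `id`, `ka`, `cl`, `vc`, `vp`, `q` and the
#'   drawn `eta_*` columns.
#' @export
draw_individual_params <- function(model, subjects, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(subjects)
  typ <- typical_param_matrix(model, subjects)
  eta <- matrix(0, n, length(model$typ), dimnames = list(NULL, names(model$typ)))
  for (pn in names(model$omega)) {
    eta[, pn] <- stats::rnorm(n, 0, model$omega[[pn]])
  }
  ind <- typ * exp(eta)
  out <- tibble::as_tibble(as.data.frame(ind))
  out$id <- if ("id" %in% names(subjects)) subjects$id else seq_len(n)
  for (pn in names(model$omega)) out[[paste0("eta_", pn)]] <- eta[, pn]
  dplyr::relocate(out, "id")
}

# One subject's pk_params from a row of a parameter matrix / tibble.
row_to_params <- function(row) {
  structural_params(ka = row[["ka"]], cl_f = row[["cl"]], vc_f = row[["vc"]],
                    vp_f = row[["vp"]], q_f = row[["q"]])
}
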