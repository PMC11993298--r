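#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted population model
#'
#' One row per model parameter: typical values, covariate coefficients
#' (`<covariate>_on_<parameter>`), IIV standard deviations
#' (`omega_<parameter>`) and the proportional residual SD. `fixed` marks
#' parameters held at their skeleton value.
#'
#' @param x A `pk_popfit` from [fit_population()].
#' @param ... Unused.
#' @return Tibble with `term`, `type`, `estimate`, `fixed`.
#' @export
tidy.pk_popfit <- function(x, ...) {
  m <- x$model
  eff_terms <- vapply(m$effects, function(e) paste0(e$covariate, "_on_", e$param),
                      character(1))
  tibble::tibble(
    term = c(names(m$typ),
             eff_terms,
             paste0("omega_", names(m$omega)),
             "sigma_prop"),
    type = c(rep("typical", length(m$typ)),
             rep("covariate", length(m$effects)),
             rep("iiv", length(m$omega)),
             "residual"),
    estimate = c(unname(m$typ),
                 vapply(m$effects, function(e) e$theta, numeric(1)),
                 unname(m$omega),
                 m$sigma$prop),
    fixed = c(names(m$typ) %in% m$fixed,
              rep(FALSE, length(m$effects) + length(m$omega)),
              !x$estimate_sigma)
  )
}

#' @rdname tidy.pk_popfit
#' @export
glance.pk_popfit <- function(x, ...) {
  tibble::tibble(objective = x$objective, converged = x$convergence,
                 n_subjects = x$n_subjects, n_obs = x$n_obs,
                 n_parameters = length(x$phi))
}

#' Tidy a LASSO covariate-selection fit
#'
#' @param x A `pk_lasso` from [lasso_lambda_min()].
#' @param ... Unused.
#' @return `tidy`: selected terms (incl. intercept) with coefficients on
#'   the original covariate scale. `glance`: one-row fit summary.
#' @export
tidy.pk_lasso <- function(x, ...) x$coefficients

#' @rdname tidy.pk_lasso
#' @export
glance.pk_lasso <- function(x, ...) {
  tibble::tibble(lambda_min = x$lambda_min, n = x$n,
                 cvm_min = min(x$cvm),
                 n_selected = sum(x$coefficients$term != "(Intercept)"))
}
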