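#' Correlation screening of candidate covariates
#'
#' Correlates each candidate variable with the response (individual CL/F by
#' default, drug exposure optionally) and keeps those with p < `alpha`.
#' Spearman's rank correlation is the default (robust at the study's arm
#' size of 10); Pearson is selectable. Constant covariates are skipped with
#' a warning; categorical covariates should be dummy-coded beforehand.
#'
#' @param data Data frame holding the response and candidate columns.
#' @param response Response column name (e.g. `"cl"`).
#' @param vars Character vector of candidate column names (default: all
#'   numeric columns except the response and `id`).
#' @param alpha Selection threshold on the p-value (default 0.05).
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return Tibble with `variable`, `r`, `p`, `selected`, sorted by p.
#' @export
correlation_screen <- function(data, response, vars = NULL, alpha = 0.05,
                               method = c("spearman", "pearson")) {
  method <- match.arg(method)
  if (nrow(data) < 4) stop("need at least 4 subjects to screen", call. = FALSE)
  y <- data[[response]]
  if (is.null(y)) stop("response column '", response, "' not found", call. = FALSE)
  if (is.null(vars)) {
    num <- vapply(data, is.numeric, logical(1))
    vars <- setdiff(names(data)[num], c(response, "id"))
  }
  rows <- lapply(vars, function(v) {
    x <- data[[v]]
    if (is.null(x)) stop("candidate column '", v, "' not found", call. = FALSE)
    if (stats::sd(x, na.rm = TRUE) == 0 || all(is.na(x))) {
      warning("skipping constant covariate '", v, "'", call. = FALSE)
      return(NULL)
    }
    ct <- suppressWarnings(stats::cor.test(x, y, method = method))
    tibble::tibble(variable = v, r = unname(ct$estimate), p = ct$p.value)
  })
  out <- dplyr::bind_rows(rows)
  out$selected <- out$p < alpha
  dplyr::arrange(out, .data$p)
}

#' LASSO covariate selection at lambda-min
#'
#' L1-penalized linear regression over a log-spaced `lambda` grid (100
#' values spanning 4 decades down from the smallest all-zero penalty),
#' with the penalty chosen to minimize cross-validated mean squared error
#' (lambda-min). Predictors are standardized internally and coefficients
#' reported on the original scale with an intercept. Cross-validation is
#' leave-one-out by default (appropriate at the study's n = 10); when
#' `n <= cv_folds` the fold count falls back to leave-one-out with a
#' warning. Fitting is by coordinate descent (glmnet).
#'
#' @param data Data frame with response and predictors.
#' @param response Response column name.
#' @param vars Predictor column names (default: all numeric except
#'   response and `id`).
#' @param cv_folds Number of CV folds, or `"loo"` (default) for
#'   leave-one-out.
#' @param seed Seed controlling fold assignment when `cv_folds` is a
#'   number.
#' @param nlambda,lambda_decades Grid size and decades spanned.
#' @return Object of class `pk_lasso`: list with `coefficients` (tibble of
#'   selected terms incl. intercept), `lambda_min`, `lambda` grid, `cvm`
#'   (CV mean squared error per lambda), `response`, `n`. Methods:
#'   [tidy.pk_lasso()], [glance.pk_lasso()], `predict()`,
#'   [autoplot.pk_lasso()].
#' @export
lasso_lambda_min <- function(data, response, vars = NULL, cv_folds = "loo",
                             seed = 1, nlambda = 100, lambda_decades = 4) {
  y <- data[[response]]
  if (is.null(y)) stop("response column '", response, "' not found", call. = FALSE)
  if (is.null(vars)) {
    num <- vapply(data, is.numeric, logical(1))
    vars <- setdiff(names(data)[num], c(response, "id"))
  }
  X <- as.matrix(data[, vars, drop = FALSE])
  n <- nrow(X)
  # lambda_max: smallest penalty with an all-zero solution (glmnet's 1/n
  # standardization convention; tiny inflation keeps the boundary inactive)
  Xs <- apply(X, 2, function(x) (x - mean(x)) / sqrt(mean((x - mean(x))^2)))
  lambda_max <- max(abs(crossprod(Xs, y - mean(y)))) / n * (1 + 1e-6)
  lambda <- exp(seq(log(lambda_max), log(lambda_max) - lambda_decades * log(10),
                    length.out = nlambda))
  if (identical(cv_folds, "loo")) {
    foldid <- seq_len(n)
  } else {
    if (n <= cv_folds) {
      warning("n <= cv_folds; falling back to leave-one-out", call. = FALSE)
      foldid <- seq_len(n)
    } else {
      set.seed(seed)
      foldid <- sample(rep_len(seq_len(cv_folds), n))
    }
  }
  cv <- glmnet::cv.glmnet(X, y, lambda = lambda, foldid = foldid,
                          standardize = TRUE, thresh = 1e-12,
                          grouped = length(unique(foldid)) < n)
  co <- as.matrix(stats::coef(cv, s = "lambda.min"))
  sel <- co[, 1] != 0 | rownames(co) == "(Intercept)"
  structure(list(
    coefficients = tibble::tibble(term = rownames(co)[sel],
                                  estimate = unname(co[sel, 1])),
    all_coefficients = tibble::tibble(term = rownames(co),
                                      estimate = unname(co[, 1])),
    lambda_min = cv$lambda.min, lambda = cv$lambda, cvm = cv$cvm,
    response = response, vars = vars, n = n, glmnet = cv
  ), class = "pk_lasso")
}

#' @export
print.pk_lasso <- function(x, ...) {
  cat(sprintf("<pk_lasso> response %s, n = %d, lambda_min = %.4g\n",
              x$response, x$n, x$lambda_min))
  print(x$coefficients, n = Inf)
  invisible(x)
}

#' @export
predict.pk_lasso <- function(object, newdata, ...) {
  X <- as.matrix(newdata[, object$vars, drop = FALSE])
  drop(stats::predict(object$glmnet, newx = X, s = "lambda.min"))
}

#' Published multiple-linear-regression model cards
#'
#' The five printed clearance predictors for ESRD patients, as selected by
#' the correlation screen + LASSO stage: linear terms on the original
#' covariate scales (abundances in percent, labs in the units of
#' [covariate_stats()]), with intercept. Terms map to subject-table
#' columns: e.g. `CL/F_RSV = 1.51*age + 5.16*ckmb - 57.9`.
#'
#' @return Named list of model cards; each a list with `drug`, `terms`
#'   (named coefficient vector) and `intercept`.
#' @export
mlr_cards <- function() {
  list(
    PTV = list(drug = "PTV", intercept = 17.5,
               terms = c(Phascolarctobacterium = 0.0124, urea = -0.273,
                         Veillonella = -2.20)),
    DAB = list(drug = "DAB", intercept = 44.1,
               terms = c(hct = -46.4, Clostridium_XVIII = -8.77)),
    RSV = list(drug = "RSV", intercept = -57.9,
               terms = c(age = 1.51, ckmb = 5.16)),
    MDZ = list(drug = "MDZ", intercept = 57.4,
               terms = c(triglyceride = 11.6, Anaerostipes = -17.7,
                         platelet = 0.259)),
    ATV = list(drug = "ATV", intercept = -1152,
               terms = c(height = 8.92, Sutterella = 18.6))
  )
}

#' Predict clearance from a regression card or LASSO fit
#'
#' Evaluates a linear predictor (a [mlr_cards()] entry or a `pk_lasso`
#' fit) on a subject table. Missing covariates raise a named error.
#'
#' @param fit A model card (list with `terms` and `intercept`) or a
#'   `pk_lasso` object.
#' @param subjects Data frame with the covariate columns the card names.
#' @return Numeric vector of predicted CL/F, L/hour.
#' @examples
#' mlr_predict(mlr_cards()$RSV, tibble::tibble(age = 40, ckmb = 3)) # 17.98
#' @export
mlr_predict <- function(fit, subjects) {
  if (inherits(fit, "pk_lasso")) return(predict(fit, subjects))
  miss <- setdiff(names(fit$terms), names(subjects))
  if (length(miss)) {
    stop("missing covariate(s) for prediction: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  X <- as.matrix(subjects[, names(fit$terms), drop = FALSE])
  drop(X %*% fit$terms) + fit$intercept
}
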