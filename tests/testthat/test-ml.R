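test_that("correlation screen selects perfect correlates and is deterministic", {
  set.seed(1)
  dat <- tibble::tibble(id = 1:10, cl = rlnorm(10, 2, 0.5))
  dat$same <- dat$cl
  dat$dup1 <- rnorm(10)
  dat$dup2 <- dat$dup1
  dat$flat <- 5
  expect_warning(
    sc <- correlation_screen(dat, "cl", vars = c("same", "dup1", "dup2", "flat")),
    "constant")
  expect_equal(sc$r[sc$variable == "same"], 1)
  expect_true(sc$selected[sc$variable == "same"])
  # duplicated covariate yields identical r and p
  expect_equal(sc$r[sc$variable == "dup1"], sc$r[sc$variable == "dup2"])
  expect_equal(sc$p[sc$variable == "dup1"], sc$p[sc$variable == "dup2"])
  expect_false("flat" %in% sc$variable)
  expect_error(correlation_screen(dat[1:3, ], "cl"), "4 subjects")
})

test_that("lasso grid spans from the all-zero model downwards", {
  set.seed(2)
  n <- 40
  dat <- tibble::tibble(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n))
  dat$y <- 2 * dat$x1 - 1.5 * dat$x2 + rnorm(n, 0, 0.5)
  fit <- lasso_lambda_min(dat, "y")
  # at the top of the grid every coefficient is zero and the intercept is
  # the response mean (null-model limit)
  top <- as.matrix(coef(fit$glmnet$glmnet.fit, s = max(fit$lambda)))
  expect_true(all(top[-1, 1] == 0))
  expect_equal(top[1, 1], mean(dat$y), tolerance = 1e-8)
  expect_equal(length(fit$lambda), 100)
  expect_true(fit$lambda_min %in% fit$lambda)
  # active set grows from the top of the grid to the bottom
  path <- fit$glmnet$glmnet.fit
  nz <- colSums(as.matrix(path$beta) != 0)
  expect_equal(nz[which.max(path$lambda)], c(s0 = 0), ignore_attr = TRUE)
  expect_gte(max(nz), 2)
})

test_that("the un-penalized limit matches ordinary least squares", {
  set.seed(3)
  n <- 50
  dat <- tibble::tibble(x1 = rnorm(n), x2 = runif(n), x3 = rnorm(n, 5, 2))
  dat$y <- 1 + 3 * dat$x1 - 2 * dat$x2 + 0.5 * dat$x3 + rnorm(n, 0, 0.3)
  fit <- lasso_lambda_min(dat, "y", lambda_decades = 10)
  co <- as.matrix(coef(fit$glmnet$glmnet.fit, s = min(fit$lambda)))
  ols <- coef(lm(y ~ x1 + x2 + x3, dat))
  expect_equal(unname(co[, 1]), unname(ols), tolerance = 1e-5)
})

test_that("predictions are invariant to affine rescaling of a covariate", {
  set.seed(4)
  n <- 60
  dat <- tibble::tibble(x1 = rnorm(n), x2 = rnorm(n))
  dat$y <- 2 * dat$x1 + dat$x2 + rnorm(n, 0, 0.4)
  f1 <- lasso_lambda_min(dat, "y")
  dat2 <- dat; dat2$x1 <- dat2$x1 * 100
  f2 <- lasso_lambda_min(dat2, "y")
  expect_equal(predict(f1, dat), predict(f2, dat2), tolerance = 1e-6)
})

test_that("a planted linear model is recovered at lambda-min", {
  set.seed(5)
  n <- 100
  dat <- tibble::tibble(
    age = runif(n, 20, 65),
    ckmb = rlnorm(n, log(3), 0.5),
    hct = runif(n, 0.3, 0.5),
    urea = rlnorm(n, log(20), 0.3)
  )
  dat$cl <- 1.51 * dat$age + 5.16 * dat$ckmb - 57.9 + rnorm(n, 0, 2)
  fit <- lasso_lambda_min(dat, "cl")
  est <- setNames(fit$all_coefficients$estimate, fit$all_coefficients$term)
  expect_true(all(c("age", "ckmb") %in% fit$coefficients$term))
  expect_equal(unname(est["age"]), 1.51, tolerance = 0.1)
  expect_equal(unname(est["ckmb"]), 5.16, tolerance = 0.1)
})

test_that("regression model cards evaluate the printed equations", {
  cards <- mlr_cards()
  expect_equal(mlr_predict(cards$RSV, tibble::tibble(age = 40, ckmb = 3)),
               1.51 * 40 + 5.16 * 3 - 57.9, tolerance = 1e-12)
  expect_equal(mlr_predict(cards$RSV, tibble::tibble(age = 40, ckmb = 3)),
               17.98, tolerance = 1e-10)
  expect_equal(mlr_predict(cards$ATV, tibble::tibble(height = 170, Sutterella = 1)),
               8.92 * 170 + 18.6 - 1152, tolerance = 1e-12)
  # all-zero covariates return the intercept
  expect_equal(mlr_predict(cards$MDZ, tibble::tibble(triglyceride = 0,
                                                     Anaerostipes = 0,
                                                     platelet = 0)), 57.4)
  expect_error(mlr_predict(cards$DAB, tibble::tibble(hct = 0.4)),
               "Clostridium_XVIII")
})

test_that("tidy and glance summarize lasso fits", {
  set.seed(6)
  dat <- tibble::tibble(x1 = rnorm(30), x2 = rnorm(30))
  dat$y <- dat$x1 + rnorm(30, 0, 0.2)
  fit <- lasso_lambda_min(dat, "y")
  td <- tidy(fit)
  expect_true("(Intercept)" %in% td$term)
  gl <- glance(fit)
  expect_equal(gl$n, 30)
  expect_equal(gl$lambda_min, fit$lambda_min)
})
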