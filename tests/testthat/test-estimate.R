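make_small_trial <- function(n_hv = 10, n_esrd = 10, drug = "DAB", seed = 50,
                             schedules = rich_schedule(), model = NULL) {
  s <- simulate_cohort(n_hv, n_esrd, seed = seed)
  m <- if (is.null(model)) default_models()[[drug]] else model
  r <- simulate_trial(s, models = stats::setNames(list(m), m$drug),
                      schedules = schedules, seed = seed + 1)
  list(subjects = s, records = r, model = m)
}

test_that("compiled Laplace objective matches the R reference route", {
  tr <- make_small_trial(4, 4, "DAB", seed = 95)
  m <- tr$model
  obs <- cocktailpk:::subject_obs_list(m, tr$records, tr$subjects)
  typ <- cocktailpk:::typical_param_matrix(m, tr$subjects)
  omega_inv <- diag(1 / m$omega^2, length(m$omega))
  tot_r <- 0
  for (i in seq_len(nrow(tr$subjects))) {
    li <- cocktailpk:::laplace_subject(
      setNames(rep(0, length(m$omega)), names(m$omega)),
      typ[i, ], obs[[i]], m$omega, m$sigma)
    tot_r <- tot_r + li$m2ll
  }
  flat <- cocktailpk:::flatten_obs(obs)
  tot_c <- cocktailpk:::.cpp_laplace_total(
    typ, flat$t_all, flat$y_all, flat$offsets, flat$amt,
    match(names(m$omega), names(m$typ)) - 1L, unname(m$omega),
    m$sigma$prop, m$sigma$add)$m2ll
  expect_equal(tot_c, tot_r, tolerance = 1e-8)
})

test_that("MAP Bayes is self-consistent on noise-free typical data", {
  tr <- make_small_trial(3, 3, "MDZ", seed = 60)
  m <- tr$model
  # rebuild records as the exact typical curves (no IIV, no noise)
  m0 <- m; m0$sigma <- list(prop = 0, add = 0); m0$omega <- m$omega * 0 + 1e-12
  r0 <- simulate_trial(tr$subjects, models = list(MDZ = m0),
                       schedules = rich_schedule(), seed = 61, lloq = 0)
  mb <- map_bayes(m, r0, tr$subjects)
  # with proportional error and interaction the posterior mode sits O(sigma^2)
  # away from zero even for perfect data (the log-variance term trades off
  # against the residuals); sigma_p = 0.2 bounds the shift at ~sigma_p^2
  expect_true(all(abs(mb$eta_cl) < 2 * m$sigma$prop^2))
  expect_true(all(abs(mb$eta_vc) < 2 * m$sigma$prop^2))
  expect_equal(mb$cl, typical_cl(m, tr$subjects), tolerance = 0.1)
  # with additive-only error the mode is exactly at the typical curve
  m_add <- m; m_add$sigma <- list(prop = 0, add = 1)
  mb2 <- map_bayes(m_add, r0, tr$subjects)
  expect_true(all(abs(mb2$eta_cl) < 1e-4))
  expect_equal(mb2$cl, typical_cl(m, tr$subjects), tolerance = 1e-3)
})

test_that("infinite residual noise shrinks estimates fully to the typical", {
  tr <- make_small_trial(3, 3, "MDZ", seed = 62)
  m <- tr$model
  m$sigma <- list(prop = 0, add = 1e8)
  mb <- map_bayes(m, tr$records, tr$subjects)
  expect_true(all(abs(mb$eta_cl) < 1e-4))
  expect_equal(mb$cl, typical_cl(m, tr$subjects), tolerance = 1e-3)
})

test_that("rich sampling recovers individual clearances", {
  tr <- make_small_trial(50, 50, "DAB", seed = 63)
  truth <- simulate_trial(tr$subjects, models = list(DAB = tr$model),
                          schedules = rich_schedule(), seed = 64)
  # regenerate the same individual draws the trial seed used
  set.seed(64)
  ind <- draw_individual_params(tr$model, tr$subjects)
  mb <- map_bayes(tr$model, truth, tr$subjects)
  rel <- mb$cl / ind$cl - 1
  # cohort-average recovery within 10%; per-subject spread stays moderate
  expect_lt(abs(mean(rel)), 0.10)
  expect_lt(median(abs(rel)), 0.15)
  # posterior-mode parameters are positive and finite
  expect_true(all(is.finite(mb$cl) & mb$cl > 0))
})

test_that("eta shrinkage obeys the variance inequality on the sparse design", {
  s <- simulate_cohort(2, 20, seed = 65)
  m <- default_models()$MDZ
  r <- simulate_trial(s, models = list(MDZ = m), seed = 66)
  mb <- map_bayes(m, r, s[s$group == "ESRD", ])
  shr <- attr(mb, "shrinkage")
  expect_true(all(shr$sd_eta <= shr$omega + 1e-9))
  expect_true(all(shr$shrinkage_pct >= -1e-9))
})

test_that("the noise-free limit returns the generating typical values", {
  s <- simulate_cohort(8, 8, seed = 70)
  m <- default_models()$MDZ
  gen <- m
  gen$omega <- c(cl = 1e-12) # effectively no IIV
  gen$sigma <- list(prop = 1e-4, add = 1e-4)
  r <- simulate_trial(s, models = list(MDZ = gen), schedules = rich_schedule(),
                      seed = 71, lloq = 0)
  # start the fit away from the truth so the optimizer has work to do
  skel <- gen
  skel$typ[c("cl", "vc", "vp", "q")] <- skel$typ[c("cl", "vc", "vp", "q")] * 1.3
  skel$effects[[1]]$theta <- 0.5
  skel$omega <- c(cl = 0.1)
  expect_warning(fit <- fit_population(r, s, skel, estimate_sigma = FALSE),
                 regexp = NA)
  est <- fit$model
  expect_equal(unname(est$typ["cl"]), 67.6, tolerance = 0.01)
  expect_equal(unname(est$typ["vc"]), 195, tolerance = 0.01)
  expect_equal(est$effects[[1]]$theta, 0.94, tolerance = 0.01)
  # accepted-step objective trace is monotone non-increasing
  expect_true(all(diff(fit$trace) <= 0))
})

test_that("bootstrap degenerates correctly in edge cases", {
  tr <- make_small_trial(6, 6, "MDZ", seed = 75)
  fit <- fit_population(tr$records, tr$subjects, tr$model,
                        control = list(rel.tol = 1e-5, iter.max = 60,
                                       eval.max = 200))
  bs <- bootstrap_population(tr$records, tr$subjects, tr$model, n = 1,
                             seed = 76, fit = fit,
                             control = list(rel.tol = 1e-5, iter.max = 60,
                                            eval.max = 200))
  # n = 1: the interval collapses onto the single replicate refit
  expect_equal(bs$lo90, bs$hi90)
  expect_equal(bs$median, bs$lo90)
  expect_equal(bs$n_ok, rep(1, nrow(bs)))
  expect_setequal(bs$parameter, tidy(fit)$term)
})

test_that("VPC bands are seeded and degenerate sensibly at nsim = 1", {
  tr <- make_small_trial(6, 6, "MDZ", seed = 80)
  v1 <- vpc_bands(tr$model, tr$records, tr$subjects, nsim = 1, seed = 81)
  expect_equal(v1$sim_lo, v1$sim_hi)
  v2 <- vpc_bands(tr$model, tr$records, tr$subjects, nsim = 10, seed = 82)
  v3 <- vpc_bands(tr$model, tr$records, tr$subjects, nsim = 10, seed = 82)
  expect_identical(v2$sim_med, v3$sim_med)
  expect_s3_class(autoplot(v2), "ggplot")
})

test_that("simulated profiles honour the closed-form exposure identities", {
  s <- simulate_cohort(3, 3, seed = 85)
  m <- default_models()$PTV
  pr <- simulate_profiles(m, s, t_grid = seq(0, 150, by = 0.25), seed = 86)
  # nothing on board at t = 0
  expect_true(all(pr$profiles$conc[pr$profiles$time == 0] == 0))
  # AUC over 150 h dominates AUC over 24 h
  pr24 <- simulate_profiles(m, s, t_grid = seq(0, 24, by = 0.25), seed = 86)
  expect_true(all(pr$metrics$auc >= pr24$metrics$auc))
  # a short terminal half-life drug: AUC(0-150) ~ dose / (CL/F) within 2%
  pr_typ <- simulate_profiles(m, s, t_grid = seq(0, 150, by = 0.1),
                              use_iiv = FALSE)
  cls <- typical_cl(m, s)
  expect_equal(pr_typ$metrics$auc, 10e6 / (cls * 1000), tolerance = 0.02)
})

test_that("dialysis removal ratios are recovered from 28-h comparisons", {
  pred <- tibble::tibble(id = rep(1:20, each = 1), drug = "DAB",
                         conc = rlnorm(20, 5, 0.2))
  meas <- pred
  out <- dialysis_effect(pred, meas)
  expect_true(all(out$subject$ratio == 1))
  meas0 <- pred; meas0$conc <- 0
  expect_true(all(dialysis_effect(pred, meas0)$subject$ratio == 0))
  # a drug with 70% removal injected multiplicatively with noise
  set.seed(87)
  meas70 <- pred
  meas70$conc <- pred$conc * 0.30 * exp(rnorm(20, 0, 0.05))
  got <- dialysis_effect(pred, meas70)$drug
  expect_equal(got$mean_ratio, 0.30, tolerance = 0.05)
  expect_equal(got$removal_pct, 70, tolerance = 5)
})
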