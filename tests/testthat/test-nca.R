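test_that("linear-up/log-down segments use the right rule", {
  # flat segment: linear trapezoid of equal concentrations
  expect_equal(auc_linuplogdown(c(1, 2), c(100, 100)), 100)
  # descending segment: closed-form log trapezoid (100-50)/ln 2
  expect_equal(auc_linuplogdown(c(1, 2), c(100, 50)), 50 / log(2),
               tolerance = 1e-10)
  expect_equal(auc_linuplogdown(c(1, 2), c(100, 50)), 72.1348, tolerance = 1e-4)
  # ascending and zero-bounded segments are linear
  expect_equal(auc_linuplogdown(c(0, 1), c(0, 100)), 50)
  expect_equal(auc_linuplogdown(c(0, 1, 2), c(0, 100, 0)), 100)
  expect_error(auc_linuplogdown(1, 100), "2 points")
  expect_error(auc_linuplogdown(c(1, 2), c(100, -1)), "negative")
  expect_error(auc_linuplogdown(c(2, 1), c(1, 2)), "increasing")
})

test_that("AUC is additive over interior grid points and log <= linear", {
  set.seed(3)
  p <- random_params()
  tt <- sort(c(0.01, runif(30, 0, 48)))
  cc <- conc_2cmt_oral(p, 100, 0, tt)
  for (cut in c(5, 15, 25)) {
    a1 <- auc_linuplogdown(tt[1:cut], cc[1:cut])
    a2 <- auc_linuplogdown(tt[cut:length(tt)], cc[cut:length(tt)])
    expect_equal(a1 + a2, auc_linuplogdown(tt, cc), tolerance = 1e-12)
  }
  # on a strictly descending pair the log trapezoid is below the linear one
  lin <- (80 + 20) / 2
  expect_lt(auc_linuplogdown(c(0, 1), c(80, 20) + 1e-12) - 0, lin)
})

test_that("dense-grid NCA matches adaptive quadrature and the analytic AUC", {
  p <- structural_params(18, 16.5, 25.2, 76.1, 8.01)
  tt <- seq(0, 24, by = 0.01)
  auc_grid <- auc_linuplogdown(tt, conc_2cmt_oral(p, 10, 0, tt))
  auc_quad <- integrate(function(t) conc_2cmt_oral(p, 10, 0, t), 0, 24,
                        rel.tol = 1e-10)$value
  expect_equal(auc_grid, auc_quad, tolerance = 5e-4)
  # long-horizon NCA converges to dose / (CL/F)
  tt_long <- c(seq(0, 24, by = 0.01), seq(24.1, 500, by = 0.1))
  auc_long <- auc_linuplogdown(tt_long, conc_2cmt_oral(p, 10, 0, tt_long))
  expect_equal(auc_long, auc_inf_analytic(p, 10), tolerance = 0.02)
})

test_that("cmax/tmax take the first attainment and survive permutation", {
  expect_equal(cmax_tmax(c(1, 2, 4), c(90, 50, 20)), list(cmax = 90, tmax = 1))
  expect_equal(cmax_tmax(c(1, 2, 4), c(50, 90, 90))$tmax, 2) # tie -> earlier
  set.seed(8)
  tt <- 1:12; cc <- rlnorm(12)
  ix <- sample(12)
  ord <- order(tt[ix])
  expect_equal(cmax_tmax(tt[ix][ord], cc[ix][ord]), cmax_tmax(tt, cc))
  expect_error(cmax_tmax(numeric(0), numeric(0)), "1 point")
})

test_that("geometric summaries behave like log-scale t statistics", {
  gs <- geo_summary(c(1, 10, 100))
  expect_equal(gs$gm, 10, tolerance = 1e-12)
  # independent computation of the interval
  lx <- log(c(1, 10, 100))
  expect_equal(gs$lo, exp(mean(lx) - qt(0.975, 2) * sd(lx) / sqrt(3)),
               tolerance = 1e-12)
  # all-equal values give a zero-width interval
  ge <- geo_summary(rep(7, 5))
  expect_equal(ge$lo, 7); expect_equal(ge$hi, 7)
  # scaling all values by k scales gm and CI by k
  g1 <- geo_summary(c(2, 5, 11)); g2 <- geo_summary(3 * c(2, 5, 11))
  expect_equal(3 * c(g1$gm, g1$lo, g1$hi), c(g2$gm, g2$lo, g2$hi))
  expect_error(geo_summary(c(1, 0)), "positive")
})

test_that("exposure ratios reproduce the published ratio arithmetic", {
  # vectors constructed to have the printed geometric means exactly
  r_dab <- exposure_ratio(gm_vector(6872), gm_vector(2233))
  expect_equal(r_dab$ratio, 6872 / 2233, tolerance = 1e-12)
  expect_equal(round(r_dab$ratio, 2), 3.08)
  r_ptv <- exposure_ratio(gm_vector(922), gm_vector(500))
  expect_equal(round(r_ptv$ratio, 2), 1.84)
  expect_equal(exposure_ratio(gm_vector(5), gm_vector(5))$ratio, 1)
  expect_error(exposure_ratio(numeric(0), gm_vector(1)), "non-empty")
  # Welch-on-logs p-value matches a direct t.test on the logs
  set.seed(4)
  e <- rlnorm(10, 8, 0.4); h <- rlnorm(14, 7.5, 0.3)
  expect_equal(exposure_ratio(e, h)$p,
               t.test(log(e), log(h))$p.value, tolerance = 1e-12)
})

test_that("percent change uses the decrease-positive convention", {
  expect_equal(round(percent_change(34.0, 121)), 72)
  expect_equal(percent_change(10, 10), 0)
  expect_equal(percent_change(20, 10), -100) # doubling -> -100%
})

test_that("unbound adjustment scales exposures by f_u", {
  df <- tibble::tibble(id = 1:4, group = c("HV", "HV", "ESRD", "ESRD"),
                       drug = "MDZ", cmax = c(10, 20, 5, 8),
                       tmax = 1, auc_last = c(100, 200, 50, 80), n_points = 5L)
  expect_equal(unbound_adjust(df, 1)$auc_last, df$auc_last)
  expect_equal(unbound_adjust(df, 0.5)$auc_last, df$auc_last / 2)
  expect_error(unbound_adjust(df, 1.5), "0, 1")
  # unbound ratio = bound ratio * (fu_ESRD / fu_HV)
  fu <- tibble::tibble(id = 1:4, drug = "MDZ", fu = c(0.03, 0.03, 0.0486, 0.0486))
  ub <- unbound_adjust(df, fu)
  bound <- exposure_ratio(df$auc_last[3:4], df$auc_last[1:2])$ratio
  unbound <- exposure_ratio(ub$auc_last[3:4], ub$auc_last[1:2])$ratio
  expect_equal(unbound, bound * 1.62, tolerance = 1e-12)
})

test_that("stratified summaries agree with direct subsetting", {
  set.seed(5)
  df <- tibble::tibble(id = 1:12, group = rep(c("HV", "ESRD"), each = 6),
                       sex = rep(c("M", "F"), 6), drug = "PTV",
                       cmax = rlnorm(12, 5), tmax = 1,
                       auc_last = rlnorm(12, 7), n_points = 8L)
  by_sex <- exposure_summary(df, by = "sex")
  direct <- geo_summary(df$auc_last[df$sex == "F"])
  got <- by_sex[by_sex$metric == "auc_last" & by_sex$sex == "F", ]
  expect_equal(got$gm, direct$gm)
  expect_equal(got$lo, direct$lo)
  # partition sizes sum to the total
  expect_equal(sum(by_sex$n[by_sex$metric == "auc_last"]), 12)
  # a single stratum equals the unstratified summary
  df$all <- "all"
  one <- exposure_summary(df, by = "all")
  expect_equal(one$gm[one$metric == "auc_last"], geo_summary(df$auc_last)$gm)
  # strata of size 1 are reported without a CI
  tiny <- exposure_summary(df[c(1, 2), ], by = "id")
  expect_true(all(is.na(tiny$lo)))
  # NCA pipeline feeds the summary: group ratio table has both metrics
  s <- simulate_cohort(4, 4, seed = 6)
  r <- simulate_trial(s, seed = 7)
  tab <- exposure_ratio_table(nca(r))
  expect_setequal(unique(tab$metric), c("cmax", "auc_last"))
  expect_true(all(is.finite(tab$ratio)))
})
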