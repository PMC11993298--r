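test_that("generated covariates reproduce the target group means", {
  s <- simulate_covariates(n_hv = 2000, n_esrd = 10000, seed = 101)
  esrd <- s[s$group == "ESRD", ]
  hv <- s[s$group == "HV", ]
  expect_equal(mean(esrd$scr), 1150.3, tolerance = 0.02)
  expect_equal(mean(esrd$age), 43.4, tolerance = 0.02)
  expect_equal(mean(esrd$albumin), 42.1, tolerance = 0.02)
  expect_equal(mean(hv$hct), 0.44, tolerance = 0.03)
  expect_equal(mean(hv$hgb), 137.1, tolerance = 0.02)
  # eligibility bounds from the eGFR criteria hold for every subject
  expect_true(all(hv$egfr >= 90))
  expect_true(all(esrd$egfr <= 15))
  # sex ratios scale with the study arms
  expect_equal(sum(esrd$sex == "M") / nrow(esrd), 0.7, tolerance = 1e-6)
})

test_that("zero CV collapses a covariate to its mean", {
  st <- covariate_stats()
  st$cv_hv[st$covariate == "age"] <- 0
  s <- simulate_covariates(n_hv = 8, n_esrd = 2, seed = 5, stats = st)
  expect_true(all(s$age[s$group == "HV"] == 35.6))
  st$cv_hv[st$covariate == "age"] <- -5
  expect_error(simulate_covariates(4, 2, seed = 5, stats = st), "CV%")
})

test_that("cohort generation is a pure function of the seed", {
  a <- simulate_cohort(6, 4, seed = 9)
  b <- simulate_cohort(6, 4, seed = 9)
  c <- simulate_cohort(6, 4, seed = 10)
  expect_identical(a, b)
  expect_false(identical(a$scr, c$scr))
})

test_that("genus abundances respect their configured ranges", {
  s <- simulate_covariates(50, 50, seed = 3)
  s <- simulate_microbiome(s, seed = 4)
  expect_true(all(s$Veillonella >= 0.015 & s$Veillonella <= 1.42))
  expect_true(all(s$Phascolarctobacterium >= 0.005 & s$Phascolarctobacterium <= 37))
  rng <- genus_ranges()
  rng$lo[1] <- rng$hi[1] <- 0.5
  sd2 <- simulate_microbiome(s[, 1:4], seed = 4, ranges = rng)
  expect_true(all(sd2$Veillonella == 0.5))
  rng$lo[2] <- 5; rng$hi[2] <- 1
  expect_error(simulate_microbiome(s[, 1:4], ranges = rng), "range")
})

test_that("the generating model couples log-clearance linearly to Veillonella", {
  # construction identity: with the genus effect exp(theta * x / 1.08), the
  # slope of log typical CL against abundance is exactly theta / 1.08
  subj <- tibble::tibble(dis = 1, Veillonella = seq(0.015, 1.42, length.out = 20))
  cl <- typical_cl(default_models()$PTV, subj)
  slope <- coef(lm(log(cl) ~ subj$Veillonella))[2]
  expect_equal(unname(slope), -0.677 / 1.08, tolerance = 1e-10)
})

test_that("CKD-EPI equation matches direct formula evaluation", {
  # female, age 50, creatinine exactly at the kappa knot (0.70 mg/dL)
  scr <- 0.70 * 88.4
  expected <- 141 * 1 * 1 * 0.993^50 * 1.018
  expect_equal(ckd_epi_egfr(scr, 50, "F"), expected, tolerance = 1e-12)
  # both piecewise branches coincide at the knot
  eps <- 1e-9
  expect_equal(ckd_epi_egfr(scr * (1 + eps), 50, "F"),
               ckd_epi_egfr(scr * (1 - eps), 50, "F"), tolerance = 1e-6)
  # male knot at 0.90 mg/dL
  scr_m <- 0.90 * 88.4
  expect_equal(ckd_epi_egfr(scr_m, 40, "M"), 141 * 0.993^40, tolerance = 1e-12)
  # monotone decreasing in creatinine
  grid <- ckd_epi_egfr(seq(40, 1500, by = 20), 45, "M")
  expect_true(all(diff(grid) < 0))
  expect_error(ckd_epi_egfr(100, -1, "M"), "age")
  expect_error(ckd_epi_egfr(0, 40, "M"), "creatinine")
})

test_that("phenotype assignment is total, CPIC-consistent, and strict on input", {
  # no functional CYP3A5 allele -> poor metabolizer
  g <- tibble::tibble(rs776746 = "G/G", rs2306283 = "A/A",
                      rs4149056 = "T/T", rs2231142 = "C/C")
  ph <- assign_phenotype(g)
  expect_equal(ph$cyp3a5, "poor")
  expect_equal(ph$oatp1b1, "normal")
  expect_equal(ph$bcrp, "normal")
  # all-reference diplotypes -> normal everywhere
  ref <- tibble::tibble(rs776746 = "A/A", rs2306283 = "A/A",
                        rs4149056 = "T/T", rs2231142 = "C/C")
  expect_true(all(assign_phenotype(ref) == "normal"))
  # homozygous 388G with functional 521 -> increased uptake function
  inc <- tibble::tibble(rs776746 = "A/A", rs2306283 = "G/G",
                        rs4149056 = "T/T", rs2231142 = "C/C")
  expect_equal(assign_phenotype(inc)$oatp1b1, "increased")

  # totality: every diplotype combination maps to exactly one known label
  dip <- function(a) c(paste(a[1], a[1], sep = "/"), paste(a[1], a[2], sep = "/"),
                       paste(a[2], a[2], sep = "/"))
  combos <- expand.grid(rs776746 = dip(c("A", "G")), rs2306283 = dip(c("A", "G")),
                        rs4149056 = dip(c("T", "C")), rs2231142 = dip(c("C", "A")),
                        stringsAsFactors = FALSE)
  ph_all <- assign_phenotype(combos)
  expect_equal(nrow(ph_all), 81)
  expect_true(all(ph_all$cyp3a5 %in% c("normal", "intermediate", "poor")))
  expect_true(all(ph_all$oatp1b1 %in% c("increased", "normal", "decreased", "poor")))
  expect_true(all(ph_all$bcrp %in% c("normal", "decreased", "poor")))

  # unknown allele -> indeterminate; malformed string -> parse error
  odd <- tibble::tibble(rs776746 = "A/T", rs2306283 = "A/A",
                        rs4149056 = "T/T", rs2231142 = "C/C")
  expect_equal(assign_phenotype(odd)$cyp3a5, "indeterminate")
  bad <- tibble::tibble(rs776746 = "AG", rs2306283 = "A/A",
                        rs4149056 = "T/T", rs2231142 = "C/C")
  expect_error(assign_phenotype(bad), "malformed")
})

test_that("simulated trials honour schedules, dosing and the seed contract", {
  s <- simulate_cohort(4, 3, seed = 21)
  r <- simulate_trial(s, seed = 22)
  # ESRD subjects have exactly 5 observation rows per drug, HV 8
  counts <- dplyr::count(r[r$evid == 0L, ], .data$group, .data$drug)
  expect_true(all(counts$n[counts$group == "ESRD"] == 3 * 5))
  expect_true(all(counts$n[counts$group == "HV"] == 4 * 8))
  # exactly one dose event per subject-drug, at time zero
  doses <- r[r$evid == 1L, ]
  expect_equal(nrow(doses), 7 * 5)
  expect_true(all(doses$time == 0))
  # bit-identical regeneration under the same seed
  expect_identical(r, simulate_trial(s, seed = 22))
  expect_false(identical(r$dv, simulate_trial(s, seed = 23)$dv))
})

test_that("noise-free IIV-free trials reproduce the typical curve exactly", {
  s <- simulate_cohort(2, 2, seed = 31)
  m <- default_models()$MDZ
  m$omega <- c(cl = 0)[0]
  m$sigma <- list(prop = 0, add = 0)
  r <- simulate_trial(s, models = list(MDZ = m), seed = 32, lloq = 0)
  typ <- typical_param_matrix(m, s)
  for (i in seq_len(nrow(s))) {
    rows <- r[r$id == s$id[i] & r$evid == 0L, ]
    p <- structural_params(typ[i, "ka"], typ[i, "cl"], typ[i, "vc"],
                           typ[i, "vp"], typ[i, "q"])
    expect_equal(rows$dv, conc_2cmt_oral(p, 10, 0, rows$time), tolerance = 1e-12)
  }
})
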