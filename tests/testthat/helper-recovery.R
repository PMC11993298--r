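# Parameter-recovery experiment machinery shared by the acceptance tests.

# Start values displaced from the truth so a refit has genuine work to do.
jitter_skeleton <- function(m, seed) {
  set.seed(seed)
  est <- setdiff(names(m$typ), m$fixed)
  m$typ[est] <- m$typ[est] * exp(runif(length(est), -0.25, 0.25))
  for (j in seq_along(m$effects)) {
    # shrink proportional-shift effects toward zero so the start stays
    # feasible (multiplier 1 + theta must remain positive); scale others up
    fac <- if (m$effects[[j]]$form == "proportional_shift") 0.75 else 1.3
    m$effects[[j]]$theta <- m$effects[[j]]$theta * fac
  }
  m$omega[] <- m$omega * exp(runif(length(m$omega), -0.3, 0.3))
  m
}

true_parameter_table <- function(m) {
  tidy(structure(list(model = m, estimate_sigma = TRUE), class = "pk_popfit"))
}

# Simulate records from exactly the assumed error model, including the
# Gaussian tail below zero. The production simulator clamps concentrations
# at zero (physical), but a simulate-then-refit experiment must draw from
# the model being fitted, otherwise the clamp leaves a tail bias in the
# peripheral parameters of the low-concentration drugs.
simulate_trial_unclamped <- function(subjects, model, schedules, seed,
                                     doses = cocktail_doses()) {
  set.seed(seed)
  amt <- doses$amount_ug[match(model$drug, doses$drug)]
  ind <- draw_individual_params(model, subjects)
  recs <- vector("list", nrow(subjects))
  for (i in seq_len(nrow(subjects))) {
    tt <- schedules[[subjects$group[i]]]
    p <- cocktailpk:::row_to_params(ind[i, ])
    f <- conc_2cmt_oral(p, amt, 0, tt)
    y <- f * (1 + rnorm(length(tt), 0, model$sigma$prop)) +
      rnorm(length(tt), 0, model$sigma$add)
    recs[[i]] <- tibble::tibble(
      id = subjects$id[i], group = subjects$group[i], drug = model$drug,
      time = c(0, tt), amt = c(amt, rep(NA_real_, length(tt))),
      evid = c(1L, rep(0L, length(tt))), dv = c(NA_real_, y), blq = FALSE)
  }
  dplyr::bind_rows(recs)
}

# Simulate n subjects from a final model on the rich design (no censoring:
# the experiment probes the estimator, not the BLQ-handling policy) and
# refit from a jittered skeleton. Returns truth/estimate/relative error.
recovery_experiment <- function(drug, subjects, seed_trial, seed_jitter) {
  m <- default_models()[[drug]]
  r <- simulate_trial_unclamped(subjects, m, rich_schedule(), seed_trial)
  fit <- fit_population(r, subjects, jitter_skeleton(m, seed_jitter))
  truth <- true_parameter_table(m)
  est <- tidy(fit)
  dplyr::mutate(
    dplyr::inner_join(dplyr::rename(truth, true = "estimate")[, c("term", "type", "true")],
                      est[, c("term", "estimate")], by = "term"),
    rel_err = (estimate - true) / true)
}
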