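# Independent oracles used across tests.

# Stiff-safe numerical integration of the three-state absorption/
# central/peripheral system; returns concentrations (pg/mL) at `times`.
ode_conc_oracle <- function(p, amt_ug, times) {
  m <- macro_to_micro(p)
  rhs <- function(t, y, parms) {
    list(c(
      -p$ka * y[1],
      p$ka * y[1] - (m$k10 + m$k12) * y[2] + m$k21 * y[3],
      m$k12 * y[2] - m$k21 * y[3]
    ))
  }
  y0 <- c(depot = amt_ug * 1e6, central = 0, peripheral = 0)
  out <- deSolve::lsoda(y0, times = sort(unique(c(0, times))), func = rhs,
                        parms = NULL, rtol = 1e-10, atol = 1e-8)
  out[match(times, out[, "time"]), "central"] / (p$vc_f * 1000)
}

random_params <- function() {
  structural_params(
    ka = exp(runif(1, log(0.3), log(18))),
    cl_f = exp(runif(1, log(5), log(500))),
    vc_f = exp(runif(1, log(20), log(1000))),
    vp_f = exp(runif(1, log(50), log(6000))),
    q_f = exp(runif(1, log(5), log(4000)))
  )
}

# Rich sampling design used by estimation tests: early points resolve the
# fast absorption of atorvastatin (t_max ~ 0.3 h), the 48-h tail the slow
# terminal phases; both arms share it.
rich_schedule <- function() {
  tt <- c(0, 0.25, 0.5, 1, 2, 3, 4, 6, 8, 12, 24, 36, 48)
  list(HV = tt, ESRD = tt)
}

# A vector with an exact prescribed geometric mean (gm preserved under the
# symmetric spread factor).
gm_vector <- function(gm, n = 4, spread = 1.5) {
  stopifnot(n %% 2 == 0)
  gm * rep(c(spread, 1 / spread), n / 2)
}
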