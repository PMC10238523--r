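# Component physics: elastance, valve law, coronary branch ODEs, and
# agreement between the compiled and reference derivative implementations.

lv_like <- function(T = 0.845) {
  list(E_max = 2.1, E_min = 0.06, m1 = 1.32, m2 = 27.4,
       tau1 = 0.269, tau2 = 0.452, onset_frac = 0)
}

test_that("elastance hits E_min at onset and E_max at its normalised peak", {
  T <- 0.845
  p <- lv_like(T)
  expect_equal(elastance(0, p, T), 0.06)
  grid <- seq(0, T, length.out = 5000)
  expect_equal(max(elastance(grid, p, T)), 2.1, tolerance = 1e-6)
  expect_equal(min(elastance(grid, p, T)), 0.06, tolerance = 1e-9)
})

test_that("elastance matches the analytic Hill value at t = tau1", {
  # with tau2 >> tau1 and a sharp descending limb the product at tau1 is 1/2
  T <- 1
  p <- list(E_max = 2, E_min = 0.1, m1 = 1.5, m2 = 80,
            tau1 = 0.1, tau2 = 0.9, onset_frac = 0)
  N <- coroflow:::elastance_norm_const(p$m1, p$m2, 0.1, 0.9, T)
  expect_equal(elastance(0.1, p, T), 0.1 + (2 - 0.1) * 0.5 / N,
               tolerance = 1e-9)
})

test_that("atrial phase shift moves activation to late diastole", {
  T <- 0.845
  la <- list(E_max = 0.17, E_min = 0.06, m1 = 1.32, m2 = 13.1,
             tau1 = 0.110, tau2 = 0.18, onset_frac = 1 - 0.110)
  grid <- seq(0, T, length.out = 2000)
  e <- elastance(grid, la, T)
  t_peak <- grid[which.max(e)]
  # atrial kick peaks at the end-diastole boundary (activation onset 0.89 T,
  # Hill rise ~ tau1..tau2 later), i.e. within 0.15 T of the cycle wrap
  expect_lt(min(t_peak, T - t_peak), 0.15 * T)
  # and the atrium is relaxed through mid-diastole (ventricular filling)
  expect_lt(elastance(0.5 * T, la, T), 0.07)
  expect_equal(max(e), 0.17, tolerance = 1e-5)
})

test_that("chamber pressure is the linear elastance relation", {
  expect_equal(chamber_pressure(60, 2.1, 0), 126)
  expect_equal(chamber_pressure(5, 1.7, 5), 0)
  V <- seq(10, 100, by = 10)
  expect_equal(chamber_pressure(V, 0.8, 5), 0.8 * (V - 5))
})

test_that("valve law reproduces the CGS hand evaluation and its scalings", {
  expect_equal(valve_pressure_gradient(250, 0, ELCo = 1.0), 24.61,
               tolerance = 0.01)
  expect_equal(valve_pressure_gradient(0, 0, ELCo = 1.0), 0)
  # quadrupling ELCo divides the steady convective drop by 16
  expect_equal(valve_pressure_gradient(250, 0, ELCo = 4.0),
               valve_pressure_gradient(250, 0, ELCo = 1.0) / 16,
               tolerance = 1e-12)
  # reverse flow gives a negative (symmetric) drop
  expect_equal(valve_pressure_gradient(-250, 0, ELCo = 1.0), -24.61,
               tolerance = 0.01)
  # inertial term scales with dQ/dt and the dedicated mitral coefficient
  dp <- valve_pressure_gradient(0, 1000, ELCo = 4, inertial_coeff = 0.53)
  expect_equal(dp, 2 * pi * 0.53 / sqrt(4) / 1333.22 * 1000, tolerance = 1e-9)
})

test_that("coronary branch derivatives satisfy Kirchhoff balances", {
  prm <- list(R_p = 24.7, R_m = 40.2, R_d = 12.4, C_p = 0.0015, C_m = 0.012)
  d <- coronary_branch_derivatives(P_in = 100, P_out = 4, P_im = 50,
                                   dPim_dt = 120, state = c(90, 60),
                                   params = prm)
  expect_equal(d$q_in, (100 - 90) / 24.7)
  expect_equal(d$q_m, (90 - 60) / 40.2)
  expect_equal(d$q_out, (60 - 4) / 12.4)
  expect_equal(d$dP_p, (d$q_in - d$q_m) / 0.0015)      # Eq. balance at C_p
  expect_equal(d$dP_m, (d$q_m - d$q_out) / 0.012 + 120)
})

test_that("branch solver settles on the closed-form resistive chain", {
  # constant imposed pressures: steady flows must equal the resistive oracle
  prm <- list(R_p = 24.7, R_m = 40.2, R_d = 12.4, C_p = 0.0015, C_m = 0.012)
  P_in <- 96; P_out <- 4; P_im <- 30
  oracle <- (P_in - P_out) / (prm$R_p + prm$R_m + prm$R_d)
  rhs <- function(t, y, parms) {
    d <- coronary_branch_derivatives(P_in, P_out, P_im, 0, y, prm)
    list(c(d$dP_p, d$dP_m))
  }
  out <- deSolve::ode(y = c(P_p = 0, P_m = 0), times = seq(0, 10, 0.1),
                      func = rhs, parms = NULL, method = "lsoda",
                      rtol = 1e-10, atol = 1e-10)
  yf <- out[nrow(out), ]
  q_in <- (P_in - yf[["P_p"]]) / prm$R_p
  q_m <- (yf[["P_p"]] - yf[["P_m"]]) / prm$R_m
  q_out <- (yf[["P_m"]] - P_out) / prm$R_d
  expect_equal(q_in, oracle, tolerance = 1e-3)   # 0.1%
  expect_equal(q_m, oracle, tolerance = 1e-3)
  expect_equal(q_out, oracle, tolerance = 1e-3)
  # equal boundary pressures: zero steady flow
  rhs0 <- function(t, y, parms) {
    d <- coronary_branch_derivatives(50, 50, P_im, 0, y, prm)
    list(c(d$dP_p, d$dP_m))
  }
  out0 <- deSolve::ode(y = c(P_p = 0, P_m = 0), times = seq(0, 20, 0.1),
                       func = rhs0, parms = NULL, method = "lsoda",
                       rtol = 1e-10, atol = 1e-10)
  yf0 <- out0[nrow(out0), ]
  expect_equal((50 - yf0[["P_p"]]) / prm$R_p, 0, tolerance = 1e-6)
})

test_that("compiled and reference derivatives agree along a trajectory", {
  p <- build_model_parameters(table2_means_patient(), default_anatomy())
  pv <- coroflow:::pack_params(p)
  y0 <- coroflow:::initial_state(p)
  times <- seq(0, 2 * p$T, length.out = 401)
  oC <- deSolve::ode(y = y0, times = times, func = "c3vm_derivs", parms = pv,
                     dllname = "coroflow", initfunc = "c3vm_init", nout = 16,
                     outnames = coroflow:::c3vm_output_names,
                     method = "lsoda", rtol = 1e-8, atol = 1e-8, hini = 1e-4)
  oR <- deSolve::ode(y = y0, times = times,
                     func = function(t, y, pp) coroflow:::c3vm_derivs_r(t, y, pp),
                     parms = pv, method = "lsoda", rtol = 1e-8, atol = 1e-8,
                     hini = 1e-4)
  mC <- unclass(oC)[, 2:16]; mR <- unclass(oR)[, 2:16]
  expect_lt(max(abs(mC - mR)), 1e-4)
  # pointwise derivative agreement at an arbitrary state
  y <- mC[200, ]
  dR <- coroflow:::c3vm_derivs_r(times[200], y, pv)
  expect_equal(length(dR[[1]]), 15)
  expect_true(all(is.finite(dR[[1]])))
})

test_that("the R engine of integrate_to_periodic matches the compiled one", {
  # start both engines from the same converged state of the tuned model
  sim <- baseline_sim()
  y0 <- attr(sim$waveforms, "y_final")
  wC <- integrate_to_periodic(sim$params, y0 = y0, max_cycles = 10,
                              n_grid = 64)
  wR <- integrate_to_periodic(sim$params, y0 = y0, max_cycles = 10,
                              n_grid = 64, engine = "r")
  expect_lt(max(abs(wC$P_LV - wR$P_LV)), 0.05)
  expect_lt(max(abs(wC$q_LAD - wR$q_LAD)), 0.01)
})
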