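# Periodic-limit-cycle integration and target tuning.

test_that("a near-resistive circuit converges within a few cycles", {
  # shrink every capacitor/inductor and stiffen the chambers to constant
  # elastance so all storage relaxes within one cycle: the periodic solver
  # must stop almost immediately and the network must track the algebraic
  # (resistive) solution
  m <- table2_means_patient(); an <- default_anatomy()
  p <- build_model_parameters(m, an, overrides = list(
    C_ao = 1e-3, C_SAC = 1e-3, C_PVC = 1e-3, C_PA = 1e-3,
    C_cor_total_left = 1e-4, C_cor_total_right = 5e-5,
    L_PV = 1e-8, L_PC = 1e-6,
    E_max_LV = 20, E_min_LV = 20, E_max_LA = 20, E_min_LA = 20))
  y0 <- setNames(c(10, 4.5, 96, 90, 40, 12, 90, 90, 90,
                   60, 30, 60, 30, 60, 30),
                 coroflow:::c3vm_state_names)
  w <- integrate_to_periodic(p, accelerate = FALSE, y0 = y0)
  expect_lte(attr(w, "n_cycles_run"), 5)
  expect_lte(attr(w, "convergence_residual"), 1e-6)
  # each coronary branch carries the closed-form resistive-chain flow
  i <- which.min(abs(w$time - 0.75 * p$T))
  for (b in c("LAD", "LCX", "RCA")) {
    cb <- p$coronary[[b]]
    oracle <- (w$P_ao_root[i] - p$systemic$P_CV0) / (cb$R_p + cb$R_m + cb$R_d)
    expect_equal(w[[paste0("q_", b)]][i], oracle, tolerance = 0.03)
  }
})

test_that("a converged run re-integrated one more cycle is a fixed point", {
  sim <- baseline_sim()
  w2 <- integrate_to_periodic(sim$params,
                              y0 = attr(sim$waveforms, "y_final"))
  expect_lte(attr(w2, "convergence_residual"), 1e-6)
  expect_lte(attr(w2, "n_cycles_run"), 3)
})

test_that("cohort-mean patient converges within the recorded cycle budget", {
  p <- build_model_parameters(table2_means_patient(), default_anatomy())
  w <- integrate_to_periodic(p)
  # empirical bound recorded at implementation time (typ. ~120 cycles cold)
  expect_lte(attr(w, "n_cycles_run"), 250)
  expect_lte(attr(w, "convergence_residual"), 1e-6)
  expect_true(all(w$V_LV > 0) && all(w$V_LA > 0))
})

test_that("integration is deterministic", {
  p <- build_model_parameters(table2_means_patient(), default_anatomy())
  w1 <- integrate_to_periodic(p, max_cycles = 30, tol = 1e-4)
  w2 <- integrate_to_periodic(p, max_cycles = 30, tol = 1e-4)
  expect_identical(as.data.frame(w1), as.data.frame(w2))
})

test_that("non-convergence raises a residual-carrying error", {
  p <- build_model_parameters(table2_means_patient(), default_anatomy())
  err <- tryCatch(integrate_to_periodic(p, max_cycles = 3, accelerate = FALSE),
                  error = function(e) e)
  expect_s3_class(err, "coroflow_convergence_error")
  expect_true(length(err$residual_history) >= 1)
})

test_that("tuning reaches the cuff-pressure and stroke-volume targets", {
  sim <- baseline_sim()
  t <- sim$tuning
  expect_lte(abs(t$achieved_SBP - 133.0), 1)
  expect_lte(abs(t$achieved_DBP - 70.5), 1)
  expect_lte(abs(t$achieved_forward_SV - 77.87), 1)
  expect_lte(abs(t$achieved_ub_fraction - 0.15), 0.005)
})

test_that("re-tuning its own output moves nothing beyond tolerance", {
  sim <- baseline_sim()
  fit2 <- tune_patient(sim$measurements, sim$params)
  expect_lte(abs(fit2$tuning$achieved_SBP - sim$tuning$achieved_SBP), 1)
  expect_lte(abs(fit2$tuning$achieved_DBP - sim$tuning$achieved_DBP), 1)
  expect_lte(abs(fit2$tuning$achieved_forward_SV -
                   sim$tuning$achieved_forward_SV), 1)
})

test_that("periodic charge conservation holds at every capacitor", {
  sim <- baseline_sim()
  w <- sim$waveforms
  T <- attr(w, "T")
  CO <- coroflow:::forward_av_volume(w) / T
  tz <- coroflow:::trapz
  # net per-cycle current into each capacitor, from the node balances
  p <- sim$params
  i_Cao <- tz(w$time, w$Q_AV - w$q_sys - w$q_ub -
                (w$q_LAD + w$q_LCX + w$q_RCA)) / T
  i_CSAC <- tz(w$time, w$q_sys - (w$P_SAC - p$systemic$P_CV0) /
                 p$systemic$R_SV) / T
  i_CPA <- tz(w$time, w$Q_PC - w$q_pa) / T
  for (i_cap in c(i_Cao, i_CSAC, i_CPA)) {
    expect_lte(abs(i_cap), 1e-4 * CO)
  }
  # and in the coronary branches (proximal node)
  for (b in c("LAD", "LCX", "RCA")) {
    q_in <- w[[paste0("q_", b)]]; q_out <- w[[paste0("q_out_", b)]]
    expect_lte(abs(tz(w$time, q_in - q_out)) / T, 1e-4 * CO)
  }
})

test_that("mean LA inflow over the cycle equals the imposed source mean", {
  sim <- baseline_sim()
  w <- sim$waveforms
  T <- attr(w, "T")
  expect_equal(coroflow:::trapz(w$time, w$q_pa) / T,
               sim$params$pulmonary$Q_MPV, tolerance = 1e-3)
})

test_that("simulate_patient is deterministic end to end", {
  m <- table2_means_patient(); an <- default_anatomy()
  ctl <- tune_control()
  s1 <- simulate_patient(m, an, control = ctl)
  s2 <- simulate_patient(m, an, control = ctl)
  expect_identical(as.data.frame(s1$waveforms), as.data.frame(s2$waveforms))
  expect_identical(as.data.frame(s1$tuning), as.data.frame(s2$tuning))
})

test_that("paravalvular leak tuning recovers the specified leak volume", {
  m <- table2_means_patient()
  m$V_leak <- 8
  sim <- simulate_patient(m, default_anatomy())
  expect_lte(abs(sim$tuning$achieved_V_leak - 8), 0.5)
  expect_false(is.na(sim$tuning$R_leak))
  # leak flow is retrograde (root to LV) mostly in systole-independent phases
  expect_gt(coroflow:::leak_volume(sim$waveforms), 0)
})
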