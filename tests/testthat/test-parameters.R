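# Circuit-element derivation: MAP, total/branch resistances, compliances,
# energy-loss coefficients and the assembled parameter set.

test_that("MAP formula reproduces hand-evaluated values", {
  expect_equal(compute_map(133.0, 70.5, 71), 96.66, tolerance = 1e-4)
  expect_equal(compute_map(142.0, 72.0, 73), 101.47, tolerance = 1e-4)
  # zero pulse pressure is the identity (evaluate at the open limit)
  expect_equal(compute_map(100 + 1e-9, 100, 60), 100, tolerance = 1e-6)
  expect_error(compute_map(100, 120, 60), class = "coroflow_domain_error")
})

test_that("total coronary resistance follows the 4% flow assumption", {
  expect_equal(total_coronary_resistance(96.66, 5000 / 60), 29.00,
               tolerance = 1e-3)
  expect_equal(total_coronary_resistance(100, 100), 25.0)
  expect_equal(total_coronary_resistance(100, 50),
               2 * total_coronary_resistance(100, 100))  # flow scaling
  expect_error(total_coronary_resistance(-1, 10),
               class = "coroflow_domain_error")
})

test_that("Murray allocation: parallel-sum identity and derived LAD value", {
  an <- coronary_anatomy(0.10, 0.06, 0.09)
  r <- allocate_branch_resistances(an, 29.0)
  expect_equal(r$R_branch[r$branch == "LAD"], 69.2, tolerance = 0.05)
  # exact identity: branch totals recombine in parallel to R_total
  expect_equal(1 / sum(1 / r$R_branch), 29.0, tolerance = 1e-12)
  # symmetric areas: each branch total is 3 R_total
  rs <- allocate_branch_resistances(coronary_anatomy(0.08, 0.08, 0.08), 10)
  expect_equal(rs$R_branch, rep(30, 3), tolerance = 1e-12)
})

test_that("stenosis factor and proximal/medial/distal split", {
  an <- coronary_anatomy(0.08, 0.08, 0.08, A_sten_LAD = 0.04)
  r <- allocate_branch_resistances(an, 100 / 3)  # branch totals 100
  lad <- r[r$branch == "LAD", ]
  expect_equal(lad$alpha, 0.5)
  expect_equal(lad$R_adjusted, 400)              # alpha^-2 = 4
  expect_equal(c(lad$R_p, lad$R_m, lad$R_d), c(128, 208, 64))
  # alpha = 1 is the identity; splits always sum to the branch total
  lcx <- r[r$branch == "LCX", ]
  expect_equal(lcx$R_adjusted, lcx$R_branch)
  expect_equal(r$R_p + r$R_m + r$R_d, r$R_adjusted, tolerance = 1e-12)
  # tiny alpha is legal (alpha in (0, 1])
  expect_silent(allocate_branch_resistances(
    coronary_anatomy(0.08, 0.08, 0.08, A_sten_LAD = 1e-12), 10))
})

test_that("compliance allocation conserves side totals and splits 11/89", {
  an <- coronary_anatomy(0.10, 0.06, 0.09)
  cc <- allocate_branch_compliances(an, 0.020, 0.0125)
  expect_equal(cc$C_branch[cc$branch == "LAD"], 0.0125)
  expect_equal(cc$C_branch[cc$branch == "LCX"], 0.0075)
  expect_equal(sum(cc$C_branch[cc$branch != "RCA"]), 0.020)  # conservation
  expect_equal(cc$C_branch[cc$branch == "RCA"], 0.0125)
  lad <- cc[cc$branch == "LAD", ]
  expect_equal(c(lad$C_p, lad$C_m), c(0.001375, 0.011125))
  expect_equal(cc$C_p + cc$C_m, cc$C_branch, tolerance = 1e-15)
})

test_that("energy-loss coefficient: identities and limits", {
  expect_equal(energy_loss_coefficient(2.0, 4.0), 4.0)   # EOA = A/2 => ELCo = A
  expect_equal(energy_loss_coefficient(0.84, 4.0), 1.063, tolerance = 1e-3)
  expect_equal(energy_loss_coefficient(1.5, 1e9), 1.5, tolerance = 1e-6)
  eoas <- seq(0.4, 2.0, by = 0.2)
  elcos <- energy_loss_coefficient(eoas, 4.0)
  expect_true(all(elcos > eoas))                         # ELCo > EOA always
  expect_true(all(diff(elcos) > 0))                      # monotone in EOA
  expect_error(energy_loss_coefficient(4.0, 4.0),
               class = "coroflow_domain_error")
})

test_that("build_model_parameters populates constants, paths and overrides", {
  m <- table2_means_patient(); an <- default_anatomy()
  p <- build_model_parameters(m, an)
  expect_equal(p$systemic$R_ao, 0.05)
  expect_equal(p$systemic$R_SV, 0.05)
  expect_equal(p$systemic$R_pda, 0.05)
  expect_equal(p$systemic$P_CV0, 4)
  expect_equal(p$pulmonary$C_PVC, 40)
  expect_equal(p$pulmonary$C_PA, 4)
  expect_equal(p$lv$E_max, 2.1)
  expect_equal(p$la$m2, 13.1)
  expect_equal(p$rho, 1050)
  # no regurgitation measured: the three optional paths are absent
  expect_null(p$valves$ar)
  expect_null(p$valves$mr)
  expect_null(p$valves$leak)
  # positive measurements instantiate them
  m2 <- m; m2$EOA_AR <- 0.2; m2$EOA_MR <- 0.3; m2$V_leak <- 5
  p2 <- build_model_parameters(m2, an)
  expect_false(is.null(p2$valves$ar))
  expect_false(is.null(p2$valves$mr))
  expect_false(is.null(p2$valves$leak))
  # purity: same inputs, identical output
  expect_identical(p, build_model_parameters(m, an))
})

test_that("compliance override propagates through the dependent splits", {
  m <- table2_means_patient(); an <- default_anatomy()
  p <- build_model_parameters(m, an, overrides = list(C_cor_total_left = 0.04))
  share_LAD <- an$A_LAD / (an$A_LAD + an$A_LCX)
  expect_equal(p$coronary$LAD$C_p, 0.11 * share_LAD * 0.04, tolerance = 1e-12)
  expect_equal(p$coronary$LAD$C_m, 0.89 * share_LAD * 0.04, tolerance = 1e-12)
  expect_equal(p$C_cor_total_left, 0.04)
  # untouched side unchanged
  expect_equal(p$coronary$RCA$C_m, 0.89 * 0.0125, tolerance = 1e-12)
})

test_that("derived coronary totals use CO from forward LVOT SV", {
  m <- table2_means_patient(); an <- default_anatomy()
  p <- build_model_parameters(m, an)
  CO <- m$forward_LVOT_SV * m$HR / 60
  expect_equal(p$R_cor_total, compute_map(m$SBP, m$DBP, m$HR) / (0.04 * CO),
               tolerance = 1e-12)
  r <- allocate_branch_resistances(an, p$R_cor_total)
  expect_equal(p$coronary$LCX$R_m, r$R_m[r$branch == "LCX"], tolerance = 1e-12)
})
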