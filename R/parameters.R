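# Derivation of every circuit element from the non-invasive measurements.

#' Mean arterial pressure from cuff pressures and heart rate
#'
#' `MAP = DBP + (1/3 + 0.0012 * HR) * (SBP - DBP)`, the heart-rate-corrected
#' form factor estimate of the mean from brachial systolic/diastolic pressure.
#'
#' @param SBP,DBP systolic/diastolic pressure, mmHg (`SBP > DBP > 0`).
#' @param HR heart rate, beats/min.
#' @return MAP in mmHg.
#' @export
#' @examples
#' compute_map(133.0, 70.5, 71)
compute_map <- function(SBP, DBP, HR) {
  check_that(all(DBP > 0) && all(SBP > DBP), "requires SBP > DBP > 0",
             class = "coroflow_domain_error")
  check_that(all(HR > 0), "requires HR > 0", class = "coroflow_domain_error")
  DBP + (1 / 3 + HR * 0.0012) * (SBP - DBP)
}

#' Total coronary resistance
#'
#' The mean coronary flow is taken as 4.0% of cardiac output, so the lumped
#' resistance of the whole coronary tree is `R = MAP / (0.04 * CO)`.
#'
#' @param MAP mean arterial pressure, mmHg.
#' @param CO cardiac output, mL/s.
#' @return Total coronary resistance, mmHg s/mL.
#' @export
#' @examples
#' total_coronary_resistance(96.66, 5000 / 60)
total_coronary_resistance <- function(MAP, CO) {
  check_that(all(MAP > 0) && all(CO > 0), "requires MAP > 0 and CO > 0",
             class = "coroflow_domain_error")
  MAP / (0.04 * CO)
}

# fraction of CO routed to the coronary tree, used by the allocation above
CORONARY_FLOW_FRACTION <- 0.04

#' Murray-law allocation of coronary branch resistances
#'
#' Splits the total coronary resistance across the LAD, LCX and RCA using a
#' variation of Murray's law, `R_j = (sum_i A_i^1.3 / A_j^1.3) * R_total`
#' (all three branches pooled into one allocation), applies the stenosis
#' adjustment `R -> R * alpha^-2` with `alpha = A_sten/A`, and divides each
#' branch total into proximal/medial/distal elements with fixed fractions
#' 0.32 / 0.52 / 0.16.
#'
#' The unadjusted branch totals satisfy the exact identity that their
#' parallel combination equals `R_total`.
#'
#' @param anatomy a [coronary_anatomy()] row.
#' @param R_total total coronary resistance, mmHg s/mL.
#' @return Tibble with one row per branch: `branch`, `alpha`, `R_branch`
#'   (Murray total before stenosis), `R_adjusted`, and the split `R_p`,
#'   `R_m`, `R_d`.
#' @export
#' @examples
#' allocate_branch_resistances(coronary_anatomy(0.10, 0.06, 0.09), 29)
allocate_branch_resistances <- function(anatomy, R_total) {
  validate_coronary_anatomy(anatomy)
  check_that(R_total > 0, "requires R_total > 0", class = "coroflow_domain_error")
  A <- c(LAD = anatomy$A_LAD, LCX = anatomy$A_LCX, RCA = anatomy$A_RCA)
  As <- c(LAD = anatomy$A_sten_LAD, LCX = anatomy$A_sten_LCX,
          RCA = anatomy$A_sten_RCA)
  alpha <- As / A
  check_that(all(alpha > 0 & alpha <= 1), "requires alpha in (0, 1]",
             class = "coroflow_domain_error")
  w <- sqrt(A)^2.6                         # A^1.3 Murray weights
  R_branch <- sum(w) / w * R_total
  R_adj <- R_branch * alpha^-2
  tibble(
    branch = names(A), alpha = unname(alpha),
    R_branch = unname(R_branch), R_adjusted = unname(R_adj),
    R_p = unname(0.32 * R_adj), R_m = unname(0.52 * R_adj),
    R_d = unname(0.16 * R_adj)
  )
}

#' Area-proportional allocation of coronary branch compliances
#'
#' The two left branches share the total left coronary compliance in
#' proportion to cross-sectional area (`C_j = A_j / sum(A_left) * C_left`);
#' the RCA takes the full right total. Within a branch the compliance is
#' divided across the proximal and medial capacitors as 0.11 / 0.89.
#'
#' @param anatomy a [coronary_anatomy()] row.
#' @param C_left_total,C_right_total side totals, mL/mmHg.
#' @return Tibble with one row per branch: `branch`, `C_branch`, `C_p`, `C_m`.
#' @export
allocate_branch_compliances <- function(anatomy, C_left_total, C_right_total) {
  validate_coronary_anatomy(anatomy)
  check_that(C_left_total > 0 && C_right_total > 0,
             "requires positive compliance totals",
             class = "coroflow_domain_error")
  A_left <- c(LAD = anatomy$A_LAD, LCX = anatomy$A_LCX)
  C_branch <- c(A_left / sum(A_left) * C_left_total, RCA = C_right_total)
  tibble(
    branch = names(C_branch), C_branch = unname(C_branch),
    C_p = unname(0.11 * C_branch), C_m = unname(0.89 * C_branch)
  )
}

#' Energy-loss coefficient of a valve
#'
#' `ELCo = EOA * A / (A - EOA)`: the effective area that governs the net
#' (post-recovery) transvalvular pressure loss, given the effective orifice
#' area and the downstream cross-section `A`.
#'
#' @param EOA effective orifice area, cm^2 (`0 < EOA < A`).
#' @param A downstream reference area, cm^2.
#' @return ELCo in cm^2 (always `> EOA`; tends to `EOA` as `A -> Inf`).
#' @export
#' @examples
#' energy_loss_coefficient(0.84, 4.0)
energy_loss_coefficient <- function(EOA, A) {
  check_that(all(EOA > 0) && all(EOA < A),
             "requires 0 < EOA < A (ELCo diverges at EOA = A)",
             class = "coroflow_domain_error")
  EOA * A / (A - EOA)
}

# Table of fixed circuit constants (units: mmHg, mL, s).
default_constants <- function() {
  list(
    R_ao = 0.05, R_SV = 0.05, R_pda = 0.05, P_CV0 = 4,
    C_ao = 0.5, C_SAC = 2, R_SA = 0.8,            # tunable initials
    L_PV = 5e-4, R_PV = 0.002, R_PVC = 0.001, C_PVC = 40,
    L_PC = 3e-4, R_PC = 0.21, R_PA = 0.01, C_PA = 4,
    M_MV = 0.53,                                   # g/cm^2 mitral inertance
    rho = 1050,                                    # kg/m^3
    C_cor_total_left = 0.0250, C_cor_total_right = 0.0125,
    # LV / LA double-Hill elastance parameter sets (tau as fractions of T)
    E_max_LV = 2.1, E_min_LV = 0.06, m1_LV = 1.32, m2_LV = 27.4,
    tau1_LV = 0.269, tau2_LV = 0.452, V0_LV = 5,
    E_max_LA = 0.17, E_min_LA = 0.06, m1_LA = 1.32, m2_LA = 13.1,
    tau1_LA = 0.110, tau2_LA = 0.18, V0_LA = 4,
    # smooth-diode numerics
    R_diode = 1000, q_eps = 0.25, delta_reg = 0.1
  )
}

# valve-law coefficients in model units (mmHg, mL/s) from CGS inputs
.valve_B <- function(ELCo, rho_cgs) rho_cgs / (2 * ELCo^2) / DYN_PER_MMHG
.valve_L <- function(inertial_cgs, ELCo) 2 * pi * inertial_cgs / sqrt(ELCo) / DYN_PER_MMHG
.reg_k <- function(ELCo, rho_cgs) ELCo * sqrt(2 * DYN_PER_MMHG / rho_cgs)

#' Build the full circuit parameter set for one patient
#'
#' Maps a measurement row and coronary anatomy to every element of the
#' closed-loop circuit: fixed constants, tunable initial values, elastance
#' chamber parameters (with the double-Hill normalisation constant
#' precomputed), valve energy-loss/inertance coefficients, and the coronary
#' branch elements derived via [total_coronary_resistance()],
#' [allocate_branch_resistances()] and [allocate_branch_compliances()] using
#' `CO = forward_LVOT_SV * HR / 60` and [compute_map()]. Regurgitant and
#' paravalvular-leak paths are instantiated only when the corresponding
#' measurement is positive.
#'
#' This is a pure function of its inputs; tuning ([tune_patient()]) returns a
#' modified copy.
#'
#' @param meas a [patient_measurements()] row.
#' @param anatomy a [coronary_anatomy()] row.
#' @param overrides named list overriding any constant by its abbreviation
#'   (e.g. `list(C_cor_total_left = 0.03, E_max_LV = 2.5)`); dependent
#'   quantities are recomputed.
#' @return A list of class `c3vm_params`.
#' @export
build_model_parameters <- function(meas, anatomy, overrides = list()) {
  validate_patient_measurements(meas)
  validate_coronary_anatomy(anatomy)
  k <- modifyList(default_constants(), overrides)
  m <- as.list(meas[1, ])
  rho_cgs <- k$rho / 1000

  T <- m$T
  MAP <- compute_map(m$SBP, m$DBP, m$HR)
  CO <- m$forward_LVOT_SV * m$HR / 60       # mL/s

  R_total <- total_coronary_resistance(MAP, CO)
  res <- allocate_branch_resistances(anatomy, R_total)
  cmp <- allocate_branch_compliances(anatomy, k$C_cor_total_left,
                                     k$C_cor_total_right)
  cor <- purrr::map(c(LAD = "LAD", LCX = "LCX", RCA = "RCA"), function(b) {
    r <- res[res$branch == b, ]
    cc <- cmp[cmp$branch == b, ]
    list(R_p = r$R_p, R_m = r$R_m, R_d = r$R_d,
         C_p = cc$C_p, C_m = cc$C_m,
         im_pressure_scale = if (b == "RCA") 0.5 else 1.0)
  })

  mk_chamber <- function(E_max, E_min, m1, m2, tau1, tau2, V0, onset_frac = 0) {
    list(E_max = E_max, E_min = E_min, m1 = m1, m2 = m2,
         tau1 = tau1, tau2 = tau2, V0 = V0, onset_frac = onset_frac,
         N = elastance_norm_const(m1, m2, tau1 * T, tau2 * T, T))
  }
  lv <- mk_chamber(k$E_max_LV, k$E_min_LV, k$m1_LV, k$m2_LV,
                   k$tau1_LV, k$tau2_LV, k$V0_LV)
  # atrial activation is phase-shifted to late diastole (atrial kick)
  la <- mk_chamber(k$E_max_LA, k$E_min_LA, k$m1_LA, k$m2_LA,
                   k$tau1_LA, k$tau2_LA, k$V0_LA,
                   onset_frac = 1 - k$tau1_LA)

  ELCo_AV <- energy_loss_coefficient(m$EOA_AV, m$A_ascending_aorta)
  ELCo_MV <- m$EOA_MV     # infinite-reference-area limit for the mitral inflow
  valves <- list(
    av = list(EOA = m$EOA_AV, ELCo = ELCo_AV, direction = "forward",
              L = .valve_L(rho_cgs, ELCo_AV), B = .valve_B(ELCo_AV, rho_cgs)),
    mv = list(EOA = m$EOA_MV, ELCo = ELCo_MV, direction = "forward",
              L = .valve_L(k$M_MV, ELCo_MV), B = .valve_B(ELCo_MV, rho_cgs)),
    ar = NULL, mr = NULL, leak = NULL
  )
  if (m$EOA_AR > 0) {
    ELCo_AR <- energy_loss_coefficient(m$EOA_AR, m$A_LVOT)
    valves$ar <- list(EOA = m$EOA_AR, ELCo = ELCo_AR, direction = "regurgitant",
                      k = .reg_k(ELCo_AR, rho_cgs))
  }
  if (m$EOA_MR > 0) {
    valves$mr <- list(EOA = m$EOA_MR, ELCo = m$EOA_MR, direction = "regurgitant",
                      k = .reg_k(m$EOA_MR, rho_cgs))
  }
  if (m$V_leak > 0) {
    # constant-resistance path in parallel with the AV; R_leak is tuned so the
    # per-cycle retrograde volume matches V_leak
    valves$leak <- list(V_leak = m$V_leak, R_leak = 5)
  }

  p <- structure(list(
    T = T, T_EJ = m$T_EJ, HR = m$HR,
    lv = lv, la = la, valves = valves,
    systemic = list(R_ao = k$R_ao, R_SV = k$R_SV, R_SA = k$R_SA,
                    R_pda = k$R_pda, R_ub = (MAP - k$P_CV0) / (0.15 * CO),
                    C_ao = k$C_ao, C_SAC = k$C_SAC, P_CV0 = k$P_CV0),
    pulmonary = list(L_PV = k$L_PV, R_PV = k$R_PV, R_PVC = k$R_PVC,
                     C_PVC = k$C_PVC, L_PC = k$L_PC, R_PC = k$R_PC,
                     R_PA = k$R_PA, C_PA = k$C_PA,
                     Q_MPV = m$forward_LVOT_SV / T),
    coronary = cor,
    R_cor_total = R_total,
    C_cor_total_left = k$C_cor_total_left,
    C_cor_total_right = k$C_cor_total_right,
    rho = k$rho,
    numerics = list(R_diode = k$R_diode, q_eps = k$q_eps,
                    delta_reg = k$delta_reg),
    derived = list(MAP_input = MAP, CO_input = CO,
                   forward_LVOT_SV = m$forward_LVOT_SV,
                   EDV = m$EDV, ESV = m$ESV)
  ), class = "c3vm_params")
  p
}

#' @export
print.c3vm_params <- function(x, ...) {
  cat("<c3vm_params>\n")
  cat(sprintf("  cycle: T = %.3f s (HR %.1f), T_EJ = %.3f s\n", x$T, x$HR, x$T_EJ))
  cat(sprintf("  inputs: MAP = %.1f mmHg, CO = %.1f mL/s, forward SV = %.1f mL\n",
              x$derived$MAP_input, x$derived$CO_input, x$derived$forward_LVOT_SV))
  cat(sprintf("  R_cor_total = %.2f mmHg s/mL; C_cor left/right = %.4f / %.4f mL/mmHg\n",
              x$R_cor_total, x$C_cor_total_left, x$C_cor_total_right))
  for (b in names(x$coronary)) {
    cb <- x$coronary[[b]]
    cat(sprintf("  %s: R(p,m,d) = %.1f/%.1f/%.1f, C(p,m) = %.5f/%.5f, im scale %.1f\n",
                b, cb$R_p, cb$R_m, cb$R_d, cb$C_p, cb$C_m, cb$im_pressure_scale))
  }
  cat(sprintf("  tunables: C_ao = %.3f, C_SAC = %.3f, R_SA = %.3f, R_ub = %.3f, Q_MPV = %.1f\n",
              x$systemic$C_ao, x$systemic$C_SAC, x$systemic$R_SA,
              x$systemic$R_ub, x$pulmonary$Q_MPV))
  paths <- c(AR = !is.null(x$valves$ar), MR = !is.null(x$valves$mr),
             PVL = !is.null(x$valves$leak))
  cat("  optional paths:", if (any(paths)) paste(names(paths)[paths], collapse = ", ")
      else "none", "\n")
  invisible(x)
}

#' Flatten derived parameters for audit
#'
#' Returns the full parameter set as a two-column tibble (name, value) using
#' the standard abbreviations, e.g. for `--dump-params` style output.
#'
#' @param params a `c3vm_params` object.
#' @return Tibble with columns `parameter`, `value`.
#' @export
dump_parameters <- function(params) {
  stopifnot(inherits(params, "c3vm_params"))
  flat <- unlist(params[c("T", "T_EJ", "HR", "lv", "la", "systemic",
                          "pulmonary", "coronary", "R_cor_total",
                          "C_cor_total_left", "C_cor_total_right", "rho")])
  flat <- flat[vapply(flat, is.numeric, logical(1))]
  tibble(parameter = names(flat), value = as.numeric(flat))
}
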