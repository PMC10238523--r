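# Component-level physics: elastance chambers, valve laws, coronary branch
# ODEs, and the packed-parameter representation shared with the compiled
# derivative function in src/c3vm.c.

# normalisation constant of the double-Hill product so that max_t E = E_max
elastance_norm_const <- function(m1, m2, tau1_s, tau2_s, T) {
  h <- function(t) {
    g1 <- (t / tau1_s)^m1
    g2 <- (t / tau2_s)^m2
    (g1 / (1 + g1)) / (1 + g2)
  }
  grid <- seq(0, T, length.out = 2001)
  i <- which.max(h(grid))
  lo <- grid[max(i - 1, 1)]; hi <- grid[min(i + 1, length(grid))]
  opt <- optimize(h, c(lo, hi), maximum = TRUE, tol = 1e-12)
  max(opt$objective, h(grid[i]))
}

#' Time-varying chamber elastance (double-Hill)
#'
#' `E(t) = (E_max - E_min) * [g1/(1+g1)] * [1/(1+g2)] / N + E_min` with
#' `g1 = (t/tau1)^m1`, `g2 = (t/tau2)^m2` and `N` the cycle maximum of the
#' bracketed product, so that the cycle maximum of `E` is exactly `E_max`.
#' Atrial activation is handled through `onset_frac`: the chamber's local
#' time is `(t - onset_frac * T) mod T`.
#'
#' @param t time within the cycle, s (vectorised).
#' @param params chamber parameter list with `E_max`, `E_min`, `m1`, `m2`,
#'   `tau1`, `tau2` (fractions of `T`), `onset_frac` and optionally a
#'   precomputed normalisation `N` (as stored in [build_model_parameters()]
#'   output).
#' @param T cycle duration, s.
#' @return Elastance in mmHg/mL.
#' @export
#' @examples
#' p <- build_model_parameters(
#'   patient_measurements(SBP = 133, DBP = 70.5, HR = 71,
#'                        forward_LVOT_SV = 77.9, EOA_AV = 0.84, EOA_MV = 4,
#'                        A_LVOT = 3.5, A_ascending_aorta = 7,
#'                        EDV = 130, ESV = 52.1),
#'   coronary_anatomy(0.1075, 0.0908, 0.1195))
#' elastance(0, p$lv, p$T)      # = E_min
elastance <- function(t, params, T) {
  tau1 <- params$tau1 * T
  tau2 <- params$tau2 * T
  N <- params$N %||% elastance_norm_const(params$m1, params$m2, tau1, tau2, T)
  onset <- (params$onset_frac %||% 0) * T
  tl <- (t - onset) %% T
  g1 <- (tl / tau1)^params$m1
  g2 <- (tl / tau2)^params$m2
  (params$E_max - params$E_min) * (g1 / (1 + g1)) / (1 + g2) / N + params$E_min
}

#' Chamber pressure from the elastance relation
#'
#' `P = E * (V - V0)`.
#'
#' @param V chamber volume, mL.
#' @param E instantaneous elastance, mmHg/mL.
#' @param V0 unstressed volume, mL.
#' @return Pressure, mmHg.
#' @export
chamber_pressure <- function(V, E, V0) E * (V - V0)

#' Transvalvular pressure gradient (energy-loss law)
#'
#' `dP = [2 pi rho_i / sqrt(ELCo)] dQ/dt + [rho / (2 ELCo^2)] Q |Q|`,
#' evaluated in CGS (`rho` in g/cm^3, `Q` in mL/s, `ELCo` in cm^2) and
#' converted to mmHg. The inertial coefficient defaults to the blood density;
#' the mitral valve uses its dedicated inertance constant instead.
#'
#' @param Q flow, mL/s.
#' @param dQdt flow derivative, mL/s^2.
#' @param ELCo energy-loss coefficient, cm^2.
#' @param rho blood density, kg/m^3.
#' @param inertial_coeff CGS inertial coefficient (g/cm^2-equivalent);
#'   defaults to `rho/1000` (density-based aortic term).
#' @return Pressure gradient, mmHg.
#' @export
#' @examples
#' valve_pressure_gradient(250, 0, ELCo = 1.0)  # ~24.6 mmHg
valve_pressure_gradient <- function(Q, dQdt = 0, ELCo, rho = 1050,
                                    inertial_coeff = NULL) {
  check_that(all(ELCo > 0), "requires ELCo > 0", class = "coroflow_domain_error")
  rho_cgs <- rho / 1000
  ic <- inertial_coeff %||% rho_cgs
  .valve_L(ic, ELCo) * dQdt + .valve_B(ELCo, rho_cgs) * Q * abs(Q)
}

#' Coronary branch state derivatives (three-resistor, two-capacitor circuit)
#'
#' One coronary branch is a chain `P_in -R_p- [P_p, C_p] -R_m- [P_m, C_m]
#' -R_d- P_out`, with the medial capacitor referenced to the intramyocardial
#' pressure source `P_im` (ventricular compression). Flows are
#' `q_in = (P_in - P_p)/R_p`, `q_m = (P_p - P_m)/R_m`,
#' `q_out = (P_m - P_out)/R_d`; the capacitor balances are
#' `dP_p/dt = (q_in - q_m)/C_p` and
#' `dP_m/dt = (q_m - q_out)/C_m + dP_im/dt`.
#'
#' Under constant imposed pressures the steady state is the purely resistive
#' chain `q_in = q_m = q_out = (P_in - P_out)/(R_p + R_m + R_d)`.
#'
#' @param P_in,P_out inlet (aortic root) and outlet (venous) pressures, mmHg.
#' @param P_im intramyocardial pressure, mmHg (`im_pressure_scale * P_LV`).
#' @param dPim_dt time derivative of `P_im`, mmHg/s.
#' @param state numeric vector `c(P_p, P_m)` of node pressures, mmHg.
#' @param params branch parameter list with `R_p`, `R_m`, `R_d`, `C_p`, `C_m`.
#' @return List with `dP_p`, `dP_m`, `q_in`, `q_m`, `q_out`.
#' @export
coronary_branch_derivatives <- function(P_in, P_out, P_im, dPim_dt,
                                        state, params) {
  check_that(params$R_p > 0 && params$R_m > 0 && params$R_d > 0,
             "requires positive branch resistances",
             class = "coroflow_domain_error")
  P_p <- state[[1]]; P_m <- state[[2]]
  q_in <- (P_in - P_p) / params$R_p
  q_m <- (P_p - P_m) / params$R_m
  q_out <- (P_m - P_out) / params$R_d
  list(dP_p = (q_in - q_m) / params$C_p,
       dP_m = (q_m - q_out) / params$C_m + dPim_dt,
       q_in = q_in, q_m = q_m, q_out = q_out)
}

# ---------------------------------------------------------------------------
# Packed parameter vector: the single source of truth for the layout shared
# by the compiled derivatives (src/c3vm.c) and the R reference implementation
# below. Order must match src/c3vm.c exactly.

c3vm_state_names <- c("V_LV", "V_LA", "P_ao_root", "P_SAC", "P_PVC", "P_PA",
                      "Q_AV", "Q_MV", "Q_PC",
                      "P_cor_p_LAD", "P_cor_m_rel_LAD",
                      "P_cor_p_LCX", "P_cor_m_rel_LCX",
                      "P_cor_p_RCA", "P_cor_m_rel_RCA")

c3vm_output_names <- c("P_LV", "P_LA", "E_LV",
                       "q_LAD", "q_LCX", "q_RCA",
                       "q_out_LAD", "q_out_LCX", "q_out_RCA",
                       "q_ub", "q_sys", "q_pa",
                       "q_AR", "q_MR", "q_leak", "q_src")

pack_params <- function(p) {
  stopifnot(inherits(p, "c3vm_params"))
  T <- p$T
  la_onset <- p$la$onset_frac * T
  v <- p$valves
  kAR <- if (is.null(v$ar)) 0 else v$ar$k
  kMR <- if (is.null(v$mr)) 0 else v$mr$k
  Gleak <- if (is.null(v$leak)) 0 else 1 / v$leak$R_leak
  # half-sine pulmonary inflow amplitude so the cycle mean equals Q_MPV
  A_src <- pi * T * p$pulmonary$Q_MPV / (2 * p$T_EJ)
  cb <- function(b) {
    x <- p$coronary[[b]]
    c(x$R_p, x$R_m, x$R_d, x$C_p, x$C_m, x$im_pressure_scale)
  }
  c(
    T, p$T_EJ,
    p$lv$E_max, p$lv$E_min, p$lv$m1, p$lv$m2, p$lv$tau1 * T, p$lv$tau2 * T,
    p$lv$V0, p$lv$N,
    p$la$E_max, p$la$E_min, p$la$m1, p$la$m2, p$la$tau1 * T, p$la$tau2 * T,
    p$la$V0, p$la$N, la_onset,
    v$av$L, v$av$B, v$mv$L, v$mv$B,
    kAR, kMR, Gleak,
    p$systemic$C_ao,
    p$systemic$R_ao + p$systemic$R_pda + p$systemic$R_SA,
    p$systemic$R_ub, p$systemic$R_SV, p$systemic$C_SAC, p$systemic$P_CV0,
    p$pulmonary$C_PVC, p$pulmonary$R_PVC + p$pulmonary$R_PC,
    p$pulmonary$L_PC, p$pulmonary$R_PA, p$pulmonary$C_PA, A_src,
    p$numerics$R_diode, p$numerics$q_eps, p$numerics$delta_reg,
    cb("LAD"), cb("LCX"), cb("RCA")
  )
}

# R reference implementation of the full system derivatives, operating on the
# packed vector. Mirrors src/c3vm.c line for line; used as the oracle in
# cross-checks and available as engine = "r" in integrate_to_periodic().
c3vm_derivs_r <- function(t, y, pv) {
  hill <- function(tl, Emax, Emin, m1, m2, tau1, tau2, N) {
    if (tl <= 0) return(Emin)
    g1 <- (tl / tau1)^m1
    g2 <- (tl / tau2)^m2
    (Emax - Emin) * (g1 / (1 + g1)) / (1 + g2) / N + Emin
  }
  T <- pv[1]; T_EJ <- pv[2]
  E_LV <- hill(t %% T, pv[3], pv[4], pv[5], pv[6], pv[7], pv[8], pv[10])
  tl_la <- (t - pv[19]) %% T
  E_LA <- hill(tl_la, pv[11], pv[12], pv[13], pv[14], pv[15], pv[16], pv[18])
  P_LV <- E_LV * (y[1] - pv[9])
  P_LA <- E_LA * (y[2] - pv[17])
  P_root <- y[3]; P_SAC <- y[4]; P_PVC <- y[5]; P_PA <- y[6]
  Q_AV <- y[7]; Q_MV <- y[8]; Q_PC <- y[9]

  R_bk <- pv[39]; q_eps <- pv[40]; delta <- pv[41]
  # reverse block engages only for reverse flow under an unfavorable gradient
  sig <- function(q, dp) {
    1 / (1 + exp(pmin(q / q_eps, 700))) / (1 + exp(pmin(dp / 0.1, 700)))
  }
  dQ_AV <- (P_LV - P_root - pv[21] * Q_AV * abs(Q_AV) -
              R_bk * sig(Q_AV, P_LV - P_root) * Q_AV) / pv[20]
  dQ_MV <- (P_LA - P_LV - pv[23] * Q_MV * abs(Q_MV) -
              R_bk * sig(Q_MV, P_LA - P_LV) * Q_MV) / pv[22]

  regflow <- function(k, dp) if (k > 0) k * pos(dp) / sqrt(abs(dp) + delta) else 0
  q_AR <- regflow(pv[24], P_root - P_LV)
  q_MR <- regflow(pv[25], P_LV - P_LA)
  q_leak <- pv[26] * (P_root - P_LV)

  q_sys <- (P_root - P_SAC) / pv[28]
  q_ub <- (P_root - pv[32]) / pv[29]

  q_src <- if (t %% T < T_EJ) pv[38] * sin(pi * (t %% T) / T_EJ) else 0
  dP_PVC <- (q_src - Q_PC) / pv[33]
  dQ_PC <- (P_PVC - P_PA - pv[34] * Q_PC) / pv[35]
  q_pa <- (P_PA - P_LA) / pv[36]
  dP_PA <- (Q_PC - q_pa) / pv[37]

  q_in <- q_out <- numeric(3)
  dcor <- numeric(6)
  for (j in 1:3) {
    o <- 42 + (j - 1) * 6
    R_p <- pv[o]; R_m <- pv[o + 1]; R_d <- pv[o + 2]
    C_p <- pv[o + 3]; C_m <- pv[o + 4]; s <- pv[o + 5]
    P_p <- y[10 + (j - 1) * 2]; w <- y[11 + (j - 1) * 2]
    P_im <- s * P_LV
    P_m <- w + P_im
    q_in[j] <- (P_root - P_p) / R_p
    q_m <- (P_p - P_m) / R_m
    q_out[j] <- (P_m - pv[32]) / R_d
    dcor[(j - 1) * 2 + 1] <- (q_in[j] - q_m) / C_p
    dcor[(j - 1) * 2 + 2] <- (q_m - q_out[j]) / C_m
  }

  dV_LV <- Q_MV + q_AR + q_leak - Q_AV - q_MR
  dV_LA <- q_pa + q_MR - Q_MV
  dP_root <- (Q_AV - q_sys - q_ub - q_AR - q_leak - sum(q_in)) / pv[27]
  dP_SAC <- (q_sys - (P_SAC - pv[32]) / pv[30]) / pv[31]

  list(c(dV_LV, dV_LA, dP_root, dP_SAC, dP_PVC, dP_PA,
         dQ_AV, dQ_MV, dQ_PC, dcor),
       c(P_LV, P_LA, E_LV, q_in, q_out, q_ub, q_sys, q_pa,
         q_AR, q_MR, q_leak, q_src))
}
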