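# Global and per-branch coronary hemodynamic metrics.

#' Left-ventricular stroke work from the PV loop
#'
#' Signed shoelace area of the pressure--volume loop over one periodic cycle,
#' converted to joules (1 mmHg mL = 1.33322e-4 J). Positive for the
#' physiological counterclockwise loop; traversing the loop in reverse flips
#' the sign.
#'
#' @param waves a `c3vm_waveforms` cycle (or any data frame with `P_LV` and
#'   `V_LV` columns sampling a closed loop).
#' @return Work in J.
#' @export
lv_workload <- function(waves) {
  P <- waves$P_LV; V <- waves$V_LV
  n <- length(P)
  # periodic input: the loop must close
  closure <- abs(V[n] - V[1]) + abs(P[n] - P[1]) / 10
  scale <- max(diff(range(V)), 1e-9)
  check_that(closure <= 0.05 * scale,
             "open PV loop: input does not sample one periodic cycle",
             class = "coroflow_domain_error")
  # shoelace on the closed polygon (drop the duplicated endpoint); the
  # physiological fill-eject cycle is counterclockwise in the (V, P) plane,
  # giving a positive signed area
  P <- P[-n]; V <- V[-n]
  area <- 0.5 * sum(V * (c(P[-1], P[1])) - c(V[-1], V[1]) * P)
  area * JOULE_PER_MMHG_ML
}

# index mask of the systolic window [t_open, t_open + T_EJ) on the cycle grid,
# wrapping around the cycle end
systole_mask <- function(waves, T_EJ) {
  T <- attr(waves, "T") %||% max(waves$time)
  check_that(T_EJ < T, "requires T_EJ < T", class = "coroflow_domain_error")
  qa <- waves$Q_AV
  thr <- max(1, 0.02 * max(qa))
  i_open <- which(qa > thr)[1]
  if (is.na(i_open)) i_open <- 1       # no ejection: fall back to cycle start
  t_open <- waves$time[i_open]
  dt <- (waves$time - t_open) %% T
  dt < T_EJ
}

#' Per-branch coronary flow metrics by cardiac phase
#'
#' Splits the cycle into systole (aortic-valve opening to opening + `T_EJ`)
#' and diastole (remainder) and reports, per branch, the full-cycle mean and
#' phase means/peaks of the proximal branch flow, plus the total coronary
#' flow and (when `LV_mass` is given) the myocardial blood flow.
#'
#' @param waves a `c3vm_waveforms` cycle.
#' @param T_EJ systolic ejection time, s (defaults to the value stored on
#'   `waves`).
#' @param LV_mass LV mass in g, for the mL/min/g normalisation (optional).
#' @return Object of class `c3vm_coronary`: a tibble with one row per branch
#'   (`mean_flow`, `mean_systolic`, `mean_diastolic`, `peak_systolic`,
#'   `peak_diastolic`, all mL/s) and attributes `total_flow_ml_min` and
#'   `mbf_ml_min_g`.
#' @export
coronary_phase_metrics <- function(waves, T_EJ = NULL, LV_mass = NA_real_) {
  T_EJ <- T_EJ %||% attr(waves, "T_EJ")
  T <- attr(waves, "T") %||% max(waves$time)
  sys <- systole_mask(waves, T_EJ)
  t <- waves$time
  # duration-weighted means on the (possibly wrapped) phase windows; the
  # uniform grid makes simple phase averages duration-consistent. Drop the
  # duplicated endpoint so each phase sample carries equal weight.
  keep <- seq_len(nrow(waves) - 1)
  out <- purrr::map_dfr(c("LAD", "LCX", "RCA"), function(b) {
    q <- waves[[paste0("q_", b)]]
    full <- trapz(t, q) / T
    s <- sys[keep]; qk <- q[keep]
    tibble(
      branch = b,
      mean_flow = full,
      mean_systolic = mean(qk[s]),
      mean_diastolic = mean(qk[!s]),
      peak_systolic = max(qk[s]),
      peak_diastolic = max(qk[!s])
    )
  })
  class(out) <- c("c3vm_coronary", class(out))
  attr(out, "frac_systole") <- mean(sys[keep])
  total <- sum(out$mean_flow) * 60
  attr(out, "total_flow_ml_min") <- total
  attr(out, "mbf_ml_min_g") <- if (is.na(LV_mass)) NA_real_ else total / LV_mass
  out
}

#' Global hemodynamic metrics from a converged cycle
#'
#' @param sim a `c3vm_sim` object, or a `c3vm_waveforms` cycle together with
#'   `meas`.
#' @param meas the measurement row (needed only when passing raw waveforms).
#' @return One-row tibble: LV workload (J), max LV pressure (mmHg), model MAP
#'   (time-average aortic-root pressure, mmHg), cardiac output (mL/min),
#'   model SBP/DBP (mmHg), mean transvalvular AV gradient over ejection
#'   (mmHg), a Doppler-style mean gradient proxy (`4 v^2` on the continuity
#'   velocity, mmHg), max AV velocity proxy (m/s) and heart rate.
#' @export
global_hemodynamics <- function(sim, meas = NULL) {
  if (inherits(sim, "c3vm_sim")) {
    waves <- sim$waveforms
    meas <- sim$measurements
  } else {
    waves <- sim
    check_that(!is.null(meas), "meas required when passing waveforms")
  }
  T <- attr(waves, "T")
  t <- waves$time
  SV <- forward_av_volume(waves)
  ej <- waves$Q_AV > max(1, 0.02 * max(waves$Q_AV))
  dp_av <- waves$P_LV - waves$P_ao_root
  v_av <- waves$Q_AV / (100 * meas$EOA_AV)       # m/s by continuity
  tibble(
    label = meas$label, phase_tag = meas$phase_tag,
    LV_workload_J = lv_workload(waves),
    max_P_LV = max(waves$P_LV),
    MAP_model = trapz(t, waves$P_ao_root) / T,
    CO_ml_min = SV * meas$HR,
    SBP_model = max(waves$P_ao_root),
    DBP_model = min(waves$P_ao_root),
    mean_AV_gradient = if (any(ej)) mean(dp_av[ej]) else 0,
    mean_AV_gradient_doppler = if (any(ej)) mean(4 * v_av[ej]^2) else 0,
    max_AV_velocity_proxy = max(waves$Q_AV) / (100 * meas$EOA_AV),
    HR = meas$HR
  )
}

#' Full hemodynamic report for one simulated patient
#'
#' @param sim a `c3vm_sim` object.
#' @return Object of class `c3vm_report`: list with `global` (one-row tibble,
#'   see [global_hemodynamics()]) and `coronary` (per-branch tibble, see
#'   [coronary_phase_metrics()]).
#' @export
hemodynamic_report <- function(sim) {
  stopifnot(inherits(sim, "c3vm_sim"))
  structure(list(
    global = global_hemodynamics(sim),
    coronary = coronary_phase_metrics(sim$waveforms,
                                      T_EJ = sim$measurements$T_EJ,
                                      LV_mass = sim$measurements$LV_mass)
  ), class = "c3vm_report")
}

#' @export
print.c3vm_report <- function(x, ...) {
  g <- x$global
  cat(sprintf("<c3vm_report> %s (%s)\n", g$label, g$phase_tag))
  cat(sprintf("  LV workload %.2f J | max P_LV %.0f mmHg | MAP %.0f | CO %.0f mL/min\n",
              g$LV_workload_J, g$max_P_LV, g$MAP_model, g$CO_ml_min))
  cat(sprintf("  AV: mean gradient %.1f mmHg, vmax proxy %.2f m/s\n",
              g$mean_AV_gradient, g$max_AV_velocity_proxy))
  print(as_tibble(x$coronary))
  invisible(x)
}

#' Pre/post intervention comparison
#'
#' Percent change per metric, `(post - pre)/pre * 100` (absolute delta when
#' the pre value is 0), plus the coronary-response classification of the
#' patient: all three branch mean flows increased, all decreased, or mixed.
#'
#' @param pre,post `c3vm_report` objects for the same patient label.
#' @return Tibble with `metric`, `pre`, `post`, `delta`, `delta_type`
#'   (`"percent"` or `"absolute"`); attribute `classification`.
#' @export
compare_pre_post <- function(pre, post) {
  stopifnot(inherits(pre, "c3vm_report"), inherits(post, "c3vm_report"))
  check_that(identical(pre$global$label, post$global$label),
             "pre/post labels do not match", class = "coroflow_domain_error")
  gp <- pre$global; gq <- post$global
  num <- vapply(gp, is.numeric, logical(1))
  rows <- purrr::map_dfr(names(gp)[num], function(nm) {
    a <- gp[[nm]]; b <- gq[[nm]]
    if (abs(a) > 0) {
      tibble(metric = nm, pre = a, post = b,
             delta = (b - a) / a * 100, delta_type = "percent")
    } else {
      tibble(metric = nm, pre = a, post = b, delta = b - a,
             delta_type = "absolute")
    }
  })
  cor_rows <- purrr::map_dfr(seq_len(nrow(pre$coronary)), function(i) {
    a <- pre$coronary$mean_flow[i]; b <- post$coronary$mean_flow[i]
    tibble(metric = paste0("mean_flow_", pre$coronary$branch[i]),
           pre = a, post = b,
           delta = if (abs(a) > 0) (b - a) / a * 100 else b - a,
           delta_type = if (abs(a) > 0) "percent" else "absolute")
  })
  out <- bind_rows(rows, cor_rows)
  d <- post$coronary$mean_flow - pre$coronary$mean_flow
  attr(out, "classification") <- if (all(d > 0)) "all-branches-increase"
    else if (all(d < 0)) "all-branches-decrease" else "mixed"
  out
}
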