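# broom-style tidiers and ggplot2 autoplot methods.

#' Tidy a waveform cycle into long format
#'
#' @param x a `c3vm_waveforms` tibble.
#' @param signals optional character vector restricting which columns to keep.
#' @param ... unused.
#' @return Long tibble with `time_s`, `signal`, `value`, `units`.
#' @export
tidy.c3vm_waveforms <- function(x, signals = NULL, ...) {
  unit_of <- function(s) {
    if (grepl("^(P_|E_)", s)) {
      if (startsWith(s, "E_")) "mmHg/mL" else "mmHg"
    } else if (grepl("^(q_|Q_)", s)) "mL/s" else if (grepl("^V_", s)) "mL"
    else "1"
  }
  cols <- setdiff(names(x), "time")
  if (!is.null(signals)) cols <- intersect(cols, signals)
  out <- tidyr::pivot_longer(as_tibble(x)[, c("time", cols)],
                             -"time", names_to = "signal",
                             values_to = "value")
  out$units <- vapply(out$signal, unit_of, character(1))
  names(out)[names(out) == "time"] <- "time_s"
  out
}

#' @rdname tidy.c3vm_waveforms
#' @export
tidy.c3vm_sim <- function(x, signals = NULL, ...) {
  tidy.c3vm_waveforms(x$waveforms, signals = signals, ...)
}

#' One-row summary of a simulated patient
#'
#' @param x a `c3vm_sim` object.
#' @param ... unused.
#' @return The [global_hemodynamics()] row augmented with the total coronary
#'   flow, its fraction of cardiac output, and convergence/tuning metadata.
#' @export
glance.c3vm_sim <- function(x, ...) {
  g <- global_hemodynamics(x)
  cor <- coronary_phase_metrics(x$waveforms, T_EJ = x$measurements$T_EJ,
                                LV_mass = x$measurements$LV_mass)
  g$total_coronary_flow_ml_min <- attr(cor, "total_flow_ml_min")
  g$coronary_flow_fraction <- attr(cor, "total_flow_ml_min") / g$CO_ml_min
  g$mbf_ml_min_g <- attr(cor, "mbf_ml_min_g")
  g$n_cycles_run <- attr(x$waveforms, "n_cycles_run")
  g$convergence_residual <- attr(x$waveforms, "convergence_residual")
  g
}

#' Waveform overview plot
#'
#' Chamber/root pressures, valve flows and the three coronary branch flows
#' over one converged cycle.
#'
#' @param object a `c3vm_sim` object.
#' @param ... unused.
#' @return A ggplot object (facetted by signal group).
#' @export
autoplot.c3vm_sim <- function(object, ...) {
  long <- tidy(object, signals = c("P_LV", "P_LA", "P_ao_root",
                                   "Q_AV", "Q_MV",
                                   "q_LAD", "q_LCX", "q_RCA"))
  long$panel <- dplyr::case_when(
    long$signal %in% c("P_LV", "P_LA", "P_ao_root") ~ "pressure [mmHg]",
    long$signal %in% c("Q_AV", "Q_MV") ~ "valve flow [mL/s]",
    TRUE ~ "coronary flow [mL/s]"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_s, y = .data$value,
                                     colour = .data$signal)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~panel, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "time [s]", y = NULL,
                  title = sprintf("%s (%s)", object$measurements$label,
                                  object$measurements$phase_tag)) +
    ggplot2::theme_minimal()
}

#' Pressure--volume loop plot
#'
#' @param sim a `c3vm_sim` object.
#' @return A ggplot object of the LV PV loop.
#' @export
plot_pv_loop <- function(sim) {
  w <- sim$waveforms
  ggplot2::ggplot(tibble(V = w$V_LV, P = w$P_LV),
                  ggplot2::aes(x = .data$V, y = .data$P)) +
    ggplot2::geom_path() +
    ggplot2::labs(x = "LV volume [mL]", y = "LV pressure [mmHg]",
                  title = sprintf("stroke work %.2f J", lv_workload(w))) +
    ggplot2::theme_minimal()
}

#' Sensitivity bar chart
#'
#' @param object a `c3vm_sensitivity` tibble from [run_sensitivity()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.c3vm_sensitivity <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object),
                              dplyr::all_of(c("err_LAD", "err_LCX", "err_RCA")),
                              names_to = "branch", values_to = "error_pct")
  long$branch <- sub("err_", "", long$branch)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$parameter, y = .data$error_pct,
                                     fill = .data$branch)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "max relative error in mean flow [%]") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
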