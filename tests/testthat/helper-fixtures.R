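# Shared fixtures. Everything is generated in code; the cohort-mean patient
# is the reference severe-AS case used across files, and its (expensive)
# tuned simulation is computed once per test run and cached.

table2_means_patient <- function(EOA_AV = 0.84) {
  patient_measurements(
    label = "cohort-mean", phase_tag = if (EOA_AV > 1) "post" else "pre",
    SBP = 133.0, DBP = 70.5, HR = 71,
    forward_LVOT_SV = 77.87, EOA_AV = EOA_AV, EOA_MV = 4.0,
    A_LVOT = 3.5, A_ascending_aorta = 7.0,
    EDV = 130, ESV = 130 - 77.87, LV_mass = 160
  )
}

default_anatomy <- function() {
  coronary_anatomy(A_LAD = pi * (0.37 / 2)^2,
                   A_LCX = pi * (0.34 / 2)^2,
                   A_RCA = pi * (0.39 / 2)^2)
}

.sim_cache <- new.env(parent = emptyenv())

# tuned simulation of the cohort-mean severe-AS patient (cached)
baseline_sim <- function() {
  if (is.null(.sim_cache$pre)) {
    .sim_cache$pre <- simulate_patient(table2_means_patient(), default_anatomy())
  }
  .sim_cache$pre
}

# same patient with the valve opened to a prosthesis-scale EOA (cached)
post_sim <- function() {
  if (is.null(.sim_cache$post)) {
    .sim_cache$post <- simulate_patient(table2_means_patient(EOA_AV = 1.7),
                                        default_anatomy())
  }
  .sim_cache$post
}

# full sensitivity table of the cohort-mean patient (cached)
mean_patient_sensitivity <- function() {
  if (is.null(.sim_cache$sens)) {
    .sim_cache$sens <- run_sensitivity(sim = baseline_sim(),
                                       meas = table2_means_patient())
  }
  .sim_cache$sens
}
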