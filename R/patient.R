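#' Canonical patient measurement set
#'
#' Builds a validated one-row tibble of the non-invasive measurements the
#' model needs for one patient at one time point (pre- or post-intervention).
#' Canonical units are mmHg (pressures), mL (volumes), s (times) and cm^2
#' (areas); conversions from config files are handled by
#' [read_patient_config()].
#'
#' `T` defaults to `60/HR`; when both are supplied they must agree within 1%.
#' `T_EJ` defaults to the classic systolic-ejection scaling `0.3 * sqrt(T)`.
#' Regurgitant orifice areas and the paravalvular leak volume default to 0
#' (absent paths).
#'
#' @param label patient identifier.
#' @param phase_tag `"pre"` or `"post"`.
#' @param SBP,DBP brachial systolic/diastolic pressure, mmHg.
#' @param HR heart rate, beats/min.
#' @param T cardiac cycle duration, s (default `60/HR`).
#' @param T_EJ systolic ejection time, s (default `0.3 * sqrt(T)`).
#' @param forward_LVOT_SV forward LVOT stroke volume, mL.
#' @param EOA_AV,EOA_MV effective orifice areas of the aortic and mitral
#'   valves, cm^2.
#' @param A_LVOT,A_ascending_aorta LVOT and ascending-aorta cross-sectional
#'   areas, cm^2.
#' @param EOA_AR,EOA_MR regurgitant effective orifice areas, cm^2 (0 if none).
#' @param V_leak paravalvular leak volume per cycle, mL (0 if none).
#' @param EDV,ESV end-diastolic / end-systolic LV volume, mL.
#' @param LV_mass LV mass, g; optional, only used for the myocardial
#'   blood-flow metric.
#' @return A one-row tibble of class `c3vm_patient`.
#' @seealso [coronary_anatomy()], [read_patient_config()]
#' @export
#' @examples
#' patient_measurements(SBP = 133, DBP = 70.5, HR = 71,
#'                      forward_LVOT_SV = 77.9, EOA_AV = 0.84, EOA_MV = 4,
#'                      A_LVOT = 3.5, A_ascending_aorta = 7,
#'                      EDV = 130, ESV = 52.1)
patient_measurements <- function(label = "patient", phase_tag = "pre",
                                 SBP, DBP, HR, T = NULL, T_EJ = NULL,
                                 forward_LVOT_SV, EOA_AV, EOA_MV,
                                 A_LVOT, A_ascending_aorta,
                                 EOA_AR = 0, EOA_MR = 0, V_leak = 0,
                                 EDV, ESV, LV_mass = NA_real_) {
  if (is.null(T)) T <- 60 / HR
  if (is.null(T_EJ)) T_EJ <- 0.3 * sqrt(T)
  out <- tibble(
    label = as.character(label), phase_tag = as.character(phase_tag),
    SBP = SBP, DBP = DBP, HR = HR, T = T, T_EJ = T_EJ,
    forward_LVOT_SV = forward_LVOT_SV,
    EOA_AV = EOA_AV, EOA_MV = EOA_MV,
    A_LVOT = A_LVOT, A_ascending_aorta = A_ascending_aorta,
    EOA_AR = EOA_AR, EOA_MR = EOA_MR, V_leak = V_leak,
    EDV = EDV, ESV = ESV, LV_mass = LV_mass
  )
  class(out) <- c("c3vm_patient", class(out))
  validate_patient_measurements(out)
  out
}

#' Validate a patient measurement row
#'
#' Checks the physiological invariants of a measurement set and raises a
#' classed `coroflow_validation_error` naming the violated rule.
#'
#' @param meas one-row data frame as produced by [patient_measurements()].
#' @return `meas`, invisibly, when valid.
#' @export
validate_patient_measurements <- function(meas) {
  req <- c("SBP", "DBP", "HR", "T", "T_EJ", "forward_LVOT_SV", "EOA_AV",
           "EOA_MV", "A_LVOT", "A_ascending_aorta", "EOA_AR", "EOA_MR",
           "V_leak", "EDV", "ESV")
  miss <- setdiff(req, names(meas))
  check_that(length(miss) == 0,
             sprintf("schema error: missing required field(s): %s",
                     paste(miss, collapse = ", ")),
             class = "coroflow_schema_error")
  m <- as.list(meas[1, ])
  check_that(m$DBP > 0 && m$SBP > m$DBP, "invariant violated: SBP > DBP > 0")
  check_that(m$HR > 0, "invariant violated: HR > 0")
  check_that(abs(m$T - 60 / m$HR) <= 0.01 * (60 / m$HR),
             "invariant violated: T must equal 60/HR within 1%")
  check_that(m$T_EJ > 0 && m$T_EJ < m$T, "invariant violated: 0 < T_EJ < T")
  check_that(m$ESV > 0 && m$EDV > m$ESV, "invariant violated: 0 < ESV < EDV")
  check_that(m$forward_LVOT_SV > 0, "invariant violated: forward_LVOT_SV > 0")
  for (a in c("EOA_AV", "EOA_MV", "A_LVOT", "A_ascending_aorta")) {
    check_that(m[[a]] > 0, sprintf("invariant violated: %s > 0", a))
  }
  check_that(m$EOA_AV < m$A_ascending_aorta,
             "invariant violated: EOA_AV < A_ascending_aorta")
  for (a in c("EOA_AR", "EOA_MR", "V_leak")) {
    check_that(m[[a]] >= 0, sprintf("invariant violated: %s >= 0", a))
  }
  if (m$EOA_AR > 0) {
    check_that(m$EOA_AR < m$A_LVOT, "invariant violated: EOA_AR < A_LVOT")
  }
  invisible(meas)
}

#' Proximal coronary anatomy
#'
#' Cross-sectional areas (cm^2) of the three modelled coronary branches, with
#' optional stenotic areas. A stenotic area equal to the branch area means no
#' stenosis.
#'
#' @param A_LAD,A_LCX,A_RCA proximal branch cross-sectional areas, cm^2.
#' @param A_sten_LAD,A_sten_LCX,A_sten_RCA stenotic cross-sectional areas,
#'   cm^2; default to the branch areas (no stenosis).
#' @return One-row tibble of class `c3vm_anatomy`.
#' @export
#' @examples
#' coronary_anatomy(0.1075, 0.0908, 0.1195)
coronary_anatomy <- function(A_LAD, A_LCX, A_RCA,
                             A_sten_LAD = A_LAD, A_sten_LCX = A_LCX,
                             A_sten_RCA = A_RCA) {
  out <- tibble(A_LAD = A_LAD, A_LCX = A_LCX, A_RCA = A_RCA,
                A_sten_LAD = A_sten_LAD, A_sten_LCX = A_sten_LCX,
                A_sten_RCA = A_sten_RCA)
  class(out) <- c("c3vm_anatomy", class(out))
  validate_coronary_anatomy(out)
  out
}

#' @rdname coronary_anatomy
#' @param anatomy one-row data frame with the anatomy fields.
#' @export
validate_coronary_anatomy <- function(anatomy) {
  req <- c("A_LAD", "A_LCX", "A_RCA")
  miss <- setdiff(req, names(anatomy))
  check_that(length(miss) == 0,
             sprintf("schema error: missing required field(s): %s",
                     paste(miss, collapse = ", ")),
             class = "coroflow_schema_error")
  a <- as.list(anatomy[1, ])
  for (b in c("LAD", "LCX", "RCA")) {
    A <- a[[paste0("A_", b)]]
    As <- a[[paste0("A_sten_", b)]] %||% A
    check_that(A > 0, sprintf("invariant violated: A_%s > 0", b))
    check_that(As > 0 && As <= A,
               sprintf("invariant violated: 0 < A_sten_%s <= A_%s", b, b))
  }
  invisible(anatomy)
}

# unit conversion factors to the canonical system, keyed by declared unit
.unit_to_canonical <- list(
  mmHg = 1, kPa = 7.50062,
  mL = 1, ml = 1, L = 1000,
  s = 1, ms = 1e-3,
  `cm2` = 1, `cm^2` = 1, `mm2` = 0.01, `mm^2` = 0.01,
  `mL/s` = 1, `L/min` = 1000 / 60,
  g = 1, bpm = 1, `beats/min` = 1
)

.canonical_units <- c(
  SBP = "mmHg", DBP = "mmHg", HR = "bpm", T = "s", T_EJ = "s",
  forward_LVOT_SV = "mL", EOA_AV = "cm2", EOA_MV = "cm2", A_LVOT = "cm2",
  A_ascending_aorta = "cm2", EOA_AR = "cm2", EOA_MR = "cm2", V_leak = "mL",
  EDV = "mL", ESV = "mL", LV_mass = "g",
  A_LAD = "cm2", A_LCX = "cm2", A_RCA = "cm2",
  A_sten_LAD = "cm2", A_sten_LCX = "cm2", A_sten_RCA = "cm2"
)

# dimension class of each canonical unit, used to reject cross-dimension
# declarations such as SBP in mL
.unit_dimension <- c(
  mmHg = "pressure", kPa = "pressure",
  mL = "volume", ml = "volume", L = "volume",
  s = "time", ms = "time",
  cm2 = "area", `cm^2` = "area", mm2 = "area", `mm^2` = "area",
  `mL/s` = "flow", `L/min` = "flow",
  g = "mass", bpm = "rate", `beats/min` = "rate"
)

#' Read a patient configuration file
#'
#' Reads a JSON or YAML config whose keys match the
#' [patient_measurements()] and [coronary_anatomy()] field names, normalises
#' units to the canonical system (mmHg, mL, s, cm^2) and returns validated
#' objects. An optional `units` block may declare, per field, either the
#' canonical unit or a convertible one (`kPa` -> mmHg, `L/min` -> mL/s,
#' `mm^2` -> cm^2, `ms` -> s).
#'
#' @param path path to a `.json`, `.yaml` or `.yml` file.
#' @return A list with elements `measurements` (`c3vm_patient`) and
#'   `anatomy` (`c3vm_anatomy`).
#' @export
read_patient_config <- function(path) {
  check_that(file.exists(path), sprintf("config file not found: %s", path),
             class = "coroflow_schema_error")
  cfg <- if (grepl("\\.(ya?ml)$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  units <- cfg$units
  cfg$units <- NULL

  convert <- function(field, value) {
    if (is.null(units[[field]])) return(value)
    u <- units[[field]]
    fac <- .unit_to_canonical[[u]]
    check_that(!is.null(fac), sprintf("unknown unit '%s' for field %s", u, field),
               class = "coroflow_schema_error")
    canon <- .canonical_units[[field]]
    check_that(!is.null(canon) &&
                 identical(.unit_dimension[[u]], .unit_dimension[[canon]]),
               sprintf("unit '%s' is not convertible to %s for field %s",
                       u, canon %||% "?", field),
               class = "coroflow_schema_error")
    value * fac
  }
  cfg <- purrr::imap(cfg, function(v, k) if (is.numeric(v)) convert(k, v) else v)

  anat_fields <- c("A_LAD", "A_LCX", "A_RCA",
                   "A_sten_LAD", "A_sten_LCX", "A_sten_RCA")
  miss_anat <- setdiff(c("A_LAD", "A_LCX", "A_RCA"), names(cfg))
  check_that(length(miss_anat) == 0,
             sprintf("schema error: missing required field(s): %s",
                     paste(miss_anat, collapse = ", ")),
             class = "coroflow_schema_error")
  anatomy <- do.call(coronary_anatomy, cfg[intersect(anat_fields, names(cfg))])

  meas_args <- cfg[setdiff(names(cfg), anat_fields)]
  known <- c("label", "phase_tag", names(.canonical_units))
  meas_args <- meas_args[intersect(names(meas_args), known)]
  for (f in c("SBP", "DBP", "HR", "forward_LVOT_SV", "EOA_AV", "EOA_MV",
              "A_LVOT", "A_ascending_aorta", "EDV", "ESV")) {
    check_that(f %in% names(meas_args),
               sprintf("schema error: missing required field(s): %s", f),
               class = "coroflow_schema_error")
  }
  meas <- do.call(patient_measurements, meas_args)
  list(measurements = meas, anatomy = anatomy)
}

#' Write a patient configuration file
#'
#' Inverse of [read_patient_config()]: serialises a measurement row and
#' anatomy row to JSON (canonical units, with an explicit `units` block).
#'
#' @param meas one-row `c3vm_patient`.
#' @param anatomy one-row `c3vm_anatomy`.
#' @param path output path (`.json`).
#' @return `path`, invisibly.
#' @export
write_patient_config <- function(meas, anatomy, path) {
  lst <- c(as.list(meas[1, ]), as.list(anatomy[1, ]))
  lst <- lst[!vapply(lst, function(x) is.na(x) && !is.character(x), logical(1))]
  lst$units <- as.list(.canonical_units[intersect(names(.canonical_units), names(lst))])
  jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
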