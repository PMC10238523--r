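# Internal helpers and physical constants.

# 1 mmHg = 1333.22 dyn/cm^2
DYN_PER_MMHG <- 1333.22
# 1 mmHg mL = 1.33322e-4 J
JOULE_PER_MMHG_ML <- 1.33322e-4

# trapezoidal integral of y(x) on an ordered grid
trapz <- function(x, y) {
  n <- length(x)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n]) / 2)
}

pos <- function(x) pmax(x, 0)

# One draw from a normal truncated to [lower, upper] via inverse-CDF so that
# the draw consumes exactly one uniform from the current RNG stream.
# sd = 0 degenerates to the mean (checked against the bounds).
rtnorm1 <- function(mean, sd, lower = -Inf, upper = Inf) {
  if (sd < 0) abort("rtnorm1: sd must be >= 0", class = "coroflow_generation_error")
  if (sd == 0) {
    if (mean < lower || mean > upper) {
      abort(sprintf("infeasible truncation: mean %.3g outside [%.3g, %.3g] with sd = 0",
                    mean, lower, upper),
            class = "coroflow_generation_error")
    }
    runif(1) # keep the stream position identical to the sd > 0 path
    return(mean)
  }
  plo <- pnorm(lower, mean, sd)
  phi <- pnorm(upper, mean, sd)
  if (phi - plo < 1e-12) {
    abort(sprintf("infeasible truncation: [%.3g, %.3g] has ~zero mass under N(%.3g, %.3g)",
                  lower, upper, mean, sd),
          class = "coroflow_generation_error")
  }
  qnorm(runif(1, plo, phi), mean, sd)
}

# numbered checks raise classed conditions so callers/tests can be specific
check_that <- function(ok, msg, class = "coroflow_validation_error") {
  if (!isTRUE(ok)) abort(msg, class = class)
  invisible(TRUE)
}
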