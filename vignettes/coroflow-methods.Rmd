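---
title: "Methods: a closed-loop lumped-parameter model of coronary and global hemodynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a closed-loop lumped-parameter model of coronary and global hemodynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Aortic stenosis raises the transvalvular pressure gradient and the left
ventricle's workload, and reshapes coronary perfusion: elevated ventricular
pressure compresses the intramural coronary vessels in systole, so most
coronary flow is delivered in diastole. Valve replacement changes all of
these at once, and the direction of the coronary response is patient
specific. Measuring coronary flow non-invasively is hard; a calibrated
lumped-parameter (0D) circuit driven entirely by routine non-invasive
measurements (Doppler echocardiography, CT coronary cross-sections, cuff
pressure) offers mean and phase-resolved coronary flow estimates in seconds
of compute per patient.

`coroflow` implements such a circuit end to end: patient measurements in,
tuned periodic waveforms and hemodynamic metric tables out.

## Circuit model

The closed loop contains, in order:

* **Left atrium and left ventricle** as time-varying elastance chambers,
  `P = E(t) (V - V0)`. `E(t)` is the normalised double-Hill product
  `E(t) = (Emax - Emin) [g1/(1+g1)] [1/(1+g2)] / N + Emin` with
  `g1 = (t/tau1)^m1`, `g2 = (t/tau2)^m2`; `N` is the cycle maximum of the
  bracketed product, computed numerically (2001-point grid plus a local
  `optimize()` refinement), so `max E = Emax` exactly. LV parameters:
  `Emax = 2.1`, `Emin = 0.06` mmHg/mL, `m1 = 1.32`, `m2 = 27.4`,
  `tau1 = 0.269 T`, `tau2 = 0.452 T`. LA: `0.17`, `0.06`, `1.32`, `13.1`,
  `0.110 T`, `0.18 T`. Atrial activation is phase-shifted so its onset sits
  at `t = T - tau1,LA T` — the atrial kick peaks at the end-diastolic cycle
  boundary, immediately before ventricular activation. The exact functional
  form and atrial timing are design choices of this package: the parameter
  names and values constrain, but do not fix, the waveform family.
* **Valves** with an energy-loss pressure drop evaluated in CGS and
  converted to mmHg:
  `dP = [2 pi rho_i / sqrt(ELCo)] dQ/dt + [rho / (2 ELCo^2)] Q |Q|`,
  `ELCo = EOA * A / (A - EOA)`. The aortic valve uses the ascending-aorta
  area as `A` and the blood density as inertial coefficient; the mitral
  valve uses its dedicated inertance constant `M_MV = 0.53 g/cm^2` and, as
  this package's choice, the infinite-reference-area limit `ELCo = EOA` (no
  pressure-recovery correction for the mitral inflow). Aortic and mitral
  flows are inductor states with a smooth diode: a reverse resistance
  `R_bk = 1000 mmHg s/mL` blended in only when the flow is reverse *and*
  the gradient unfavorable (logistic blending over 0.25 mL/s in flow and a
  0.1 mmHg gradient window). Residual reverse leakage is below 0.1 mL/s
  (~0.05 mL per cycle), and a favorable gradient can always open the valve
  from zero flow. Hard switches would break a variable-step stiff solver;
  this blending keeps the right-hand side C1-continuous in practice.
* **Optional regurgitant paths** (aortic, mitral) using the same orifice
  law quasi-steadily in the reverse direction,
  `q = ELCo sqrt(2 dP / rho)` (smoothed near zero gradient over 0.1 mmHg),
  and an optional **paravalvular leak**: a constant-resistance path in
  parallel with the aortic valve whose resistance is tuned so the per-cycle
  retrograde volume equals the measured `V_leak`.
* **Systemic circulation**: aortic-root capacitor `C_ao` (the node where
  the coronary inlets and the upper-body branch `R_ub` attach), series
  resistance `R_ao + R_pda + R_SA` to the systemic arteries/veins capacitor
  `C_SAC`, then `R_SV` into the constant central venous pressure
  `P_CV0 = 4 mmHg`.
* **Pulmonary circulation**: an imposed pulmonary-valve inflow — a
  half-sine of duration `T_EJ` per cycle scaled so its cycle mean is the
  tunable `Q_MPV` (only the mean is a specified parameter) — feeding
  `C_PVC`, then `R_PVC + R_PC` with inertance `L_PC` into `C_PA`, then
  `R_PA` into the left atrium. `L_PV`/`R_PV` sit in series with the ideal
  flow source and therefore cannot influence the downstream dynamics; they
  are retained as parameters for completeness.
* **Three coronary branches** (LAD, LCX, RCA), each a
  `R_p - [C_p] - R_m - [C_m] - R_d` chain from the aortic root to `P_CV0`,
  with the medial capacitor referenced to an intramyocardial pressure
  source `P_im` (ventricular compression): `P_im = P_LV` for the left
  branches and `0.5 P_LV` for the RCA (no right ventricle is modelled).
  The implementation tracks `w = P_m - P_im` as the state, so
  `q_m - q_out = C_m dw/dt`; referencing the medial capacitor to the
  source rather than to ground is a deliberate choice where the circuit
  convention is ambiguous, and it is what produces the systolic
  impediment/diastolic dominance of coronary flow.

States (15): `V_LV`, `V_LA`, six capacitor pressures, `Q_AV`, `Q_MV`, the
pulmonary inductor flow, and a `(P_p, w)` pair per coronary branch.

## Deriving the elements from measurements

* `MAP = DBP + (1/3 + 0.0012 HR)(SBP - DBP)` from the cuff pressures.
* Cardiac output `CO = forward LVOT SV x HR / 60`. The forward LVOT stroke
  volume is used (rather than `EDV - ESV`) because the tuning target is the
  Doppler-measured forward output; with regurgitation the volumetric
  difference would double-count the regurgitant volume.
* Total coronary resistance `R_total = MAP / (0.04 CO)`: the coronary tree
  receives 4.0% of cardiac output at mean arterial pressure.
* Branch totals by a Murray-law variation over all three branches pooled,
  `R_j = (sum_i A_i^1.3 / A_j^1.3) R_total` — the three totals recombine in
  parallel to `R_total` exactly. A focal stenosis multiplies the branch
  total by `alpha^-2` with `alpha = A_sten / A`. Within a branch the split
  is fixed: 0.32/0.52/0.16 proximal/medial/distal.
* Compliance is allocated per side: the left total is shared between LAD
  and LCX proportionally to area, the RCA takes the right total; within a
  branch 0.11/0.89 proximal/medial. The side totals were never published;
  this package defaults to `0.0250` (left) and `0.0125` (right) mL/mmHg,
  chosen once to give physiological biphasic coronary waveforms, and
  exposes both as overrides. Mean branch flow is provably insensitive to
  them (periodic charge conservation); they shape the waveform only.

## Integration and tuning

The stiff system is integrated cycle by cycle with `deSolve`'s `lsoda`
(variable-step, automatic stiffness switching; initial step 0.1 ms;
`rtol = atol = 1e-8`), with the derivative function compiled in C and an
identical pure-R reference implementation cross-checked in the tests.
Capacitor pressures and inductor flows start at zero and chamber volumes at
EDV-scale guesses. Convergence is declared when the relative L2 norm of the
difference between consecutive full-cycle state trajectories (256-interval
uniform grid) falls below `1e-6`; the norm choice is this package's, the
threshold is the model's stated residual criterion.

The slowest transient is the pulmonary venous capacitor
(`C_PVC = 40 mL/mmHg`, time constant ~8 s, i.e. ~10 cycles), so a
safeguarded Aitken extrapolation of cycle-end states is applied: the
contraction ratio is estimated from two consecutive clean cycle-to-cycle
differences, extrapolation happens only when two successive estimates agree
(within 0.05), lie in (0.2, 0.97), and the previous jump actually shrank
the difference; amplification is capped at 30x and the scheme falls back to
plain iteration when it stalls. The reported residual always comes from an
un-extrapolated consecutive-cycle pair, so a converged result re-integrated
one more cycle reproduces `residual <= 1e-6`. Cold starts converge in
roughly 50–150 cycles (0.2–0.5 s); warm-started re-solves in a handful.

Free parameters are tuned deterministically, in a fixed sweep order, each
objective evaluation being a full periodic solve (warm-started):

1. `Q_MPV` so the modelled forward LVOT stroke volume (`∫ max(Q_AV, 0) dt`)
   matches the measurement within 1 mL — by periodic mass conservation this
   is essentially a one-shot update;
2. a damped least-squares fit (`minpack.lm::nls.lm` on log-transformed
   parameters, bounded, finite-difference steps of 1% so solver-level noise
   cannot corrupt the Jacobian) of `(C_ao, C_SAC, R_SA)` to the aortic-root
   pressure extrema vs the cuff SBP/DBP, within 1 mmHg each. The aortic
   root is compared directly against the brachial values — no brachial
   transfer function. Two pressure targets under-determine three
   parameters, so a weak ridge residual anchors `C_SAC`, keeping the fit
   unique and reproducible;
3. `R_ub` so the upper-body branch carries 15% of cardiac output (±0.5
   percentage points);
4. if a paravalvular leak volume is specified, a log-secant iteration on
   the leak resistance to match the retrograde volume within 0.5 mL.

Sweeps repeat (cap 20) until all tolerances hold simultaneously; in
practice one or two sweeps suffice. Tuning a patient takes a few seconds on
one CPU.

## Metrics

* **LV workload**: signed shoelace area of the `P_LV`–`V_LV` loop over the
  converged cycle, `1 mmHg mL = 1.33322e-4 J`; the physiological loop is
  counterclockwise in the (V, P) plane and yields positive work.
* **Phase decomposition**: systole is `[t_open, t_open + T_EJ)` where
  `t_open` is aortic-valve opening (first `Q_AV` crossing of a 2% peak
  threshold) and `T_EJ` is the *measured* ejection time — an input, not a
  pressure-crossing detection; diastole is the remainder. Per branch the
  full-cycle mean, phase means and phase peaks of proximal inflow are
  reported, plus total coronary flow (mL/min) and, when LV mass is
  provided, myocardial blood flow (mL/min/g).
* **Transvalvular gradient**: mean of `P_LV - P_root` over the ejection
  window. A Doppler-style proxy (`4 v^2` with `v = Q_AV / (100 EOA)` m/s)
  and a peak-velocity proxy `max(Q_AV)/(100 EOA)` are reported alongside;
  both are continuity-equation proxies, not measured Doppler velocities,
  and the peak proxy runs high because the modelled ejection waveform is
  peakier than a half-sine.
* **Pre/post deltas**: percent change per metric (absolute when the pre
  value is zero) and the trichotomy classification of the coronary
  response (all branches increase / all decrease / mixed).

## Sensitivity harness

Each input among `MAP`, `CO`, the three branch areas and the two side
compliances is varied independently by ±20%; only the coronary elements
that depend on it are rebuilt, and the systemic tuning stays frozen at
baseline. This freezing is deliberate: re-tuning would, by construction of
the `R_total` formula, cancel the MAP/CO perturbations exactly, so frozen
tuning is the only reading under which those rows are informative. Reported
per row: the maximum (over both signs) relative change in mean branch flow
per branch, the across-branch mean, and the same for peak flows.

## The synthetic cohort generator

The generator emulates a severe-AS TAVR cohort at the published
characteristics: SBP 133.0 ± 18.9 / 142.0 ± 22.3 mmHg (pre/post), DBP
70.5 ± 9.2 / 72.0 ± 15.4, HR 71 ± 14 / 73 ± 13, EF 59.9 ± 8.4 / 62.3 ± 7.0 %,
stenotic EOA 0.84 ± 0.19 cm², post maximum AV velocity 2.75 ± 0.65 m/s.
Every field is an independent truncated normal (inverse-CDF draws, one
uniform per field, fixed draw order), seeded per `(seed, index)` and
bit-reproducible; `sd = 0` degenerates to the mean exactly. Quantities a
cohort table does not print are stand-ins chosen once as typical adult
values: mitral EOA 4.0 ± 0.8 cm², LVOT area 3.5 ± 0.5 cm², ascending aorta
7.0 ± 1.0 cm², EDV 130 ± 25 mL, LV mass 160 ± 30 g,
`T_EJ = 0.3 sqrt(T) ± 0.02 s`, and proximal coronary diameters
3.7/3.4/3.9 ± 0.4 mm (LAD/LCX/RCA). The post EOA is derived from the drawn
post velocity through the half-sine continuity proxy
`EOA = (pi/2) SV / (T_EJ v_max) / 100`.

What the generator does **not** emulate: inter-measurement correlations
(e.g. pressure–EF coupling), regurgitant lesions and paravalvular leak
(defaults zero; the paths are exercised directly in tests), measurement
error structure, and coronary artery disease prevalence. Passing tests on
synthetic cohorts therefore demonstrate the pipeline's correctness and the
model's internal physiology, not clinical agreement on real patients.

## Numerical choices and degenerate inputs

* `T` is derived from HR when absent and must agree with `60/HR` within 1%
  when both are given; `T_EJ` defaults to the classic `0.3 sqrt(T)`.
* `ELCo` diverges as `EOA -> A`; this is rejected as a domain error.
* Stenosis factors `alpha` outside `(0, 1]` are rejected.
* Unstressed volumes `V0 = 5` (LV) and `4` (LA) mL are unpublished
  constants chosen so the cohort-mean volumes give physiological pressures;
  both are overridable.
* The `lv_workload` input must sample a closed loop; open trajectories are
  rejected rather than silently closed.
* A near-resistive configuration (tiny capacitors, constant elastance)
  reaches its periodic orbit within a cycle; the residual definition needs
  a confirmation pair, so the solver reports convergence after ~3 cycles.

## Problem sizes

The test suite and the acceptance script run the cohort-mean patient
(tuned, ~30–60 periodic solves), a 19-patient seeded cohort through full
tuning, and the sensitivity harness on a 5-patient seeded cohort — sizes
chosen to exercise every code path while keeping a complete run in the
single-digit minutes on one CPU.

## Known limitations

* No coronary autoregulation: resistance is fixed by the derivation, so
  perfusion-pressure changes pass straight through to flow (the model's
  sensitivity to MAP reflects this deliberately).
* No right heart: the RCA's intramyocardial source is `0.5 P_LV`, not an RV
  pressure.
* No brachial-to-aortic transfer function; cuff pressures are matched at
  the aortic root.
* The velocity and Doppler-gradient outputs are continuity proxies.
* Validation here is internal (oracles, conservation laws, published
  sensitivity magnitudes); no patient-level clinical data ships with the
  package.
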