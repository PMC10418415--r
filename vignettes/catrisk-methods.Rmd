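---
title: "catrisk: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{catrisk: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(catrisk)
```

## The problem

Drug-induced proarrhythmia — QT prolongation leading to Torsade de Pointes
(TdP) — remains a leading cause of drug withdrawal. The CiPA initiative
established a reference panel of compounds with clinically adjudicated
high, intermediate and low TdP risk, and a classification recipe in which a
small number of waveform-derived predictors feed a multinomial logistic
model that outputs per-compound risk probabilities.

`catrisk` implements that analysis for calcium-transient (CaT) recordings
of spontaneously beating cardiomyocyte wells, comparing a control line with
an aged-phenotype (progeria-derived) line whose baseline repolarization is
longer and whose drug response is stronger. Because no public instrument
data exist for this assay, the package ships a synthetic CaT generator that
emulates the statistical structure the analysis assumes; every pipeline
stage is exercised and tested against it.

## The six-parameter phenotype

Each well recording is reduced to six parameters:

* **P80** — mean peak width at 80% recovery (the level
  `baseline + 0.2 * (peak - baseline)`), in seconds;
* **8/2 (R82)** — mean per-cycle ratio of the 80%-recovery width to the
  20%-recovery width, a triangulation/EAD indicator that is >= 1 by
  construction;
* **CL** — mean inter-peak interval (s);
* **AMP** — mean peak height above the per-cycle baseline (a.u.);
* **PN** — number of detected cycles;
* **CSD** — sample standard deviation of the inter-peak intervals (s),
  a beat-irregularity measure (0 when fewer than 3 peaks).

Cycles are detected on a moving-average-smoothed copy of the signal
(window 0.1 s) by local maxima with prominence at least 0.3 of the
smoothed range and spacing at least 0.25 s; widths are then measured on
the **raw** signal with linear interpolation at the level crossings.
These two thresholds deliberately reject the EAD hump as a separate peak,
so an early afterdepolarization widens P80 (and inflates 8/2) instead of
incrementing PN.

Two robustness rules matter in practice:

* **Debounced crossings.** A level crossing only counts if the signal
  stays on the far side for `crossing_debounce` seconds (default 0.06 s).
  On amplitude-suppressed wells the 20%-recovery level sits within noise
  of the plateau; without debouncing a single noisy sample collapses the
  20% width and the 8/2 ratio explodes.
* **Per-cycle baseline = minimum since the previous peak.** With
  incomplete decay between beats this baseline sits slightly above the
  true diastolic level, which shortens measured widths; the generator
  defaults are calibrated against the *extracted* P80, not the analytic
  pulse width (below).

`r82` is the mean of per-cycle ratios (not a ratio of means): per-cycle
pairing is the natural EAD indicator. CSD uses the n−1 sample standard
deviation because replicate wells carry few beats.

## The synthetic generator

A well is a pulse train. Each pulse rises linearly over `upstroke_time`,
holds a plateau for `plateau_time` and decays exponentially with constant
`decay_tau`; pulses are **additively superposed**, so the previous beat's
tail persists into the next cycle (incomplete calcium clearance), and the
record starts in steady state via a virtual pulse one cycle before t = 0.
Cycle lengths are lognormal with a controllable CV; Gaussian noise and an
optional linear drift (default 0) are added. For the noise-free canonical
pulse the width at recovery fraction r is

    (1 - (1-r)) * upstroke + plateau + tau * log(1/(1-r))

e.g. `0.8*u + p + tau*log(5)` at 80% recovery — the analytic oracle used
in the tests.

**Cell lines.** Defaults: 30 s records at 50 Hz, amplitude 1 a.u., noise
SD 0.02 a.u. (recording length, rate and noise are stated nowhere in the
source assay; these resolve sub-second upstrokes at trivial cost).
Control beats at 1.3 s cycles, progeria at 1.6 s. The plateau and decay
constants were calibrated **once**, by secant iteration of a single scale
factor against the full extraction pipeline, so that the mean extracted
P80 of undosed wells is 0.70 s (control) and 0.98 s (progeria) — the two
baseline targets the assay reports. The calibration is against extraction
rather than the analytic width because the measured value carries the
diastolic-baseline bias described above (about −4% at these settings).
A per-well lognormal jitter (SD 0.05) on the duration constants, shared
between the pre and post recording of a well, reproduces the reported
across-well spread (±0.04–0.05 s).

**Drug effects.** Each compound has a Hill-type prolongation model
(scales plateau and decay by `1 + f`), a Hill amplitude-suppression
model, an EAD probability ramping linearly from `ead_onset_dose` to the
top dose, deterministic beat cessation at `cessation_dose`, and an added
cycle-length CV (`irregularity_gain`). The progeria profile multiplies
all fractional effects by `sensitivity = 1.5` (control 1.0) — the single
mechanism that realizes the aged line's greater susceptibility. The
shipped per-compound table (`drug_effects_synthetic.csv`) is **synthetic
calibration, not measured data**: high-risk compounds get strong
prolongation and EAD propensity (dofetilide and quinidine also cease at
their top dose), intermediates moderate prolongation with occasional
EADs, low-risk compounds amplitude/rate effects with minimal
prolongation, and diltiazem a large irregularity gain.

**EAD rendering.** An EAD-flagged well renders a Gaussian hump on every
decay at 70% of the decay span (span defined as 2.6 decay-time-constants,
~93% recovery), SD 0.3 tau, amplitude 0.3 of the main pulse. This
placement guarantees the 80%-recovery crossing lands past the hump at all
prolongation levels, pushing the 8/2 ratio from its baseline (~2.6) past
the sigmoid centre (3), while the hump's prominence stays below the peak
detector's threshold.

## Profile transforms and radial plots

Per compound, cell line and dose, the six parameters are summarized as
percent change from the same well's pre-dose baseline, averaged over
replicate wells. Two transforms shape the radial ("spider") profiles:

* the **EAD indicator** `1 / (1 + exp(-9 (x - 3)))` applied to the 8/2
  axis. The printed source form is typographically ambiguous; the standard
  logistic (slope 9, centre 3) is the only reading that saturates and can
  act as an indicator. It is applied to the *raw* post-dose 8/2 value,
  whose plausible EAD values bracket 3 (percent changes do not); a switch
  (`r82_input = "pct"`) selects the alternative.
* the **log-modulus** `L(x) = sign(x) log10(|x| + 1)` on the other five
  axes (base 10; odd, monotone, 0 at 0).

Ceased wells contribute only to the PN axis; a dose where all wells
ceased is drawn as a gap.

## CiPA-style predictors

Per compound and cell line, three predictors enter the risk model:

1. **Arrhythmia type**, ordinal NONE = 0 / OTHER = 1 / TYPE_A = 2.
   TYPE_A when at any dose at least 25% of wells have an EAD indicator
   above 0.5; else OTHER when any dose has ≥ 50% ceased wells or a mean
   P80 change ≥ +100%; else NONE (precedence TYPE_A > OTHER > NONE; all
   thresholds configurable — the source specifies none). Wells whose
   amplitude collapsed below 35% of their own baseline are excluded from
   the EAD count: at that signal level the 20%-recovery width is
   noise-dominated and the 8/2 ratio unmeasurable.
2. **P80@Cmax** — the per-dose mean P80 changes interpolated linearly in
   log10(dose) at the clinical Cmax, clamped (and flagged) when Cmax lies
   outside the tested grid, as for bepridil and diltiazem.
3. **P80_Max** — the maximum defined per-dose mean.

The two continuous predictors are min–max normalized to [0, 1] across
the 11-compound panel within each cell line (z-score available); the
ordinal score stays on 0/1/2.

## The risk model

A three-class multinomial logistic model (full softmax
parameterization, ridge penalty `1/(2C) ||W||^2` on the weights only,
`C = 1` by default, intercepts unpenalized) is fitted per cell line by
L-BFGS-B with analytic gradients, a 1000-iteration cap and zero
initialization — deterministic and row-permutation invariant. This
mirrors the conventional scikit-learn recipe the source describes, but is
authored in-package because no equivalent solver ships in the dependency
set.

Prediction is **in-sample** on the 11 training compounds by default,
faithful to the source analysis; this is circular by construction, and a
leave-one-out mode is provided as a labeled extension. The decision
quantity is `combined_risk = P(high) + P(intermediate)` against a 0.8
threshold.

## What a green test establishes — and what it does not

The generator reproduces the *statistical structure* the analysis
assumes: two baseline P80 levels with realistic spread, monotone
dose-dependent prolongation, EAD morphology that drives the 8/2
indicator, cessation, and irregularity. It does not model ion-channel
kinetics, action potentials, pacing, optical artifacts, or well-to-well
spatial effects; passing tests validate the pipeline's measurement and
classification logic on calibrated input, not any wet-lab claim. Two
known cosmetic limits: heavily amplitude-suppressed wells (verapamil at
top doses) have unreliable 8/2 values — gated out of classification but
still visible on radial plots — and very irregular wells (diltiazem)
show mild upward 8/2 drift from elevated diastolic baselines.

## Numerical and degenerate-input choices

* Flat or beat-free traces (smoothed range below `noise_floor`, 0.1 a.u.)
  yield zero cycles and the all-`NA` phenotype sentinel with `pn = 0`;
  pairing such a well as a *baseline* drops it with a warning, as a
  *post* recording it flags the well ceased (PN change −100%).
* Truncated widths (no debounced crossing before the cycle boundary) are
  flagged and excluded from the P80/8-2 means but still count in PN.
* Percent change of a parameter that is 0 in both phases (CSD of a
  perfectly regular well) is defined as 0.
* `p80_at_cmax` drops fully-ceased doses before interpolating; a panel
  with zero spread normalizes to 0.5 with a warning.
* Well seeds derive deterministically from the master seed
  (`(seed * 1000003 + i * 7919) mod 2147483629`), keeping every derived
  seed a valid 32-bit integer; all simulation is exactly reproducible.
* The optimizer cap (1000) is far above the ~50 iterations the
  11-compound fits need; non-convergence returns coefficients with a
  warning rather than failing.
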