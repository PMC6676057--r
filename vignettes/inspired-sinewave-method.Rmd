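---
title: "Cardiac output from an inspired tracer sinewave: model, estimator and validation statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cardiac output from an inspired tracer sinewave}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(istco)
```

## The measurement principle

The inspired sinewave technique (IST) forces the inspired concentration of
a soluble tracer gas — nitrous oxide here — to oscillate sinusoidally over
successive breaths, by default around a mean of 4% with amplitude 3% and a
60-second period. The lung passes this oscillation on to the expired gas,
but damped and phase-shifted: the more tracer the pulmonary capillary
blood carries away, and the larger the alveolar gas store it must charge,
the smaller and later the expired sinewave. Reading the expired amplitude
and phase against the inspired ones therefore measures two quantities at
once: the pulmonary blood flow that actually participates in gas exchange
(`Q_eff`, L/min) and the effective lung volume (`ELV`, L). Because the
forcing period is short (< 3 min), tracer returning in mixed-venous blood
has not yet recirculated appreciably and the venous tracer fraction can be
taken as zero; the package keeps a `venous_fraction` hook for studying the
recirculation error, off by default.

Two properties of the principle shape everything downstream:

* blood flow bypassing ventilated lung (shunt) is invisible: the method
  reads `Q_eff = Q * (1 - f_shunt)`, so a 30% shunt yields a reading of
  70% of the thermodilution cardiac output, exactly;
* each reported value summarises a trailing window of breaths, so the
  monitor registers haemodynamic change late (roughly half a window) and
  attenuates fast transients.

## The tidal lung model

The forward model is a single, well-mixed alveolar compartment ventilated
tidally. Each breath is a two-stage update of the alveolar fraction
`F_A`:

1. **Mixing.** The end-expiratory gas (`ELV`), rebreathed dead-space gas
   (`V_D`, at the previous end-tidal fraction) and fresh gas
   (`V_T - V_D`, at the inspired fraction) mix instantaneously:
   `F_mix = (ELV F_A + V_D F_ET + (V_T - V_D) F_I) / (ELV + V_T)`.
2. **Uptake.** Over the breath period `T_b` the mixed fraction relaxes
   exponentially towards the mixed-venous fraction at the rate set by the
   solubility-weighted effective flow:
   `F_A' = F_v + (F_mix - F_v) exp(-lambda Q_eff (T_b/60) / (ELV + V_T))`.

End-tidal sampling is ideal (`F_ET = F_A`), sensor error is additive
Gaussian noise on the recorded end-tidal value only, and the tracer
volume removed per breath, `(ELV + V_T)(F_mix - F_A')`, makes the mass
bookkeeping exact by construction. This two-stage recursion is a
documented reconstruction of the tidal model class used by sinusoidally
forced gas-exchange devices — faithful in behaviour, with guaranteed
positivity and exact mass accounting, but not claimed to be bit-identical
to any particular device's internal equations. There is no intra-breath
gas transport, no multi-compartment heterogeneity and no analyser
dynamics (see Non-goals below).

Default parameter values and their origins:

| parameter | default | meaning |
|---|---|---|
| `solubility` | 0.47 | Ostwald blood–gas coefficient of N2O at body temperature (standard physiology value) |
| `tidal_volume` | 8 ml/kg | the protocol's volume-controlled setting |
| `dead_space` | 2.2 ml/kg | series dead space; not printed by typical protocols, standard value, configurable |
| `resp_rate` | 15 /min | fixed through the protocol |
| `venous_fraction` | 0 | no-recirculation assumption at short periods |

### Closed-form steady state

Because the recursion is linear in `F_A`
(`F_A[n] = a F_A[n-1] + b F_I[n]`), its periodic steady state under
sinusoidal forcing is available exactly as the discrete transfer
`H = b / (1 - a e^{-i w T_b})`: `tidal_transfer()` returns its modulus
(amplitude ratio), negated argument (phase lag) and DC gain. A test
verifies that simulating the recursion to steady state and fitting
sinusoids reproduces this closed form to 1e-8, so using `H` inside the
inverse search *is* matching the tidal model's own steady state, just
without re-simulating in the optimiser loop.

`continuous_transfer()` gives the continuously ventilated limit
(`amplitude_ratio = V'A / sqrt((V'A + lambda Q_eff)^2 + (w ELV)^2)`, with
the matching arctangent phase), used as an independent oracle and to seed
the inversion. The tidal response approaches it linearly as the breath
period shrinks with alveolar ventilation fixed: the worst-grid
discrepancy over `Q_eff` 2–10 L/min × `ELV` 0.5–2.5 L halves with each
halving of `T_b` (about 6% at 1 s, 2% by 0.25 s). The first-order gap is
inherent to the split of each breath into instantaneous mixing followed
by uptake; at the study's 4-s breaths the two models genuinely differ
(by design the estimator inverts the tidal model, not the continuous
one), and the package treats the continuous form strictly as a limit
oracle.

## The estimator

`fit_sinusoid()` is ordinary least squares on `{1, sin, cos}` at the
known forcing frequency — the standard three-parameter quadrature fit.
`invert_window()` minimises the squared mismatch between observed and
model (amplitude ratio, phase lag) over `(Q_eff, ELV)` inside
physiological bounds (0.5–25 L/min, 0.2–5 L, covering 37–53 kg pigs and
adult humans), starting from the analytic continuous-form inversion plus
a coarse log-spaced grid, refined with a bounded quasi-Newton step.
Windows whose observations sit outside the model's reachable set (e.g. a
lossless ratio-1/lag-0 window) end on the bound and are flagged
`at_bound` rather than silently reported. The mean-level ratio is *not*
part of the default objective — it is the observable most corrupted by
sensor offset — but `use_mean_gain = TRUE` adds it.

`rolling_estimates()` applies this to trailing 3-minute windows every
30 s, the monitor's reporting scheme: one inversion per window, the
window itself doing the averaging (rather than averaging faster
per-breath inversions — with 45 breaths per window the single fit is the
better-conditioned reading of the same data). Estimator precision is
noise-limited per window: with 0.1%-absolute end-tidal noise a single
45-breath window carries roughly 10–15% standard error in `Q_eff` at
mid-range parameters (close to the information-theoretic limit for three
fitted sinusoid parameters), which averages down over the reporting
stream; the test suite asserts < 5% variability for a 20-minute averaged
reading at study-scale parameters, and exact recovery (≤ 2%, in practice
~1e-5) for noiseless windows across the whole parameter grid.

Alignment with an intermittent reference uses `estimate_delay()`
(regression R² over a lag grid, ties to the smallest lag; note the
nearest-estimate pairing quantises lags to the 30-s reporting grid, so
ties on the plateau around the true lag are expected) and
`pair_measurements()` (nearest estimate within ±15 s after lag
correction).

## Method-comparison statistics

The validation toolkit mirrors how continuous cardiac output monitors are
judged against bolus thermodilution:

* **Repeatability** (`repeatability_coefficient()`): pooled within-triplet
  CV of accepted thermodilution triplicates, scaled by `1.96*sqrt(2)`
  (the least-significant-change factor). The triplet acceptance rule —
  three injections within 10% — is itself part of the simulated protocol.
* **Interchangeability** (`interchangeability()`): a pair agrees when the
  difference is below `((Q_T + Q_IST)/2) * sqrt(2) * R_QT`.
* **Repeated-measures Bland–Altman** (`bland_altman()`): limits of
  agreement from `between-subject variance of subject-mean differences +
  mean within-subject variance`, so many measurements per animal do not
  fake precision; the bias CI comes from the subject-level means
  (t, `n_subjects - 1` df). The delta mode re-expresses each subject
  against its own baseline, which removes the between-animal offset that
  dominates absolute disagreement.
* **Four-quadrant and half-circle polar trending** (`four_quadrant()`,
  `polar_analysis()`): consecutive paired changes, with an exclusion zone
  of 15% of the mean cardiac output. One consistent exclusion rule is
  used for both: a change is excluded when the magnitude of its polar
  radius `|(dQ_T + dQ_IST)/2|` is below the threshold (the radius is the
  quantity the polar plot actually draws; applying the same rule to the
  four-quadrant plot keeps the two analyses comparable). Angles are in
  degrees, measured from the 45° line of identity, with net-negative
  changes reflected through the origin onto the half circle `(-90°, 90°]`.
  Conventional benchmarks: concordance > 92% good, 90–95% marginal;
  angular bias within ±5° with > 95% of points inside ±30° good.
* **TIM** (`tim_classify()`): reference changes whose repeatability CIs
  overlap are *uninterpretable*; the rest are classed interchangeable /
  uncertain / non-interchangeable against boundary lines anchored at the
  first pair. The second boundary's intercept factor is implemented
  exactly as printed in the method description, which is asymmetric
  (`(1 + R_QT)` on both intercepts); since that asymmetry may be a
  typesetting artefact, `boundary = "symmetric"` provides the
  `(1 - R_QT)` variant. The class fractions always partition 100%.

## The virtual study generator

`run_virtual_study()` emulates the porcine validation protocol so the
whole pipeline is testable without animal data: 8 virtual pigs of
37–53 kg; baseline cardiac output 3.5–5.5 L/min held for 10 min with a
slow AR(1) wobble (60-s correlation time, 1.5% stationary SD, clipped at
±5% so the protocol's 15% baseline-fluctuation rule always holds); an
esmolol phase dropping output by 1.3–1.8 L/min; recovery; a dobutamine
phase raising it 3.3–4.2 L/min above baseline — all transitions
exponential with a 45-s time constant, the pace of the drug effects the
protocol describes. The drop/rise ranges sit above the protocol's ≥ 1 and
≥ 3 L/min requirements by a margin exceeding the wobble clip, so the
generated trajectories satisfy the requirements for every draw, not just
on average. Thermodilution triplets are sampled every 3–5 min with 5%
per-injection CV (typical triplicate variability; configurable), end-tidal
noise is 0.001 absolute fraction, and effective lung volume scales with
weight (25–35 ml/kg). Shunt is 2–5% for healthy lungs; the lavage flag
draws it from 15–35%, reproducing the saline-lavage lung-injury
condition. The coupling of the slowly varying flow to the breath model is
quasi-static — each breath uses the instantaneous `Q_eff` — which is
consistent with minutes-scale haemodynamic change against 4-s breaths.

What the generator deliberately does not emulate: pharmacokinetics (drug
levels are represented only by their haemodynamic effect), blood-gas
chemistry, ventilator mechanics, analyser response times, and real
within-animal cardiac output spectra (the AR(1) wobble is a modelling
choice with exposed parameters). Passing end-to-end tests therefore shows
the pipeline recovers what this model generates — including the
shunt-induced underestimation mechanism — not that the device achieves
any particular in-vivo agreement.

## Worked pipeline

```{r pipeline, eval = FALSE}
cfg <- scenario_config(n_subjects = 8, seed = 11, lavage = TRUE,
                       shunt_range = c(0, 0))
res <- run_pipeline(cfg)
res$report$trend$concordance_4q   # ~100% at low noise, no shunt
res$report$trend$angular_bias     # within a few degrees of 0
res$report$agreement$bias         # small: no shunt, no offset sources
```

With shunt levels 0 / 0.1 / 0.2 / 0.3 at a shared seed the
delta-regression slope falls monotonically (roughly as `1 - f_shunt`
times the no-shunt slope) — the gas-exchange reading of an increasingly
bypassed circulation.

## Numerical choices and limitations

* Problem sizes in the shipped tests: 3-period fitting windows after a
  10-period warm-up; 5×5 round-trip grids; 8-subject cohorts over 35-min
  protocols; 40-seed noise ensembles. Each was chosen as the smallest
  size at which the property under test is stable.
* The inversion is deterministic (fixed grid + bounded local refinement);
  phase differences are wrapped to `[0, 2*pi)`; `at_bound` marks
  unreachable observations; windows with fewer than 4 breaths are
  skipped with a warning.
* Degenerate inputs fail loudly: rank-deficient sinusoid designs,
  non-monotone breath times, fractions outside `[0, 1]`, non-positive
  flows in the statistics, infeasible scenario ranges.
* The delay estimate is quantised by the 30-s reporting grid and needs a
  trajectory with structure; on a featureless plateau the R² profile is
  flat and the tie rule returns the smallest lag.
* Simulated cohorts have far fewer paired measurements (~8–10 per
  subject per condition) than a real protocol's continuous recording;
  trending percentages from a single virtual cohort carry sampling noise
  of a few percent.
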