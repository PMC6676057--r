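# istco — inspired sinewave technique cardiac output

`istco` simulates and analyses the **inspired sinewave technique (IST)**,
a noninvasive, fully automated respiratory method for continuous cardiac
output monitoring in mechanically ventilated subjects. The inspired
nitrous oxide fraction is forced to oscillate sinusoidally (mean 4%,
amplitude 3%, period 60 s); pulmonary capillary blood flow damps and
delays the expired oscillation, and inverting a single-compartment tidal
lung model on each rolling 3-minute window recovers both the effective
pulmonary blood flow Q̇_IST and the effective lung volume (ELV).

The package is aimed at researchers developing or validating
respiratory-based cardiac output monitors. It provides:

* **Forward model** — the tidal two-stage breath recursion (instant
  mixing of ELV, rebreathed dead-space and fresh gas; exponential uptake
  `exp(-λ·Q_eff·T_b/(ELV+V_T))` with λ the N₂O blood–gas Ostwald
  coefficient, 0.47), its exact discrete-time steady-state transfer
  `H = b/(1 − a·e^{−iωT_b})`, and the continuous-ventilation closed form
  `V̇A/√((V̇A+λQ_eff)² + (ωELV)²)` as an independent oracle.
* **Estimator** — least-squares sinusoid fits at the known forcing
  frequency, bounded inversion of (amplitude ratio, phase lag) for
  (Q_eff, ELV), rolling 3-min/30-s estimates, regression-based delay
  estimation and pairing with intermittent reference measurements.
* **Method-comparison statistics** — interchangeability rate with the
  `((Q̇_T+Q̇_IST)/2)·√2·R_QT` criterion, repeated-measures Bland–Altman
  limits of agreement, four-quadrant concordance with a 15% exclusion
  zone, half-circle polar plot analysis (angular bias, radial limits,
  ±30° concordance), and the trend interchangeability method (TIM).
* **Virtual porcine study generator** — 8 virtual animals (37–53 kg,
  8 ml/kg tidal volume), baseline → esmolol (≥1 L/min drop) → dobutamine
  (≥3 L/min rise) trajectories, triplicate thermodilution every 3–5 min
  with the ≤10%-spread acceptance rule, and a saline-lavage condition
  with elevated shunt — so the full pipeline is testable with no
  external data. Because gas exchange only sees blood reaching
  ventilated lung, a shunt fraction `f` makes the method read
  `Q̇·(1−f)`: the underestimation mechanism the analysis toolkit is built
  to expose.

## Worked example

Simulate a monitored subject (44 kg, ELV 1.3 L, cardiac output 5 L/min
with a 5% physiological shunt, 0.1%-absolute end-tidal sensor noise) and
run the monitor's rolling estimator:

```r
library(istco)

wave <- sinewave_config()                      # 4% / 3% / 60 s forcing
vent <- ventilation_config(weight = 44)        # 8 ml/kg at 15 breaths/min
lung <- lung_params(elv = 1.3, cardiac_output = 5, shunt_fraction = 0.05)

breaths <- simulate_breath_series(lung, vent, wave, duration = 900,
                                  sensor_noise_sd = 0.001, seed = 42)
est <- rolling_estimates(breaths, vent, wave)  # 3-min window, 30-s stride
head(subset(est, report_time_s >= 300)[, 1:3], 4)
#>  report_time_s q_ist_lmin    elv_l
#>            300   4.726723 1.254461
#>            330   4.413653 1.241991
#>            360   4.597825 1.254974
#>            390   4.969897 1.276189
```

Each row is one monitor reading: at `report_time_s` seconds the previous
3 minutes of breaths gave an effective pulmonary blood flow `q_ist_lmin`
(truth here: 5 × 0.95 = 4.75 L/min — single readings scatter around it
with roughly 10% noise-limited precision, averaging to 4.99 L/min over
this run) and an effective lung volume `elv_l` (truth 1.3 L).

A complete virtual validation study — simulation, estimation, delay
correction, pairing and the full statistics report:

```r
res <- run_pipeline(scenario_config(n_subjects = 8, seed = 11,
                                    lavage = TRUE, shunt_range = c(0, 0)))
res$report$trend$concordance_4q   #> 100        (four-quadrant, % concordant)
res$report$trend$angular_bias     #> -1.29      (degrees from the 45° identity line)
res$report$trend$slope            #> 0.92       (ΔQ̇_IST vs ΔQ̇_T regression)
res$report$agreement$bias         #> -0.037     (L/min, Bland–Altman)
```

With no shunt and low noise the two methods trend together (concordance
100%, angular bias ≈ 0°); raising the shunt to 0.1/0.2/0.3 drags the
Δ-regression slope down monotonically while thermodilution still sees
the full flow.

A thin command-line driver wraps the same functions
(`inst/cli/ist.R`; subcommands `simulate`, `synth`, `estimate`,
`compare`, `pipeline`).

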