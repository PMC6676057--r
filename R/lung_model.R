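#' Inspired tracer fraction at a given time
#'
#' Evaluates the sinusoidal forcing
#' `M + A * sin(2*pi*(t - t0)/T_p + phi0)`, clipped to [0, 1] (under the
#' `sinewave_config` invariant the clip never triggers).
#'
#' @param t Time(s) in seconds, vectorised.
#' @param wave A [sinewave_config()].
#' @return Inspired gas fraction(s), same length as `t`.
#' @export
inspired_waveform <- function(t, wave) {
  stopifnot(inherits(wave, "sinewave_config"), is.numeric(t), all(is.finite(t)))
  f <- wave$mean_fraction + wave$amplitude *
    sin(2 * pi * (t - wave$onset_time) / wave$period + wave$phase_offset)
  pmin(pmax(f, 0), 1)
}

#' Advance the lung state by one breath
#'
#' One step of the single-compartment tidal recursion. Each breath is a
#' two-stage update:
#' \enumerate{
#'   \item mixing of the end-expiratory alveolar gas with rebreathed
#'     dead-space gas and fresh inspired gas,
#'     `F_mix = (ELV*F_A + V_D*F_ET + (V_T - V_D)*F_I) / (ELV + V_T)`;
#'   \item first-order relaxation towards the mixed-venous fraction over
#'     the breath period, driven by the tracer solubility and the effective
#'     pulmonary blood flow:
#'     `F_A' = F_v + (F_mix - F_v) * exp(-lambda*Q_eff*(T_b/60)/(ELV + V_T))`.
#' }
#' End-tidal sampling is ideal (`F_ET' = F_A'`). The tracer volume removed
#' by blood, `uptake = (ELV + V_T)*(F_mix - F_A')` (litres at body
#' conditions), makes the mass bookkeeping of the step exact.
#'
#' @param f_a_prev Alveolar fraction at end of previous breath.
#' @param f_et_prev End-tidal fraction of previous breath (rebreathed from
#'   dead space; equals `f_a_prev` in noiseless simulation).
#' @param f_i Inspired fraction of the current breath.
#' @param vent A [ventilation_config()].
#' @param lung A [lung_params()].
#' @return A list with `f_a`, `f_et` and `uptake`.
#' @export
#' @examples
#' v <- ventilation_config(tidal_volume = 0.32, dead_space = 0.12)
#' l <- lung_params(elv = 1.5, cardiac_output = 5)
#' step_breath(0.04, 0.04, 0.04, v, l)
step_breath <- function(f_a_prev, f_et_prev, f_i, vent, lung) {
  stopifnot(inherits(vent, "ventilation_config"), inherits(lung, "lung_params"))
  fr <- c(f_a_prev, f_et_prev, f_i)
  if (!all(is.finite(fr)) || any(fr < 0) || any(fr > 1))
    stop("fractions must be finite and in [0, 1]")
  elv <- lung$elv; vt <- vent$tidal_volume; vd <- vent$dead_space
  f_mix <- (elv * f_a_prev + vd * f_et_prev + (vt - vd) * f_i) / (elv + vt)
  decay <- exp(-lung$solubility * lung$effective_flow *
                 (vent$breath_period / 60) / (elv + vt))
  f_a <- lung$venous_fraction + (f_mix - lung$venous_fraction) * decay
  list(f_a = f_a, f_et = f_a, uptake = (elv + vt) * (f_mix - f_a))
}

# Internal vectorised breath loop shared by the constant-Q simulator and the
# virtual study (time-varying effective flow, quasi-static per breath).
# q_eff: effective flow per breath (L/min, length n). Returns the noiseless
# alveolar trace and per-breath uptake.
breath_recursion <- function(f_i, q_eff, elv, vt, vd, tb, lambda, f_v) {
  n <- length(f_i)
  f_a <- numeric(n)
  uptake <- numeric(n)
  a_mix_prev <- (elv + vd) / (elv + vt)     # F_ET fed back equals F_A
  b_mix <- (vt - vd) / (elv + vt)
  decay <- exp(-lambda * q_eff * (tb / 60) / (elv + vt))
  state <- f_v
  for (i in seq_len(n)) {
    f_mix <- a_mix_prev * state + b_mix * f_i[i]
    state <- f_v + (f_mix - f_v) * decay[i]
    f_a[i] <- state
    uptake[i] <- (elv + vt) * (f_mix - state)
  }
  list(f_a = f_a, uptake = uptake)
}

#' Simulate a breath-by-breath tracer series
#'
#' Runs the tidal recursion from an initial alveolar fraction equal to the
#' mixed-venous fraction (tracer-free lung by default), with breaths
#' stamped at `t_n = n * T_b` and the inspired fraction read from the
#' forcing waveform at breath start. The recorded end-tidal fraction is
#' perturbed by independent zero-mean Gaussian sensor noise and clipped to
#' [0, 1]; the noiseless alveolar fraction is kept alongside.
#'
#' @param lung A [lung_params()].
#' @param vent A [ventilation_config()].
#' @param wave A [sinewave_config()].
#' @param duration Simulated time (s, > 0); a warning is issued below three
#'   forcing periods, where downstream sinusoid fits are unreliable.
#' @param sensor_noise_sd Standard deviation of the additive end-tidal
#'   sensor noise (fraction units, >= 0).
#' @param seed Optional integer; when given the series is reproducible.
#' @return A `data.frame` of class `"breath_series"` with columns
#'   `breath_index`, `t_start_s`, `f_i_n2o`, `f_et_n2o`, `f_a_n2o`.
#' @export
#' @examples
#' b <- simulate_breath_series(lung_params(1.5, 5), ventilation_config(weight = 40),
#'                             sinewave_config(), duration = 360, seed = 1)
#' head(b)
simulate_breath_series <- function(lung, vent, wave, duration,
                                   sensor_noise_sd = 0, seed = NULL) {
  stopifnot(inherits(lung, "lung_params"), inherits(vent, "ventilation_config"),
            inherits(wave, "sinewave_config"))
  if (!is.numeric(duration) || duration <= 0) stop("`duration` must be > 0")
  if (sensor_noise_sd < 0) stop("`sensor_noise_sd` must be >= 0")
  if (duration < 3 * wave$period)
    warning("duration below three forcing periods; fits will be unreliable")
  tb <- vent$breath_period
  n <- floor(duration / tb)
  t_n <- (seq_len(n) - 1) * tb
  f_i <- inspired_waveform(t_n, wave)
  sim <- breath_recursion(f_i, rep(lung$effective_flow, n), lung$elv,
                          vent$tidal_volume, vent$dead_space, tb,
                          lung$solubility, lung$venous_fraction)
  if (!is.null(seed)) set.seed(seed)
  f_et <- sim$f_a
  if (sensor_noise_sd > 0)
    f_et <- pmin(pmax(f_et + rnorm(n, 0, sensor_noise_sd), 0), 1)
  structure(data.frame(breath_index = seq_len(n) - 1L, t_start_s = t_n,
                       f_i_n2o = f_i, f_et_n2o = f_et, f_a_n2o = sim$f_a),
            class = c("breath_series", "data.frame"))
}

#' Steady-state transfer of the tidal recursion (exact)
#'
#' The tidal recursion is linear in the alveolar fraction,
#' `F_A[n] = a F_A[n-1] + b F_I[n]` with
#' `a = g (ELV + V_D)/(ELV + V_T)`, `b = g (V_T - V_D)/(ELV + V_T)` and
#' `g = exp(-lambda Q_eff (T_b/60)/(ELV + V_T))`, so its periodic steady
#' state under sinusoidal forcing is the discrete transfer
#' `H = b / (1 - a exp(-i w T_b))` evaluated at the forcing frequency.
#' This closed form is exactly what simulating the recursion to steady
#' state and fitting a sinusoid would return, and is what the inverse
#' procedure matches against.
#'
#' @param q_eff Effective pulmonary blood flow (L/min).
#' @param elv Effective lung volume (L).
#' @param vent A [ventilation_config()].
#' @param wave A [sinewave_config()] (only the period is used).
#' @param solubility Tracer Ostwald blood-gas coefficient.
#' @return A list with `amplitude_ratio` (expired/inspired, in (0, 1)),
#'   `phase_lag` (radians, positive = expired lags inspired) and
#'   `mean_gain` (ratio of mean levels for zero venous return).
#' @seealso [continuous_transfer()] for the continuous-ventilation limit.
#' @export
tidal_transfer <- function(q_eff, elv, vent, wave, solubility = 0.47) {
  stopifnot(inherits(vent, "ventilation_config"),
            inherits(wave, "sinewave_config"))
  tb <- vent$breath_period
  vt <- vent$tidal_volume; vd <- vent$dead_space
  g <- exp(-solubility * q_eff * (tb / 60) / (elv + vt))
  a <- g * (elv + vd) / (elv + vt)
  b <- g * (vt - vd) / (elv + vt)
  h <- b / (1 - a * exp(-1i * 2 * pi * tb / wave$period))
  list(amplitude_ratio = Mod(h),
       phase_lag = (-Arg(h)) %% (2 * pi),
       mean_gain = b / (1 - a))
}

#' Continuous-ventilation transfer function
#'
#' Closed-form frequency response of the continuously ventilated
#' single-compartment lung, the limit of the tidal model as the breath
#' period shrinks with alveolar ventilation held fixed. With
#' `w = 2*pi/T_p` and alveolar ventilation and solubility-weighted blood
#' flow in L/s:
#' `amplitude_ratio = V'A / sqrt((V'A + lambda*Q_eff)^2 + (w*ELV)^2)`,
#' `phase_lag = atan(w*ELV / (V'A + lambda*Q_eff))`,
#' `mean_gain = V'A / (V'A + lambda*Q_eff)`.
#' Used as an independent oracle for the tidal recursion and to seed the
#' inverse search.
#'
#' @inheritParams tidal_transfer
#' @param lung A [lung_params()] (uses `elv`, `effective_flow`,
#'   `solubility`).
#' @return A list with `amplitude_ratio`, `phase_lag` (rad) and
#'   `mean_gain`.
#' @export
continuous_transfer <- function(lung, vent, wave) {
  stopifnot(inherits(lung, "lung_params"), inherits(vent, "ventilation_config"),
            inherits(wave, "sinewave_config"))
  va <- vent$alveolar_ventilation / 60          # L/s
  if (va <= 0) stop("alveolar ventilation must be > 0")
  lq <- lung$solubility * lung$effective_flow / 60
  w <- 2 * pi / wave$period
  list(amplitude_ratio = va / sqrt((va + lq)^2 + (w * lung$elv)^2),
       phase_lag = atan(w * lung$elv / (va + lq)),
       mean_gain = va / (va + lq))
}
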