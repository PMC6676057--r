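#' Sinusoidal inspired-gas forcing configuration
#'
#' Describes the inspired tracer sinewave delivered by the gas injection
#' system: fraction oscillates as `M + A * sin(2*pi*(t - t0)/T_p + phi0)`.
#' Defaults are the standard operating point: mean 4%, amplitude 3%,
#' period 60 s.
#'
#' @param mean_fraction Mean inspired tracer fraction M (dimensionless,
#'   strictly inside (0, 1)).
#' @param amplitude Oscillation amplitude A (fraction). Must satisfy
#'   `0 <= A <= min(M, 1 - M)` so the inspired fraction never leaves [0, 1].
#' @param period Forcing period T_p in seconds (> 0).
#' @param phase_offset Phase offset phi0 in radians.
#' @param onset_time Time t0 (s) at which the sine starts from phase
#'   `phi0`.
#'
#' @return An object of class `"sinewave_config"`.
#' @seealso [inspired_waveform()]
#' @export
#' @examples
#' wave <- sinewave_config()
#' inspired_waveform(c(0, 15, 30), wave)
sinewave_config <- function(mean_fraction = 0.04, amplitude = 0.03,
                            period = 60, phase_offset = 0, onset_time = 0) {
  stopifnot(is.numeric(mean_fraction), length(mean_fraction) == 1L,
            is.numeric(amplitude), length(amplitude) == 1L,
            is.numeric(period), length(period) == 1L)
  if (!is.finite(mean_fraction) || mean_fraction <= 0 || mean_fraction >= 1)
    stop("`mean_fraction` must lie strictly inside (0, 1)")
  if (!is.finite(amplitude) || amplitude < 0 ||
      amplitude > min(mean_fraction, 1 - mean_fraction) + 1e-12)
    stop("`amplitude` must satisfy 0 <= A <= min(M, 1 - M)")
  if (!is.finite(period) || period <= 0) stop("`period` must be > 0")
  structure(list(mean_fraction = mean_fraction, amplitude = amplitude,
                 period = period, phase_offset = phase_offset,
                 onset_time = onset_time),
            class = "sinewave_config")
}

#' Volume-controlled ventilation configuration
#'
#' Tidal volume and series dead space can be given directly (litres) or
#' derived from body weight using the standard settings of the porcine
#' protocol: tidal volume 8 ml/kg and dead space 2.2 ml/kg.
#'
#' @param tidal_volume Tidal volume V_T (L). Defaults to `0.008 * weight`.
#' @param dead_space Series (airway + apparatus) dead space V_D (L),
#'   `0 <= V_D < V_T`. Defaults to `0.0022 * weight`.
#' @param resp_rate Respiratory rate f_R (breaths per minute, > 0).
#' @param weight Body weight (kg), only used to default the volumes.
#'
#' @return An object of class `"ventilation_config"` with the derived
#'   `breath_period` (s) and `alveolar_ventilation` (L/min) included.
#' @export
#' @examples
#' ventilation_config(weight = 40)                       # 0.32 L at 15 bpm
#' ventilation_config(tidal_volume = 0.5, dead_space = 0.15, resp_rate = 12)
ventilation_config <- function(tidal_volume = NULL, dead_space = NULL,
                               resp_rate = 15, weight = NULL) {
  if (is.null(tidal_volume)) {
    if (is.null(weight)) stop("give either `tidal_volume` or `weight`")
    tidal_volume <- 0.008 * weight
  }
  if (is.null(dead_space))
    dead_space <- if (is.null(weight)) 0.3 * tidal_volume else 0.0022 * weight
  stopifnot(is.numeric(tidal_volume), is.numeric(dead_space),
            is.numeric(resp_rate))
  if (!is.finite(resp_rate) || resp_rate <= 0) stop("`resp_rate` must be > 0")
  if (!is.finite(dead_space) || dead_space < 0 || tidal_volume <= dead_space)
    stop("volumes must satisfy V_T > V_D >= 0")
  structure(list(tidal_volume = tidal_volume, dead_space = dead_space,
                 resp_rate = resp_rate,
                 breath_period = 60 / resp_rate,
                 alveolar_ventilation = resp_rate * (tidal_volume - dead_space)),
            class = "ventilation_config")
}

#' Physiological lung and circulation parameters
#'
#' The "truth" (in simulation) or unknowns (in estimation) of the gas
#' exchange model. Blood flow that bypasses ventilated lung (shunt) takes
#' no part in tracer uptake, so the model only sees the effective flow
#' `Q_eff = Q * (1 - f_shunt)`.
#'
#' @param elv Effective lung volume ELV (L): end-expiratory alveolar gas
#'   volume participating in tracer exchange. Must be > 0.
#' @param cardiac_output Total cardiac output Q (L/min, >= 0).
#' @param shunt_fraction Fraction of Q bypassing ventilated lung, in
#'   [0, 1).
#' @param solubility Ostwald blood-gas partition coefficient of the tracer
#'   (dimensionless, > 0). Default 0.47, the body-temperature value for
#'   nitrous oxide.
#' @param venous_fraction Mixed-venous tracer fraction returning to the
#'   lung. Default 0: venous recirculation of the sinewave is assumed
#'   negligible at forcing periods under ~3 minutes. A nonzero value is a
#'   hook for studying the recirculation scaling error.
#'
#' @return An object of class `"lung_params"` with the derived
#'   `effective_flow` (L/min) included.
#' @export
#' @examples
#' lung_params(elv = 1.5, cardiac_output = 5)
#' lung_params(elv = 1.2, cardiac_output = 6, shunt_fraction = 0.3)
lung_params <- function(elv, cardiac_output, shunt_fraction = 0,
                        solubility = 0.47, venous_fraction = 0) {
  stopifnot(is.numeric(elv), is.numeric(cardiac_output),
            is.numeric(shunt_fraction), is.numeric(solubility),
            is.numeric(venous_fraction))
  if (!is.finite(elv) || elv <= 0) stop("`elv` must be > 0")
  if (!is.finite(cardiac_output) || cardiac_output < 0)
    stop("`cardiac_output` must be >= 0")
  if (!is.finite(shunt_fraction) || shunt_fraction < 0 || shunt_fraction >= 1)
    stop("`shunt_fraction` must lie in [0, 1)")
  if (!is.finite(solubility) || solubility <= 0)
    stop("`solubility` must be > 0")
  if (!is.finite(venous_fraction) || venous_fraction < 0 ||
      venous_fraction > 1)
    stop("`venous_fraction` must lie in [0, 1]")
  structure(list(elv = elv, cardiac_output = cardiac_output,
                 shunt_fraction = shunt_fraction, solubility = solubility,
                 venous_fraction = venous_fraction,
                 effective_flow = cardiac_output * (1 - shunt_fraction)),
            class = "lung_params")
}

#' @export
print.sinewave_config <- function(x, ...) {
  cat(sprintf("Inspired sinewave: mean %.3f, amplitude %.3f, period %g s\n",
              x$mean_fraction, x$amplitude, x$period))
  invisible(x)
}

#' @export
print.ventilation_config <- function(x, ...) {
  cat(sprintf(
    "Ventilation: V_T %.3f L, V_D %.3f L, %g breaths/min (V'A %.2f L/min)\n",
    x$tidal_volume, x$dead_space, x$resp_rate, x$alveolar_ventilation))
  invisible(x)
}

#' @export
print.lung_params <- function(x, ...) {
  cat(sprintf(
    "Lung: ELV %.2f L, Q %.2f L/min, shunt %.2f (Q_eff %.2f), lambda %.2f\n",
    x$elv, x$cardiac_output, x$shunt_fraction, x$effective_flow,
    x$solubility))
  invisible(x)
}
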