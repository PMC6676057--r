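#' Least-squares sinusoid fit at a known period
#'
#' Ordinary least squares on the basis `{1, sin(w t), cos(w t)}` with
#' `w = 2*pi/T_p`. The fit is reported as
#' `y ~ mean + amplitude * sin(w t + phase)` with `amplitude >= 0` and
#' `phase` in (-pi, pi].
#'
#' @param t Sample times (s).
#' @param y Sample values (gas fractions).
#' @param period Known forcing period T_p (s).
#' @return An object of class `"sinewave_fit"`: list with `mean_level`,
#'   `amplitude`, `phase`, `period`, `rms_residual`, `n_points`.
#' @export
#' @examples
#' t <- seq(0, 118, by = 4)
#' fit_sinusoid(t, 0.04 + 0.03 * sin(2 * pi * t / 60), period = 60)
fit_sinusoid <- function(t, y, period) {
  stopifnot(is.numeric(t), is.numeric(y), length(t) == length(y),
            is.numeric(period), period > 0)
  if (length(t) < 4L)
    warning("fewer than 4 samples; sinusoid fit is poorly determined")
  if (diff(range(t)) < period)
    warning("samples span less than one period; fit may be unreliable")
  w <- 2 * pi / period
  x <- cbind(1, sin(w * t), cos(w * t))
  qx <- qr(x)
  if (qx$rank < 3L)
    stop("rank-deficient design: samples do not resolve a sinusoid at this period")
  beta <- qr.coef(qx, y)
  res <- y - x %*% beta
  structure(list(mean_level = unname(beta[1]),
                 amplitude = sqrt(beta[2]^2 + beta[3]^2),
                 phase = atan2(beta[3], beta[2]),
                 period = period,
                 rms_residual = sqrt(mean(res^2)),
                 n_points = length(t)),
            class = "sinewave_fit")
}

#' @export
print.sinewave_fit <- function(x, ...) {
  cat(sprintf(
    "Sinusoid fit (T = %g s, n = %d): mean %.5f, amplitude %.5f, phase %.4f rad (rms %.2e)\n",
    x$period, x$n_points, x$mean_level, x$amplitude, x$phase, x$rms_residual))
  invisible(x)
}

# Objective of the inverse problem: squared mismatch between the observed
# (amplitude ratio, phase lag) and the tidal model's steady-state response.
inversion_objective <- function(par, robs, lobs, vent, wave, solubility) {
  tr <- tidal_transfer(par[1], par[2], vent, wave, solubility)
  (tr$amplitude_ratio - robs)^2 + (tr$phase_lag - lobs)^2
}

# Continuous closed-form seed for the search: invert amplitude ratio r and
# lag l analytically (V'A + lambda Q = V'A cos(l)/r, w ELV = V'A sin(l)/r).
continuous_seed <- function(robs, lobs, vent, wave, solubility) {
  va <- vent$alveolar_ventilation / 60
  w <- 2 * pi / wave$period
  lobs <- min(max(lobs, 1e-3), pi / 2 - 1e-3)
  robs <- min(max(robs, 1e-6), 1 - 1e-6)
  q <- (va * cos(lobs) / robs - va) * 60 / solubility
  elv <- va * sin(lobs) / (robs * w)
  c(q_eff = q, elv = elv)
}

#' Invert one window's sinusoid fits for blood flow and lung volume
#'
#' Finds the effective pulmonary blood flow and effective lung volume whose
#' tidal-model steady-state response best matches the observed expired /
#' inspired amplitude ratio and phase lag (squared mismatch, coarse grid
#' search seeded by the continuous closed form, then bounded local
#' refinement). Deterministic given its inputs.
#'
#' The mean-level ratio is deliberately not part of the default objective:
#' it is the observable most sensitive to sensor offset. Set
#' `use_mean_gain = TRUE` to add it.
#'
#' @param fit_inspired,fit_expired [fit_sinusoid()] results for the
#'   inspired and end-tidal series over the same window.
#' @param vent A [ventilation_config()].
#' @param wave A [sinewave_config()].
#' @param bounds List with elements `q_eff` and `elv`, each `c(lower,
#'   upper)`. Defaults cover the physiological range for 37-53 kg pigs and
#'   adult humans: Q_eff 0.5-25 L/min, ELV 0.2-5 L.
#' @param solubility Tracer Ostwald coefficient.
#' @param use_mean_gain Add the mean-level ratio as a third observable.
#' @param grid_n Points per axis of the coarse search grid.
#' @return List with `q_eff` (L/min), `elv` (L), `residual` (objective at
#'   the optimum) and `at_bound` (TRUE when the optimum sits on the box,
#'   e.g. for a lossless ratio-1 / lag-0 window).
#' @export
invert_window <- function(fit_inspired, fit_expired, vent, wave,
                          bounds = list(q_eff = c(0.5, 25), elv = c(0.2, 5)),
                          solubility = 0.47, use_mean_gain = FALSE,
                          grid_n = 9) {
  stopifnot(inherits(fit_inspired, "sinewave_fit"),
            inherits(fit_expired, "sinewave_fit"))
  if (fit_inspired$amplitude <= 0 || fit_expired$amplitude < 0)
    stop("fit amplitudes must be positive")
  robs <- fit_expired$amplitude / fit_inspired$amplitude
  if (robs > 1)
    warning("expired amplitude exceeds inspired amplitude (noise?); ",
            "estimate will sit at the lossless bound")
  lobs <- (fit_inspired$phase - fit_expired$phase) %% (2 * pi)
  obj <- if (use_mean_gain) {
    gobs <- fit_expired$mean_level / fit_inspired$mean_level
    function(par) {
      tr <- tidal_transfer(par[1], par[2], vent, wave, solubility)
      (tr$amplitude_ratio - robs)^2 + (tr$phase_lag - lobs)^2 +
        (tr$mean_gain - gobs)^2
    }
  } else {
    function(par) inversion_objective(par, robs, lobs, vent, wave, solubility)
  }
  lo <- c(bounds$q_eff[1], bounds$elv[1])
  hi <- c(bounds$q_eff[2], bounds$elv[2])
  # candidate starts: log-spaced coarse grid plus the closed-form seed
  qs <- exp(seq(log(lo[1]), log(hi[1]), length.out = grid_n))
  es <- exp(seq(log(lo[2]), log(hi[2]), length.out = grid_n))
  cand <- as.matrix(expand.grid(qs, es))
  seed <- continuous_seed(robs, lobs, vent, wave, solubility)
  cand <- rbind(cand, pmin(pmax(seed, lo), hi))
  vals <- apply(cand, 1, obj)
  start <- cand[which.min(vals), ]
  opt <- nlminb(start, obj, lower = lo, upper = hi,
                control = list(abs.tol = 0, rel.tol = 1e-12))
  at_bound <- any(abs(opt$par - lo) < 1e-8 * pmax(lo, 1)) ||
    any(abs(opt$par - hi) < 1e-8 * hi)
  list(q_eff = unname(opt$par[1]), elv = unname(opt$par[2]),
       residual = opt$objective, at_bound = at_bound)
}

#' Rolling-window cardiac output estimates
#'
#' Fits inspired and expired sinusoids on every trailing window of breath
#' data and inverts each for flow and lung volume, mirroring the monitor's
#' behaviour of reporting a value every 30 s computed from the previous
#' 3 minutes. Report times run from `window` to the end of the series in
#' steps of `stride`; windows with fewer than 4 breaths are skipped with a
#' warning.
#'
#' @param breaths A breath series (`data.frame` with `t_start_s`,
#'   `f_i_n2o`, `f_et_n2o`), e.g. from [simulate_breath_series()] or
#'   [read_breath_csv()].
#' @param vent,wave,bounds,solubility Passed to [invert_window()].
#' @param window Window span (s), default 180.
#' @param stride Report interval (s), default 30.
#' @return `data.frame` with `report_time_s`, `q_ist_lmin`, `elv_l`,
#'   `residual`, `at_bound`.
#' @export
rolling_estimates <- function(breaths, vent, wave, window = 180, stride = 30,
                              bounds = list(q_eff = c(0.5, 25), elv = c(0.2, 5)),
                              solubility = 0.47) {
  stopifnot(is.data.frame(breaths),
            all(c("t_start_s", "f_i_n2o", "f_et_n2o") %in% names(breaths)))
  t_end <- max(breaths$t_start_s) + vent$breath_period
  if (t_end < window) stop("breath series shorter than one window")
  report_times <- seq(window, t_end, by = stride)
  out <- vector("list", length(report_times))
  skipped <- 0L
  for (k in seq_along(report_times)) {
    tk <- report_times[k]
    sel <- breaths$t_start_s > tk - window & breaths$t_start_s <= tk
    if (sum(sel) < 4L) { skipped <- skipped + 1L; next }
    bi <- breaths[sel, ]
    fi <- fit_sinusoid(bi$t_start_s, bi$f_i_n2o, wave$period)
    fe <- fit_sinusoid(bi$t_start_s, bi$f_et_n2o, wave$period)
    inv <- invert_window(fi, fe, vent, wave, bounds, solubility)
    out[[k]] <- data.frame(report_time_s = tk, q_ist_lmin = inv$q_eff,
                           elv_l = inv$elv, residual = inv$residual,
                           at_bound = inv$at_bound)
  }
  if (skipped > 0L)
    warning(sprintf("%d window(s) skipped (<4 breaths)", skipped))
  do.call(rbind, out[!vapply(out, is.null, logical(1))])
}

#' Estimate the reporting delay of the rolling estimator
#'
#' Because each estimate averages the trailing window, the monitor
#' registers changes late. The delay is found by regression: for each
#' candidate lag, each reference measurement at time `t` is paired with the
#' estimate nearest to `t + lag` and the regression R^2 is computed; the
#' lag maximising R^2 wins (ties go to the smallest lag).
#'
#' @param q_ist `data.frame` from [rolling_estimates()].
#' @param q_ref Reference series: `data.frame` with columns `time_s` and
#'   `value` (or `q_t_lmin`).
#' @param max_lag,lag_step Search grid (s), defaults 180 and 5.
#' @return The winning lag (s), with the R^2 profile attached as attribute
#'   `"profile"`.
#' @export
estimate_delay <- function(q_ist, q_ref, max_lag = 180, lag_step = 5) {
  stopifnot(is.data.frame(q_ist), is.data.frame(q_ref))
  vcol <- if ("value" %in% names(q_ref)) "value" else "q_t_lmin"
  lags <- seq(0, max_lag, by = lag_step)
  r2 <- rep(NA_real_, length(lags))
  for (i in seq_along(lags)) {
    idx <- vapply(q_ref$time_s + lags[i],
                  function(tt) which.min(abs(q_ist$report_time_s - tt)),
                  integer(1))
    yi <- q_ist$q_ist_lmin[idx]
    yr <- q_ref[[vcol]]
    if (length(unique(idx)) < 3L || sd(yi) == 0 || sd(yr) == 0) next
    r2[i] <- cor(yr, yi)^2
  }
  if (all(is.na(r2))) stop("no lag admitted at least 3 pairable points")
  best <- lags[which.max(r2)]   # which.max takes the first maximum: smallest lag
  structure(best, profile = data.frame(lag_s = lags, r_squared = r2))
}

#' Pair reference measurements with delay-corrected estimates
#'
#' Each reference (thermodilution) measurement at time `t` is paired with
#' the estimate nearest to `t + lag`, provided the gap is within
#' `tolerance`; unmatched measurements are dropped with a message.
#'
#' @param thermo `data.frame` with `time_s` and `q_t_lmin` (accepted
#'   triplet means); a `subject_id` column is carried through if present.
#' @param q_ist `data.frame` from [rolling_estimates()].
#' @param lag Delay correction (s, >= 0), e.g. from [estimate_delay()].
#' @param tolerance Maximum time gap (s) for a valid pair, default 15.
#' @return `data.frame` with `subject_id` (if available), `time_s`,
#'   `q_t_lmin`, `q_ist_lmin`.
#' @export
pair_measurements <- function(thermo, q_ist, lag, tolerance = 15) {
  stopifnot(is.data.frame(thermo), is.data.frame(q_ist), lag >= 0)
  target <- thermo$time_s + lag
  idx <- vapply(target,
                function(tt) which.min(abs(q_ist$report_time_s - tt)),
                integer(1))
  gap <- abs(q_ist$report_time_s[idx] - target)
  keep <- gap <= tolerance
  if (any(!keep))
    message(sprintf("%d reference measurement(s) unmatched within %g s",
                    sum(!keep), tolerance))
  out <- data.frame(time_s = thermo$time_s[keep],
                    q_t_lmin = thermo$q_t_lmin[keep],
                    q_ist_lmin = q_ist$q_ist_lmin[idx[keep]])
  if ("subject_id" %in% names(thermo))
    out <- cbind(subject_id = thermo$subject_id[keep], out)
  out
}
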