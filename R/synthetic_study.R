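#' Configuration of a virtual porcine study
#'
#' Defines the conditions of the validation protocol the generator
#' emulates: eight anaesthetised pigs (37-53 kg) under volume-controlled
#' ventilation (tidal volume 8 ml/kg) with the inspired tracer sinewave
#' running throughout; a 10-minute baseline in which cardiac output
#' fluctuates by no more than 15%; an esmolol infusion dropping cardiac
#' output by at least 1 L/min; recovery; a dobutamine infusion raising it
#' by at least 3 L/min above baseline; and triplicate thermodilution every
#' 3-5 minutes, a triplet being accepted only when its three injections
#' agree within 10%. The lavage flag reproduces the saline lung-injury
#' condition by raising the shunt fraction.
#'
#' @param n_subjects Number of virtual animals, default 8.
#' @param weight_range Body weight range (kg), default `c(37, 53)`.
#' @param baseline_q_range Baseline cardiac output range (L/min).
#' @param baseline_duration Length of the baseline plateau (s).
#' @param esmolol_drop Range (L/min) of the esmolol-induced fall, each at
#'   least 1 L/min below baseline.
#' @param dobutamine_rise Range (L/min) of the dobutamine-induced rise,
#'   each at least 3 L/min above baseline.
#' @param transition_tau Time constant (s) of the exponential
#'   haemodynamic transitions.
#' @param total_duration Protocol length (s).
#' @param thermo_interval Range (s) of the interval between thermodilution
#'   triplets, default `c(180, 300)`.
#' @param thermo_cv Coefficient of variation of a single thermodilution
#'   injection, default 0.05 (typical triplicate variability).
#' @param sensor_noise_sd End-tidal sensor noise SD (fraction units).
#' @param lavage Logical; if `TRUE` the shunt fraction is drawn from
#'   `shunt_range` (saline-lavage lung injury), otherwise from the small
#'   physiological range `c(0.02, 0.05)`.
#' @param shunt_range Post-lavage shunt fraction range.
#' @param resp_rate Respiratory rate (breaths/min), fixed through the
#'   protocol.
#' @param wave The inspired forcing, a [sinewave_config()].
#' @param wobble_sd,wobble_clip AR(1) baseline wobble: stationary SD and
#'   hard clip, both as fractions of the baseline cardiac output.
#' @param seed Integer seed making the whole study reproducible.
#' @return An object of class `"scenario_config"`.
#' @export
scenario_config <- function(n_subjects = 8, weight_range = c(37, 53),
                            baseline_q_range = c(3.5, 5.5),
                            baseline_duration = 600,
                            esmolol_drop = c(1.3, 1.8),
                            dobutamine_rise = c(3.3, 4.2),
                            transition_tau = 45,
                            total_duration = 2100,
                            thermo_interval = c(180, 300),
                            thermo_cv = 0.05,
                            sensor_noise_sd = 0.001,
                            lavage = FALSE,
                            shunt_range = c(0.15, 0.35),
                            resp_rate = 15,
                            wave = sinewave_config(),
                            wobble_sd = 0.015, wobble_clip = 0.05,
                            seed = 1) {
  esmolol_drop <- rep(esmolol_drop, length.out = 2)
  dobutamine_rise <- rep(dobutamine_rise, length.out = 2)
  if (min(esmolol_drop) < 1)
    stop("esmolol must drop cardiac output by at least 1 L/min")
  if (min(dobutamine_rise) < 3)
    stop("dobutamine must raise cardiac output by at least 3 L/min")
  if (min(baseline_q_range) <= max(esmolol_drop) + 0.5)
    stop("infeasible: esmolol drop would push cardiac output near zero")
  if (wobble_clip > 0.075)
    stop("wobble clip above 7.5% cannot guarantee the 15% baseline fluctuation bound")
  structure(list(n_subjects = n_subjects, weight_range = weight_range,
                 baseline_q_range = baseline_q_range,
                 baseline_duration = baseline_duration,
                 esmolol_drop = esmolol_drop,
                 dobutamine_rise = dobutamine_rise,
                 transition_tau = transition_tau,
                 total_duration = total_duration,
                 thermo_interval = thermo_interval, thermo_cv = thermo_cv,
                 sensor_noise_sd = sensor_noise_sd, lavage = lavage,
                 shunt_range = shunt_range, resp_rate = resp_rate,
                 wave = wave, wobble_sd = wobble_sd,
                 wobble_clip = wobble_clip, seed = seed),
            class = "scenario_config")
}

#' True cardiac output trajectory for one virtual animal
#'
#' Piecewise-smooth trajectory on a 1-second grid: baseline plateau with a
#' slow AR(1) wobble (clipped so the baseline never fluctuates beyond the
#' protocol's 15% bound), an exponential fall under esmolol, recovery to
#' baseline, and an exponential rise under dobutamine, all with time
#' constant `transition_tau`. Draws from the current RNG stream.
#'
#' @param cfg A [scenario_config()].
#' @param baseline_q Baseline cardiac output (L/min); drawn from
#'   `cfg$baseline_q_range` when `NULL`.
#' @return List with `time` (s), `q` (L/min), `baseline_q`, `drop`,
#'   `rise`, and the segment boundaries `segments` (named numeric, s).
#' @export
make_trajectory <- function(cfg, baseline_q = NULL) {
  stopifnot(inherits(cfg, "scenario_config"))
  if (is.null(baseline_q))
    baseline_q <- runif(1, cfg$baseline_q_range[1], cfg$baseline_q_range[2])
  drop <- runif(1, cfg$esmolol_drop[1], cfg$esmolol_drop[2])
  rise <- runif(1, cfg$dobutamine_rise[1], cfg$dobutamine_rise[2])
  if (drop >= baseline_q)
    stop("infeasible: esmolol drop exceeds baseline cardiac output")
  tt <- seq(0, cfg$total_duration, by = 1)
  # segment boundaries scale with the protocol length around the baseline
  t1 <- cfg$baseline_duration
  rem <- cfg$total_duration - t1
  seg <- c(baseline_end = t1,
           esmolol_end = t1 + 0.30 * rem,
           recovery_end = t1 + 0.50 * rem)
  tau <- cfg$transition_tau
  targets <- c(baseline_q, baseline_q - drop, baseline_q, baseline_q + rise)
  starts <- c(0, seg)
  q <- numeric(length(tt))
  level <- baseline_q
  for (s in seq_along(starts)) {
    lo <- starts[s]
    hi <- if (s < length(starts)) starts[s + 1] else cfg$total_duration + 1
    idx <- tt >= lo & tt < hi + (s == length(starts))
    q[idx] <- targets[s] + (level - targets[s]) * exp(-(tt[idx] - lo) / tau)
    level <- targets[s] + (level - targets[s]) *
      exp(-(min(hi, cfg$total_duration) - lo) / tau)
  }
  # slow multiplicative AR(1) wobble, clipped relative to baseline
  rho <- exp(-1 / 60)
  eps_sd <- cfg$wobble_sd * baseline_q * sqrt(1 - rho^2)
  w <- numeric(length(tt))
  w[1] <- rnorm(1, 0, cfg$wobble_sd * baseline_q)
  for (i in seq_along(tt)[-1]) w[i] <- rho * w[i - 1] + rnorm(1, 0, eps_sd)
  w <- pmin(pmax(w, -cfg$wobble_clip * baseline_q), cfg$wobble_clip * baseline_q)
  list(time = tt, q = pmax(q + w, 0.1), baseline_q = baseline_q,
       drop = drop, rise = rise, segments = seg)
}

#' One triplicate thermodilution measurement
#'
#' Draws three injections `true_q * (1 + e)`, `e ~ N(0, cv^2)`. The
#' triplet is accepted only when its spread `(max - min)/mean` is within
#' 10%; otherwise it is redrawn up to `max_attempts` times and finally
#' marked unaccepted. The reported value is the mean of the accepted
#' triplet.
#'
#' @param true_q True cardiac output at injection time (L/min).
#' @param cv Per-injection coefficient of variation (>= 0).
#' @param max_attempts Redraw limit, default 5.
#' @return List with `triplet` (length 3), `q_t` (mean), `accepted`,
#'   `attempts`.
#' @export
thermodilution_triplet <- function(true_q, cv, max_attempts = 5) {
  stopifnot(true_q > 0, cv >= 0)
  for (k in seq_len(max_attempts)) {
    tri <- true_q * (1 + rnorm(3, 0, cv))
    if ((max(tri) - min(tri)) / mean(tri) <= 0.10)
      return(list(triplet = tri, q_t = mean(tri), accepted = TRUE,
                  attempts = k))
  }
  list(triplet = tri, q_t = mean(tri), accepted = FALSE,
       attempts = max_attempts)
}

# Breath simulation with a time-varying cardiac output (quasi-static: each
# breath uses the instantaneous effective flow at its start time).
simulate_study_breaths <- function(traj, f_shunt, elv, vent, wave,
                                   sensor_noise_sd, solubility = 0.47) {
  tb <- vent$breath_period
  n <- floor(max(traj$time) / tb)
  t_n <- (seq_len(n) - 1) * tb
  q_n <- approx(traj$time, traj$q, xout = t_n, rule = 2)$y
  f_i <- inspired_waveform(t_n, wave)
  sim <- breath_recursion(f_i, q_n * (1 - f_shunt), elv, vent$tidal_volume,
                          vent$dead_space, tb, solubility, 0)
  f_et <- sim$f_a
  if (sensor_noise_sd > 0)
    f_et <- pmin(pmax(f_et + rnorm(n, 0, sensor_noise_sd), 0), 1)
  data.frame(breath_index = seq_len(n) - 1L, t_start_s = t_n, f_i_n2o = f_i,
             f_et_n2o = f_et, f_a_n2o = sim$f_a)
}

#' Generate a complete virtual study
#'
#' For each virtual animal: draws weight, baseline cardiac output, shunt
#' fraction and effective lung volume; builds the haemodynamic trajectory;
#' runs the forward lung simulation (quasi-static coupling of the slowly
#' varying effective flow to the breath-by-breath recursion) with sensor
#' noise; and samples triplicate thermodilution at random 3-5 minute
#' intervals. Fully deterministic given `cfg$seed`.
#'
#' @param cfg A [scenario_config()].
#' @return An object of class `"ist_virtual_study"`: list with `cfg` and
#'   `subjects`, each subject holding `id`, `weight`, `elv`, `f_shunt`,
#'   `vent`, `breaths`, `thermo` (one row per triplet: `subject_id`,
#'   `time_s`, `q1`..`q3`, `q_t_lmin`, `accepted`, `true_q_lmin`) and
#'   `truth` (1-s grid: `time_s`, `q_lmin`, `q_eff_lmin`).
#' @export
#' @examples
#' \donttest{
#' study <- run_virtual_study(scenario_config(n_subjects = 2, seed = 7))
#' str(study$subjects[[1]]$thermo)
#' }
run_virtual_study <- function(cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  set.seed(cfg$seed)
  subjects <- vector("list", cfg$n_subjects)
  for (i in seq_len(cfg$n_subjects)) {
    weight <- runif(1, cfg$weight_range[1], cfg$weight_range[2])
    vent <- ventilation_config(weight = weight, resp_rate = cfg$resp_rate)
    elv <- weight * runif(1, 0.025, 0.035)     # end-expiratory volume scales with size
    f_shunt <- if (cfg$lavage)
      runif(1, cfg$shunt_range[1], cfg$shunt_range[2])
    else runif(1, 0.02, 0.05)
    traj <- make_trajectory(cfg)
    breaths <- simulate_study_breaths(traj, f_shunt, elv, vent, cfg$wave,
                                      cfg$sensor_noise_sd)
    # thermodilution schedule: first triplet mid-baseline, then every 3-5 min
    times <- c()
    tnext <- runif(1, 60, 180)
    while (tnext <= cfg$total_duration - 30) {
      times <- c(times, tnext)
      tnext <- tnext + runif(1, cfg$thermo_interval[1], cfg$thermo_interval[2])
    }
    thermo <- do.call(rbind, lapply(times, function(tm) {
      tq <- approx(traj$time, traj$q, xout = tm, rule = 2)$y
      tri <- thermodilution_triplet(tq, cfg$thermo_cv)
      data.frame(subject_id = i, time_s = tm, q1 = tri$triplet[1],
                 q2 = tri$triplet[2], q3 = tri$triplet[3],
                 q_t_lmin = tri$q_t, accepted = tri$accepted,
                 true_q_lmin = tq)
    }))
    subjects[[i]] <- list(id = i, weight = weight, elv = elv,
                          f_shunt = f_shunt, baseline_q = traj$baseline_q,
                          vent = vent, breaths = breaths, thermo = thermo,
                          truth = data.frame(time_s = traj$time,
                                             q_lmin = traj$q,
                                             q_eff_lmin = traj$q * (1 - f_shunt)))
  }
  structure(list(cfg = cfg, subjects = subjects), class = "ist_virtual_study")
}

#' @export
print.ist_virtual_study <- function(x, ...) {
  cat(sprintf(
    "Virtual study: %d subjects, %g s protocol, lavage %s, seed %d\n",
    length(x$subjects), x$cfg$total_duration,
    if (x$cfg$lavage) "on" else "off", x$cfg$seed))
  invisible(x)
}

#' Packaged baseline characteristics of the porcine cohort
#'
#' Loads the per-animal baseline haemodynamic and respiratory record of
#' the eight-animal porcine validation cohort that the synthetic study
#' emulates (weight, heart rate, blood pressures, both cardiac output
#' readings, gas exchange variables, ...), transcribed into a plain-text
#' fixture, together with each variable's printed cohort mean.
#'
#' @return `data.frame` with one row per variable: `variable`,
#'   `animal1`..`animal8`, `printed_mean`.
#' @seealso [table1_summary()]
#' @export
porcine_baseline <- function() {
  path <- system.file("extdata", "porcine_baseline_table.csv",
                      package = "istco", mustWork = TRUE)
  read.csv(path, stringsAsFactors = FALSE)
}

#' Per-variable cohort means at printed precision
#'
#' Arithmetic mean of the per-animal values for each baseline variable,
#' rounded half-up to the precision used in the cohort table (inferred
#' from the decimal places of the tabulated mean).
#'
#' @param records `data.frame` in the layout of [porcine_baseline()]
#'   (columns `variable`, `animal1`..`animalN`, and `printed_mean` whose
#'   decimals set the rounding; the means themselves are recomputed).
#' @return Named numeric vector of rounded means.
#' @export
#' @examples
#' table1_summary(porcine_baseline())[c("weight_kg", "qt_lmin")]
table1_summary <- function(records) {
  stopifnot(is.data.frame(records), "variable" %in% names(records))
  acols <- grep("^animal", names(records), value = TRUE)
  stopifnot(length(acols) >= 1)
  vals <- as.matrix(records[, acols])
  m <- rowMeans(vals)
  digits <- vapply(as.character(records$printed_mean), function(s) {
    dot <- regexpr(".", s, fixed = TRUE)
    if (dot < 0) 0L else nchar(s) - dot
  }, integer(1))
  # round half-up at the table's precision (base round() is half-even)
  rounded <- floor(m * 10^digits + 0.5) / 10^digits
  setNames(rounded, records$variable)
}
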