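# Shared builders for the test suite. Default objects mirror the study's
# operating point: 4% / 3% / 60 s forcing, 8 ml/kg ventilation at 15
# breaths/min, a mid-sized pig's lung.

default_wave <- function(...) sinewave_config(...)

default_vent <- function() {
  ventilation_config(tidal_volume = 0.32, dead_space = 0.12, resp_rate = 15)
}

default_lung <- function(q = 5, elv = 1.5, shunt = 0) {
  lung_params(elv = elv, cardiac_output = q, shunt_fraction = shunt)
}

# Simulate to periodic steady state and measure the expired sinewave over
# the last `n_periods` forcing periods.
steady_fits <- function(lung, vent, wave, warmup_periods = 10,
                        n_periods = 3) {
  dur <- (warmup_periods + n_periods) * wave$period
  b <- simulate_breath_series(lung, vent, wave, duration = dur)
  sel <- b$t_start_s >= warmup_periods * wave$period
  list(inspired = fit_sinusoid(b$t_start_s[sel], b$f_i_n2o[sel], wave$period),
       expired = fit_sinusoid(b$t_start_s[sel], b$f_et_n2o[sel], wave$period))
}

# Toy paired-measurement table: one row per (subject, time).
make_pairs <- function(q_t, q_ist, subject_id = 1L,
                       time_s = seq_along(q_t) * 60) {
  data.frame(subject_id = subject_id, time_s = time_s,
             q_t_lmin = q_t, q_ist_lmin = q_ist)
}

# Delta table in the shape delta_pairs() produces.
make_deltas <- function(dq_t, dq_ist) {
  data.frame(subject_id = 1L, time_s = seq_along(dq_t) * 60,
             dq_t = dq_t, dq_ist = dq_ist, radius = (dq_t + dq_ist) / 2)
}
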