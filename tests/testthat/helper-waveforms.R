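# Analytic waveform builders used as independent oracles.

# wrap a bare voltage vector as a sweep (zero-current unless stated)
sweep_of <- function(voltage, rate = 50000, amp = 0,
                     onset = NULL, offset = NULL) {
  dur <- 1000 * length(voltage) / rate
  new_sweep(voltage, rate,
            step_amplitude = amp,
            step_onset = onset %||% 0,
            step_offset = offset %||% dur)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# isosceles-triangle spike: baseline, linear rise to peak, linear fall back
triangle_spike <- function(base_v = -35, peak_v = 45, half_base_ms = 1,
                           rate = 50000, pad_ms = 2) {
  dt <- 1000 / rate
  up <- seq(base_v, peak_v, length.out = round(half_base_ms / dt) + 1)
  v <- c(rep(base_v, round(pad_ms / dt)), up, rev(up)[-1],
         rep(base_v, round(pad_ms / dt)))
  sweep_of(v, rate)
}

# Gaussian bump of given sd (ms) on a flat baseline
gaussian_spike <- function(sigma_ms = 0.4, amp_mv = 100, base_v = -70,
                           rate = 50000, span_ms = 8) {
  t <- seq(0, span_ms, by = 1000 / rate)
  v <- base_v + amp_mv * exp(-(t - span_ms / 2)^2 / (2 * sigma_ms^2))
  sweep_of(v, rate)
}

# Biphasic upstroke: sum of two time-shifted sigmoids (AIS then SD
# component) with closed-form first and second derivatives.
two_sigmoid <- function(a1 = 48, t1 = 4, tau1 = 0.12,
                        a2 = 110, t2 = 4.4, tau2 = 0.06,
                        v0 = -70, rate = 50000, span_ms = 8) {
  s <- function(t, tc, tau) 1 / (1 + exp(-(t - tc) / tau))
  f <- function(t) v0 + a1 * s(t, t1, tau1) + a2 * s(t, t2, tau2)
  fp <- function(t) {
    s1 <- s(t, t1, tau1); s2 <- s(t, t2, tau2)
    a1 / tau1 * s1 * (1 - s1) + a2 / tau2 * s2 * (1 - s2)
  }
  fpp <- function(t) {
    s1 <- s(t, t1, tau1); s2 <- s(t, t2, tau2)
    a1 / tau1^2 * s1 * (1 - s1) * (1 - 2 * s1) +
      a2 / tau2^2 * s2 * (1 - s2) * (1 - 2 * s2)
  }
  tgrid <- seq(0, span_ms, by = 1000 / rate)
  list(sweep = sweep_of(f(tgrid), rate), f = f, fp = fp, fpp = fpp,
       t1 = t1, t2 = t2, rate = rate)
}

# analytic oracles for the two-sigmoid waveform -----------------------------

# time and voltage where the analytic dV/dt first reaches `crit` (V/s)
ts_threshold_oracle <- function(w, crit = 20) {
  t20 <- stats::uniroot(function(t) w$fp(t) - crit,
                        lower = w$t1 - 1.5, upper = w$t1,
                        tol = 1e-10)$root
  list(time = t20, voltage = w$f(t20))
}

# analytic breakpoint: argmin of f'' between the threshold time and the
# time of the dV/dt maximum (fine-grid argmin of the closed form)
ts_breakpoint_oracle <- function(w, crit = 20) {
  thr <- ts_threshold_oracle(w, crit)
  tg <- seq(thr$time, w$t2 + 1, by = 1e-4)
  tb_max <- tg[which.max(w$fp(tg))]
  tg2 <- seq(thr$time, tb_max, by = 1e-4)
  tbp <- tg2[which.min(w$fpp(tg2))]
  list(time = tbp, dvdt = w$fp(tbp),
       b = max(w$fp(tg)), t_bmax = tb_max)
}
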