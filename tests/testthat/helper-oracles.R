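# Brute-force re-implementations of the measurement definitions, operating
# on raw sample arrays with no interpolation or guards.  They stay
# independent of the production code paths they check.

bf_dvdt <- function(v, rate) {
  dt <- 1000 / rate
  n <- length(v)
  c((v[2] - v[1]) / dt,
    (v[3:n] - v[1:(n - 2)]) / (2 * dt),
    (v[n] - v[n - 1]) / dt)
}

# threshold: last sample before the peak whose dV/dt is below 20, + 1
bf_threshold <- function(v, rate, peak_i, crit = 20) {
  d <- bf_dvdt(v, rate)
  i <- peak_i
  while (i > 1 && d[i] < crit) i <- i - 1
  while (i > 1 && d[i] >= crit) i <- i - 1
  if (d[i] >= crit) return(NULL)
  v[i + 1]
}

# half-width by raw sample counting at threshold + amplitude/2
bf_half_width <- function(v, rate, peak_i, thr_v) {
  half <- thr_v + (v[peak_i] - thr_v) / 2
  i <- peak_i; while (i > 1 && v[i] >= half) i <- i - 1
  j <- peak_i; while (j < length(v) && v[j] >= half) j <- j + 1
  (j - i) * 1000 / rate
}

# mAHP: raw minimum over (peak, peak + 100 ms], truncated at limit_ms
bf_mahp <- function(v, rate, peak_i, thr_v, limit_ms = Inf) {
  dt <- 1000 / rate
  t_end <- min((peak_i - 1) * dt + 100, limit_ms)
  i1 <- min(length(v), floor(t_end / dt) + 1)
  if (i1 <= peak_i) return(NA_real_)
  thr_v - min(v[(peak_i + 1):i1])
}

# exact two-sided Mann-Whitney p by enumeration of all rank assignments
mw_enumeration_p <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  u_of <- function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2
  u_obs <- u_of(seq_len(n1))
  combos <- utils::combn(n1 + n2, n1)
  mu <- n1 * n2 / 2
  us <- apply(combos, 2, u_of)
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}
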