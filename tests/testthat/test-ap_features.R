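# Spike detection, single-AP waveform measurements, train metrics.

test_that("spike detection finds peaks with a refractory guard", {
  sub <- sweep_of(rep(-65, 1000))
  expect_equal(nrow(detect_spikes(sub)), 0)

  # two merged depolarizations that never repolarize below the criterion
  rate <- 50000
  v <- c(rep(-70, 100),
         seq(-70, 30, length.out = 50), seq(30, 5, length.out = 30),
         seq(5, 40, length.out = 30), seq(40, -70, length.out = 60),
         rep(-70, 100))
  expect_equal(nrow(detect_spikes(sweep_of(v, rate))), 1)

  # simulated 7-AP train: 7 events, within 1 ms of ground truth
  sim <- default_cell()
  sel <- find_n_spike_sweep(sim$recording, 7)
  det <- detect_spikes(sel$sweep)
  truth <- sim$truth$spike_times[[sel$sweep_index]]
  expect_equal(nrow(det), 7)
  expect_lt(max(abs(det$peak_time - truth)), 1)
})

test_that("threshold at 20 V/s is recovered on an analytic biphasic waveform", {
  w <- two_sigmoid()
  oracle <- ts_threshold_oracle(w)
  det <- detect_spikes(w$sweep)
  thr <- ap_threshold(w$sweep, det$peak_index[1])
  expect_equal(thr$voltage, oracle$voltage, tolerance = 0.2 / abs(oracle$voltage))

  # resolution robustness: doubling the sampling rate moves it < 0.2 mV
  w2 <- two_sigmoid(rate = 100000)
  det2 <- detect_spikes(w2$sweep)
  thr2 <- ap_threshold(w2$sweep, det2$peak_index[1])
  expect_lt(abs(thr2$voltage - thr$voltage), 0.2)

  # a 10 V/s linear ramp never reaches the criterion: rejected as non-spike
  t <- seq(0, 12, by = 0.02)
  ramp <- sweep_of(-70 + 10 * t)
  detr <- detect_spikes(ramp)
  expect_gte(nrow(detr), 1)
  expect_null(ap_threshold(ramp, detr$peak_index[1]))
})

test_that("AP shape follows geometry on constructed spikes", {
  # isosceles triangle: threshold -35, peak +45, 2 ms base
  tri <- triangle_spike(base_v = -35, peak_v = 45, half_base_ms = 1)
  det <- detect_spikes(tri)
  thr <- list(voltage = -35, time = 2, index = 101)  # rise starts after 2 ms pad
  sh <- ap_shape(tri, det$peak_index[1], thr)
  expect_equal(sh$peak_amplitude, 80, tolerance = 1e-6)
  expect_equal(sh$half_width, 1.0, tolerance = 0.03)
  # symmetric spike: dvdt_max = -dvdt_min
  expect_equal(sh$dvdt_max, -sh$dvdt_min, tolerance = 1e-6)

  # Gaussian bump of sd sigma: FWHM = 2.355 sigma (threshold at baseline)
  sigma <- 0.4
  g <- gaussian_spike(sigma_ms = sigma)
  detg <- detect_spikes(g)
  shg <- ap_shape(g, detg$peak_index[1],
                  list(voltage = -70, time = 0, index = 1))
  expect_equal(shg$half_width, 2 * sqrt(2 * log(2)) * sigma,
               tolerance = 0.02 / 0.94)
})

test_that("mAHP is the trough below threshold within its 100 ms window", {
  rate <- 10000
  dt <- 1000 / rate
  # monotone decay to threshold - 17 within 40 ms
  spike <- c(seq(-50, 40, length.out = 20), seq(40, -50, length.out = 20))
  decay <- -52 + (-50 - (-52)) * exp(-(seq_len(1500) * dt) / 10)
  v <- c(rep(-50, 100), spike, decay, rep(-52, 500))
  sw <- sweep_of(v, rate)
  pk <- which.max(v)
  thr <- list(voltage = -35, time = (100 - 1) * dt, index = 100)
  expect_equal(as.numeric(ap_mahp(sw, pk, thr)), 17, tolerance = 1e-3)

  # deeper trough at 120 ms is outside the window; shallower one at 80 ms wins
  v2 <- rep(-37, 3000)
  v2[1:40] <- c(seq(-37, 40, length.out = 20), seq(40, -37, length.out = 20))
  i80 <- round(80 / dt); i120 <- round(120 / dt)
  v2[(i80 - 5):(i80 + 5)] <- -40   # -5 mV below threshold -35
  v2[(i120 - 5):(i120 + 5)] <- -60
  sw2 <- sweep_of(v2, rate)
  thr2 <- list(voltage = -35, time = 0, index = 1)
  m <- ap_mahp(sw2, which.max(v2), thr2)
  expect_equal(as.numeric(m), 5, tolerance = 1e-6)

  # truncation at the next spike's threshold time
  m_trunc <- ap_mahp(sw2, which.max(v2), thr2, next_threshold_time = 50)
  expect_equal(attr(m_trunc, "truncated_at"), "next_spike")
  expect_equal(as.numeric(m_trunc), 2, tolerance = 1e-6)  # baseline -37

  # doubling gSK strictly deepens the simulated mAHP
  proto <- short_protocol(seq(100, 300, 50), duration = 500)
  m_of <- function(gsk) {
    rec <- simulate_cell(neuron_params(gSK = gsk), proto, seed = 3)$recording
    rb <- find_rheobase(rec)
    ap_feature_table(rec$sweeps[[rb$sweep_index]])$mahp[1]
  }
  expect_gt(m_of(50), m_of(25))
})

test_that("rheobase is the smallest spiking step on the ladder", {
  flat <- function(amp) sweep_of(rep(-65, 5000), amp = amp,
                                 onset = 10, offset = 90)
  spiky <- function(amp) {
    v <- rep(-65, 5000)
    v[1500:1578] <- c(seq(-65, 40, length.out = 40),
                      seq(40, -65, length.out = 40))[-40]
    sweep_of(v, amp = amp, onset = 10, offset = 90)
  }
  rec <- new_recording(list(flat(100), spiky(110), spiky(120)))
  rb <- find_rheobase(rec)
  expect_equal(rb$rheobase, 110)
  expect_false(rb$ladder_floor)
  expect_equal(rb$increment, 10)

  # lowest sweep already spikes: flagged ladder floor
  rec2 <- new_recording(list(spiky(50), spiky(100)))
  expect_true(find_rheobase(rec2)$ladder_floor)

  # nothing spikes
  rec3 <- new_recording(list(flat(100)))
  expect_null(find_rheobase(rec3))
})

test_that("ladder rheobase sits within one increment of continuous bisection", {
  sim <- default_cell()
  rb <- find_rheobase(sim$recording)
  proto1 <- function(a) short_protocol(a, duration = 500)
  spikes_at <- function(a) {
    rec <- simulate_cell(neuron_params(), proto1(a), seed = 7)$recording
    nrow(detect_spikes(rec$sweeps[[1]])) >= 1
  }
  lo <- 50; hi <- rb$rheobase
  while (hi - lo > 2) {
    mid <- (lo + hi) / 2
    if (spikes_at(mid)) hi <- mid else lo <- mid
  }
  expect_lte(abs(rb$rheobase - hi), rb$increment)
})

test_that("the n-spike sweep selector prefers exact counts, then below, lowest current", {
  train_sweep <- function(amp, k) {
    v <- rep(-65, 25000)
    for (s in seq_len(k)) {
      i0 <- 2000 + (s - 1) * 2500
      v[i0:(i0 + 78)] <- c(seq(-65, 40, length.out = 40),
                           seq(40, -65, length.out = 40))[-40]
    }
    sweep_of(v, amp = amp, onset = 10, offset = 480)
  }
  counts <- c(1, 3, 7, 12)
  rec <- new_recording(mapply(train_sweep, c(100, 150, 200, 250), counts,
                              SIMPLIFY = FALSE))
  sel <- find_n_spike_sweep(rec, 7)
  expect_equal(sel$current, 200); expect_true(sel$exact)

  rec2 <- new_recording(mapply(train_sweep, c(100, 150, 200, 250),
                               c(1, 3, 6, 8), SIMPLIFY = FALSE))
  sel2 <- find_n_spike_sweep(rec2, 7)
  expect_equal(sel2$n_spikes, 6); expect_false(sel2$exact)

  rec3 <- new_recording(mapply(train_sweep, c(100, 150, 200),
                               c(7, 7, 9), SIMPLIFY = FALSE))
  sel3 <- find_n_spike_sweep(rec3, 7)
  expect_equal(sel3$current, 100)  # tie-break: lowest current
})

test_that("ISI metrics and accommodation follow their definitions", {
  expect_equal(isi_accommodation(seq(0, 180, 30))$accommodation_ratio, 0)
  acc <- isi_accommodation(c(0, 20, 60, 100, 140, 180, 220))
  expect_equal(acc$isi_1, 20)
  expect_equal(acc$isi_6, 40)
  expect_equal(acc$accommodation_ratio, 0.5)
  acc2 <- isi_accommodation(c(0, 50, 92, 133, 173, 213, 253))
  expect_equal(acc2$accommodation_ratio, (40 - 50) / 40)  # negative allowed
  expect_true(is.na(isi_accommodation(c(0, 30))$accommodation_ratio))
})

test_that("the I-F curve matches simulator ground truth and is monotone", {
  sim <- default_cell()
  fi <- fi_curve(sim$recording)
  truth_counts <- vapply(sim$truth$spike_times, length, integer(1))
  amps <- vapply(sim$recording$sweeps, `[[`, numeric(1), "step_amplitude")
  expect_equal(fi$n_spikes, truth_counts[amps > 0][order(amps[amps > 0])])
  expect_true(all(diff(fi$n_spikes) >= 0))

  subthr <- new_recording(lapply(c(50, 100), function(a)
    sweep_of(rep(-65, 1000), amp = a, onset = 2, offset = 18)))
  expect_true(all(fi_curve(subthr)$n_spikes == 0))

  # rate variant: counts over the 0.5 s step = 2x count in Hz
  fir <- fi_curve(sim$recording, as_rate = TRUE)
  expect_equal(fir$rate, fi$n_spikes / 0.5)
})

test_that("production extractor agrees with brute-force raw-array oracles", {
  sim <- default_cell()
  rb <- find_rheobase(sim$recording)
  sel <- find_n_spike_sweep(sim$recording, 7)
  for (sw in list(sim$recording$sweeps[[rb$sweep_index]], sel$sweep)) {
    tab <- ap_feature_table(sw)
    det <- detect_spikes(sw)
    for (k in seq_len(nrow(tab))) {
      pk <- det$peak_index[k]
      bf_thr <- bf_threshold(sw$voltage, sw$sampling_rate, pk)
      expect_lt(abs(tab$threshold_voltage[k] - bf_thr), 0.5)
      bf_hw <- bf_half_width(sw$voltage, sw$sampling_rate, pk,
                             tab$threshold_voltage[k])
      expect_lt(abs(tab$half_width[k] - bf_hw), 2 * 1000 / sw$sampling_rate)
      lim <- if (k < nrow(tab)) tab$threshold_time[k + 1] else sw$step_offset
      bf_m <- bf_mahp(sw$voltage, sw$sampling_rate, pk,
                      tab$threshold_voltage[k], limit_ms = lim)
      expect_equal(tab$mahp[k], bf_m, tolerance = 0.5 / max(bf_m, 1))
    }
  }
})

test_that("latency, half-width and mAHP are invariant to a constant voltage offset", {
  sim <- default_cell()
  sel <- find_n_spike_sweep(sim$recording, 7)
  sw <- sel$sweep
  sw_shift <- new_sweep(sw$voltage + 3, sw$sampling_rate, sw$step_amplitude,
                        sw$step_onset, sw$step_offset)
  a <- ap_feature_table(sw)
  b <- ap_feature_table(sw_shift)
  expect_equal(nrow(a), nrow(b))
  expect_equal(b$threshold_voltage, a$threshold_voltage + 3, tolerance = 1e-8)
  expect_equal(b$peak_voltage, a$peak_voltage + 3, tolerance = 1e-8)
  expect_equal(b$threshold_time, a$threshold_time, tolerance = 1e-8)
  expect_equal(b$half_width, a$half_width, tolerance = 1e-8)
  expect_equal(b$mahp, a$mahp, tolerance = 1e-8)
})
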