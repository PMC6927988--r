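# Phase-plane decomposition of the AP rising phase.

test_that("phase-plane samples span threshold to repolarization", {
  # triangular spike: constant slopes -> a two-valued rectangle in (V, dV/dt)
  tri <- triangle_spike(base_v = -35, peak_v = 45, half_base_ms = 1)
  det <- detect_spikes(tri)
  thr <- list(voltage = -35, time = 2, index = 101)
  pp <- phase_plot(tri, det$peak_index[1], thr)
  slopes <- unique(round(pp$dvdt[abs(pp$dvdt) > 1], 3))
  expect_lte(length(slopes), 4)  # +slope, -slope and the corner samples
  expect_equal(max(pp$dvdt), 80, tolerance = 0.01)   # 80 mV / 1 ms
  expect_equal(min(pp$dvdt), -80, tolerance = 0.01)

  # constant trace: all dV/dt zero
  flat <- sweep_of(rep(-60, 1000))
  expect_true(all(dvdt(flat$voltage, flat$sampling_rate) == 0))

  # simulated AP traverses the loop clockwise: positive then negative dV/dt
  sim <- default_cell()
  fa <- first_ap_of_train(sim$recording)
  pps <- phase_plot(fa$sweep, fa$peak_index, fa$threshold)
  expect_gt(max(pps$dvdt), 100)
  expect_lt(min(pps$dvdt), -50)
})

test_that("breakpoint matches the analytic second-derivative argmin within one sample", {
  w <- two_sigmoid()
  oracle <- ts_breakpoint_oracle(w)
  det <- detect_spikes(w$sweep)
  thr <- ap_threshold(w$sweep, det$peak_index[1])
  bp <- find_breakpoint(w$sweep, det$peak_index[1], thr)
  expect_false(is.null(bp))
  expect_lt(abs(bp$time - oracle$time), 1000 / w$rate + 1e-9)

  # single-sigmoid (monophasic) upstroke: no breakpoint
  w1 <- two_sigmoid(a1 = 0, a2 = 110)
  det1 <- detect_spikes(w1$sweep)
  thr1 <- ap_threshold(w1$sweep, det1$peak_index[1])
  expect_null(find_breakpoint(w1$sweep, det1$peak_index[1], thr1))
})

test_that("slope ratio a/b matches the analytic construction within 1%", {
  w <- two_sigmoid()
  oracle <- ts_breakpoint_oracle(w)
  a_true <- oracle$b - oracle$dvdt
  det <- detect_spikes(w$sweep)
  thr <- ap_threshold(w$sweep, det$peak_index[1])
  sr <- slope_sd_ratio(w$sweep, det$peak_index[1], thr)
  expect_equal(sr$ratio, a_true / oracle$b, tolerance = 0.01)
  expect_equal(sr$b, oracle$b, tolerance = 0.01)
  expect_equal(sr$b_minus_a, oracle$dvdt, tolerance = 0.02)
  expect_lte(sr$a, sr$b)
  expect_identical(sr$convention, "shoulder")

  # vanishing AIS shoulder: ratio tends to 1
  w2 <- two_sigmoid(a1 = 3)
  det2 <- detect_spikes(w2$sweep)
  thr2 <- ap_threshold(w2$sweep, det2$peak_index[1])
  sr2 <- slope_sd_ratio(w2$sweep, det2$peak_index[1], thr2)
  if (!is.null(sr2)) expect_gt(sr2$ratio, 0.97)
})

test_that("ratio is invariant to voltage offset and uniform time rescaling", {
  w <- two_sigmoid()
  det <- detect_spikes(w$sweep)
  thr <- ap_threshold(w$sweep, det$peak_index[1])
  sr <- slope_sd_ratio(w$sweep, det$peak_index[1], thr)

  shifted <- sweep_of(w$sweep$voltage + 7, rate = w$rate)
  dets <- detect_spikes(shifted)
  thrs <- ap_threshold(shifted, dets$peak_index[1])
  srs <- slope_sd_ratio(shifted, dets$peak_index[1], thrs)
  expect_equal(srs$ratio, sr$ratio, tolerance = 1e-9)

  # same samples played at half speed: all slopes halve, the ratio doesn't
  slow <- sweep_of(w$sweep$voltage, rate = w$rate / 2)
  detl <- detect_spikes(slow)
  thrl <- ap_threshold(slow, detl$peak_index[1])
  srl <- slope_sd_ratio(slow, detl$peak_index[1], thrl)
  expect_equal(srl$b, sr$b / 2, tolerance = 1e-9)
  expect_equal(srl$ratio, sr$ratio, tolerance = 1e-9)
})

test_that("production second derivative equals double central differences", {
  w <- two_sigmoid()
  v <- w$sweep$voltage
  d2 <- d2vdt2(v, w$rate)
  dt <- 1000 / w$rate
  d1 <- c((v[2] - v[1]) / dt,
          (v[3:length(v)] - v[1:(length(v) - 2)]) / (2 * dt),
          (v[length(v)] - v[length(v) - 1]) / dt)
  d2_bf <- c((d1[2] - d1[1]) / dt,
             (d1[3:length(d1)] - d1[1:(length(d1) - 2)]) / (2 * dt),
             (d1[length(d1)] - d1[length(d1) - 1]) / dt)
  expect_equal(d2, d2_bf, tolerance = 1e-12)
})

test_that("raising the somatic Nav share strictly raises the simulated slope ratio", {
  proto <- short_protocol(seq(150, 450, 50), duration = 500)
  ratio_of <- function(frac) {
    p <- neuron_params(gNa_soma = 2500 * frac, gNa_ais = 2500 * (1 - frac))
    rec <- simulate_cell(p, proto, seed = 3)$recording
    fa <- first_ap_of_train(rec)
    slope_sd_ratio(fa$sweep, fa$peak_index, fa$threshold)$ratio
  }
  r <- vapply(c(0.82, 0.88, 0.94), ratio_of, numeric(1))
  expect_true(all(diff(r) > 0))
})

test_that("first AP of the 7-spike train is selected with fallback flags", {
  sim <- default_cell()
  fa <- first_ap_of_train(sim$recording)
  det <- detect_spikes(fa$sweep)
  expect_equal(fa$peak_index, det$peak_index[1])
  sub <- new_recording(list(sweep_of(rep(-65, 1000), amp = 100,
                                     onset = 2, offset = 18)))
  expect_null(first_ap_of_train(sub))
})
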