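test_that("a symmetric triangular spike has the geometric half-width", {
  fs <- 20000
  t <- seq_len(2 * fs) / fs
  v <- rep(-70, length(t))
  # gentle depolarizing ramp to threshold, then a symmetric triangle:
  # linear rise threshold -> peak over 1 ms, linear fall over 1 ms
  i0 <- fs                       # 1.0 s
  nramp <- round(0.05 * fs)
  nr <- round(0.001 * fs)
  v[(i0 - nramp):i0] <- seq(-70, -45, length.out = nramp + 1)
  v[i0:(i0 + nr)] <- seq(-45, 45, length.out = nr + 1)
  v[(i0 + nr):(i0 + 2 * nr)] <- seq(45, -45, length.out = nr + 1)
  v[(i0 + 2 * nr):(i0 + 2 * nr + nramp)] <- seq(-45, -70, length.out = nramp + 1)
  sw <- sweep_trace(t, v, 0, 0.5, 1.5, 200, "step")
  f <- ap_waveform_features(sw, 1, region = "LEC")
  expect_equal(f$threshold, -45, tolerance = 2)
  # width at 50% of amplitude: half of the 2-ms triangle base
  expect_equal(f$half_width, 1.0, tolerance = 0.05)
})

test_that("threshold matches the analytic second-derivative maximum", {
  # V(t) = V0 + A * Phi((t - t0)/s): second derivative peaks at t0 - s
  fs <- 20000
  t <- seq_len(fs) / fs
  t0 <- 0.5; s <- 0.0012; A <- 90; V0 <- -70
  v <- V0 + A * pnorm((t - t0) / s)
  # add a repolarizing tail so the rise ends in a detectable local maximum
  fall <- t > t0 + 2 * s
  v[fall] <- v[t < t0 + 2 * s][sum(t < t0 + 2 * s)] -
    pmin(2000 * (t[fall] - (t0 + 2 * s)), 40)
  sw <- sweep_trace(t, v, 0, 0.2, 0.9, 200, "step")
  f <- ap_waveform_features(sw, 1, region = "LEC",
                            config = ephys_config(min_peak = 15,
                                                  threshold_window_ms = 20))
  expect_lt(abs(f$threshold_time - (t0 - s)), 1.5 / fs)
  expect_equal(f$threshold, V0 + A * pnorm(-1), tolerance = 0.5)
  expect_equal(f$amplitude, max(v) - f$threshold, tolerance = 1e-9)
})

test_that("fAHP and DAP are read off a constructed post-spike trace", {
  fs <- 20000
  wave <- spike_waveform(threshold = -46, peak = 42, fahp = -53, dap = 2.2,
                         reset = -55, dt_ms = 1000 / fs)
  sw <- spiking_sweep(0.7, fs = fs, wave = wave)
  f <- ap_waveform_features(sw, 1, region = "MEC")
  expect_equal(f$fAHP, -53, tolerance = 0.05)
  expect_equal(f$DAP, 2.2, tolerance = 0.1)
})

test_that("a doublet inside the DAP window suppresses the DAP", {
  fs <- 20000
  wave <- spike_waveform(threshold = -46, peak = 42, fahp = -53, dap = 2.2,
                         reset = -55, t_tail = 3, dt_ms = 1000 / fs)
  sw <- spiking_sweep(c(0.7, 0.708), fs = fs, wave = wave)
  f <- ap_waveform_features(sw, 1, region = "MEC")
  expect_true(is.na(f$DAP))
  expect_identical(f$dap_absent_reason, "doublet")
})

test_that("fAHP and DAP are gated off outside MEC", {
  fs <- 20000
  sw <- spiking_sweep(0.7, fs = fs)
  f <- ap_waveform_features(sw, 1, region = "LEC")
  expect_true(is.na(f$fAHP) && is.na(f$DAP))
})

test_that("an out-of-range AP index is an error", {
  sw <- spiking_sweep(0.7)
  expect_error(ap_waveform_features(sw, 3), class = "ecs_malformed_input")
})

test_that("train ratios follow their definitions", {
  fs <- 20000
  # regular train
  sw <- spiking_sweep(seq(0.6, 1.4, 0.1), fs = fs)
  tr <- spike_train_features(sw)
  expect_equal(tr$isi1_over_isi2, 1, tolerance = 1e-6)
  expect_equal(tr$adaptation_ratio, 1, tolerance = 1e-6)
  # ISIs 10, 20, 40, 80 ms
  times <- 0.6 + c(0, cumsum(c(10, 20, 40, 80)) / 1000)
  tr2 <- spike_train_features(spiking_sweep(times, fs = fs))
  expect_equal(tr2$isi1_over_isi2, 0.5, tolerance = 1e-3)
  expect_equal(tr2$adaptation_ratio, 10 / 80, tolerance = 1e-3)
  expect_equal(tr2$isi, c(10, 20, 40, 80), tolerance = 1e-2)
})

test_that("spikes that stay below 0 mV have no width at 0 mV", {
  fs <- 20000
  wave <- spike_waveform(threshold = -46, peak = -5, fahp = -53, dap = 0,
                         reset = -55, dt_ms = 1000 / fs)
  sw <- spiking_sweep(c(0.6, 0.7, 0.8), fs = fs, wave = wave)
  tr <- spike_train_features(sw)
  expect_true(all(is.na(tr$per_ap_width_0mV)))
  expect_equal(tr$n_aps, 3L)
})

test_that("a train needs two APs", {
  tr <- spike_train_features(spiking_sweep(0.7))
  expect_equal(tr$n_aps, 1L)
  expect_identical(tr$reason, "fewer than 2 APs")
})

test_that("f-I quantities follow the stated conventions", {
  fs <- 20000
  # silent step
  fi0 <- fi_curve(list(flat_sweep(-70, dur_s = 2, fs = fs, stim_onset = 0.5,
                                  stim_offset = 1.5, step_amplitude = 250)))
  expect_equal(fi0$f_avg, 0)
  expect_true(is.na(fi0$f0) && is.na(fi0$f_ss))
  # 10 spikes in the 1-s step, first ISI 8 ms, last ISI 50 ms
  times <- 0.55 + c(0, cumsum(c(8, seq(12, 40, length.out = 7), 50)) / 1000)
  sw <- spiking_sweep(times, fs = fs, step_amplitude = 250)
  fi <- fi_curve(list(sw))
  expect_equal(fi$n_aps, 10)
  expect_equal(fi$f_avg, 10)
  expect_equal(fi$f0, 1000 / 8, tolerance = 1e-2)
  expect_equal(fi$f_ss, 1000 / 50, tolerance = 1e-2)
})

test_that("post-step AHP is measured against the pre-stimulus baseline", {
  s <- sag_sweep(-65, -95, -80, v_post_max = -65)
  # reuse the sag fixture inverted in time roles: post window minimum is v_ss
  fs <- 10000
  t <- seq_len(2 * fs) / fs
  v <- rep(-70, length(t))
  post <- t > 1.5 & t <= 1.7
  v[post] <- -73                      # 3 mV AHP after offset
  sw <- sweep_trace(t, v, 0, 0.5, 1.5, 100, "step")
  fi <- fi_curve(list(sw))
  expect_equal(fi$post_step_AHP, -3, tolerance = 1e-6)
})

test_that("rheobase is the first spiking amplitude in the series", {
  fs <- 20000
  mk <- function(amp, spike) {
    if (spike) spiking_sweep(1.0, fs = fs, dur_s = 2, stim_onset = 0.5,
                             stim_offset = 1.5, step_amplitude = amp)
    else flat_sweep(-70, dur_s = 2, fs = fs, stim_onset = 0.5,
                    stim_offset = 1.5, step_amplitude = amp)
  }
  mk2 <- function(amp, spike) { s <- mk(amp, spike); s$kind <- "rheobase_step"; s }
  sweeps <- lapply(seq(0, 120, 10), function(a) mk2(a, a >= 70))
  r <- rheobase(sweeps)
  expect_true(r$reached)
  expect_equal(r$rheobase, 70)
  # never spiking -> not reached, max tested reported
  r2 <- rheobase(lapply(seq(0, 50, 10), function(a) mk2(a, FALSE)))
  expect_false(r2$reached)
  expect_true(is.na(r2$rheobase))
  expect_equal(r2$max_tested, 50)
})
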