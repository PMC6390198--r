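test_that("points on an exact line give the slope and zero rectification", {
  di <- c(-200, -100, -50, 50, 100)
  fit <- fit_input_resistance(di, 0.05 * di)
  expect_equal(fit$R_N0, 50, tolerance = 1e-12)
  expect_equal(fit$c_AR, 0, tolerance = 1e-12)
})

test_that("quadratic coefficients are recovered to machine precision", {
  # generating slope 0.138 mV/pA (138 MOhm) with a small quadratic term
  di <- seq(-300, 100, 50)
  dv <- 0.138 * di + 1e-4 * di^2
  fit <- fit_input_resistance(di, dv)
  expect_equal(fit$R_N0, 138, tolerance = 1e-9)
  expect_equal(fit$c_AR, 1e-4, tolerance = 1e-9)
  # oracle: closed-form normal equations
  X <- cbind(di, di^2)
  beta <- solve(t(X) %*% X, t(X) %*% dv)
  expect_equal(fit$R_N0 / 1000, beta[1], tolerance = 1e-12)
  expect_equal(fit$c_AR, beta[2], tolerance = 1e-12)
})

test_that("noisy fits stay within three standard errors of the truth", {
  di <- seq(-300, 100, 50)
  mu <- 0.138 * di + 1e-4 * di^2
  X <- cbind(di, di^2)
  sigma <- 0.5
  se <- sigma * sqrt(diag(solve(t(X) %*% X)))   # exact sampling SEs
  miss_r <- 0L; miss_c <- 0L
  for (s in 1:100) {
    set.seed(s)
    fit <- fit_input_resistance(di, mu + rnorm(length(di), 0, sigma))
    if (abs(fit$R_N0 / 1000 - 0.138) > 3 * se[1]) miss_r <- miss_r + 1L
    if (abs(fit$c_AR - 1e-4) > 3 * se[2]) miss_c <- miss_c + 1L
  }
  # P(|z| > 3) ~ 0.0027: a couple of misses in 100 seeds at most
  expect_lte(miss_r, 3L)
  expect_lte(miss_c, 3L)
})

test_that("too few or rank-deficient points raise insufficient-data", {
  expect_error(fit_input_resistance(c(-100, -50), c(-5, -2.5)),
               class = "ecs_insufficient_data")
  expect_error(fit_input_resistance(c(-100, -100, -100), c(-5, -5, -5)),
               class = "ecs_insufficient_data")
})

test_that("a pure single exponential yields its time constant", {
  fs <- 20000
  t <- seq_len(2 * fs) / fs
  v <- -70 - 15 * (1 - exp(-pmax(t - 0.5, 0) * 1000 / 20))
  v[t > 1.5] <- -70   # crude release, outside the fit window
  sw <- sweep_trace(t, v, 0, 0.5, 1.5, -300, "step")
  fit <- membrane_time_constant(sw)
  expect_equal(fit$tau, 20, tolerance = 0.02)
})

test_that("the slower of two exponential components is returned", {
  fs <- 20000
  t <- seq_len(2 * fs) / fs
  tm <- pmax(t - 0.5, 0) * 1000
  v <- -70 - 3 * (1 - exp(-tm / 5)) - 10 * (1 - exp(-tm / 25))
  v[t > 1.5] <- -70
  sw <- sweep_trace(t, v, 0, 0.5, 1.5, -300, "step")
  fit <- membrane_time_constant(sw)
  expect_equal(fit$tau, 25, tolerance = 0.02 * 25)
  expect_equal(sort(fit$components)[1], 5, tolerance = 0.05 * 5)
})

test_that("sag ratio and rebound follow their defining arithmetic", {
  # (Vb - Vss)/(Vb - Vmin) = (-65+80)/(-65+95) = 15/30
  s <- sag_and_rebound(sag_sweep(-65, -95, -80))
  expect_equal(s$sag_ratio, 0.5, tolerance = 1e-6)
  expect_equal(s$rebound, 0, tolerance = 1e-6)
  # no sag: V_ss == V_min -> ratio 1; rebound bump of 4 mV
  s2 <- sag_and_rebound(sag_sweep(-65, -80, -80, v_post_max = -61))
  expect_equal(s2$sag_ratio, 1, tolerance = 1e-6)
  expect_equal(s2$rebound, 4, tolerance = 1e-6)
})

test_that("no hyperpolarization raises undefined-sag", {
  expect_error(sag_and_rebound(flat_sweep(-70, dur_s = 2, stim_onset = 0.5,
                                          stim_offset = 1.5)),
               class = "ecs_undefined_sag")
})

test_that("resting potential is the spontaneous-trace mean", {
  fs <- 10000
  t <- seq_len(10 * fs) / fs
  sw <- sweep_trace(t, rep(-70, length(t)), 0, t[1], t[length(t)],
                    0, "spontaneous")
  expect_equal(resting_potential(sw), -70)
  # a zero-mean sine over whole periods does not shift the estimate
  v2 <- -70 + sin(2 * pi * 5 * t)
  sw2 <- sweep_trace(t, v2, 0, t[1], t[length(t)], 0, "spontaneous")
  expect_equal(resting_potential(sw2), -70, tolerance = 1e-10)
})

test_that("spikes in the spontaneous window warn but still return the mean", {
  fs <- 20000
  wave <- spike_waveform(dt_ms = 1000 / fs)
  v <- rep(-70, 2 * fs)
  v <- insert_spikes(v, fs, wave)
  sw <- sweep_trace(seq_len(2 * fs) / fs, v, 0, 1 / fs, 2, 0, "spontaneous")
  expect_warning(vm <- resting_potential(sw), class = "ecs_spike_contaminated")
  expect_equal(vm, mean(v))
})
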