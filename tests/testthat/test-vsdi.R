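test_that("averaging identical trials is the identity", {
  m <- small_movie(seed = 1, noise_sd = 2)
  avg <- average_trials(list(m, m, m, m, m, m, m, m))
  expect_equal(avg$frames, m$frames)
})

test_that("paired perturbations cancel in the trial mean", {
  base <- small_movie()
  pert <- array(rnorm(prod(dim(base$frames)), 0, 3), dim(base$frames))
  m1 <- base; m1$frames <- base$frames + pert
  m2 <- base; m2$frames <- base$frames - pert
  avg <- average_trials(list(m1, m2))
  expect_equal(avg$frames, base$frames, tolerance = 1e-12)
})

test_that("averaging 8 trials shrinks the noise by sqrt(8)", {
  set.seed(42)
  sigma <- 2
  trials <- lapply(1:8, function(i) small_movie(h = 50, w = 50, nt = 40,
                                                nb = 10, stim = 11,
                                                noise_sd = sigma))
  avg <- average_trials(trials)
  resid_sd <- sd(avg$frames - 1000)
  expect_equal(resid_sd, sigma / sqrt(8), tolerance = 0.1)
})

test_that("geometry or metadata mismatches are rejected", {
  m1 <- small_movie(h = 10)
  m2 <- small_movie(h = 12)
  expect_error(average_trials(list(m1, m2)), class = "ecs_malformed_input")
  m3 <- small_movie(); m3$stimulus <- "single_0.6mA"
  expect_error(average_trials(list(m1, m3)), class = "ecs_malformed_input")
})

test_that("dF/F of a constant movie is zero with a centered baseline", {
  dff <- compute_dff(small_movie())
  expect_equal(max(abs(dff$values)), 0)
  # baseline window maps to mean zero per pixel even with structure
  clean <- array(0, c(10, 10, 60))
  clean[, , 20:40] <- 0.3
  dff2 <- compute_dff(small_movie(dff_clean = clean))
  bmeans <- apply(dff2$values[, , 1:10], c(1, 2), mean)
  expect_lt(max(abs(bmeans)), 1e-9)
})

test_that("a dye dimming of 2 per mille maps to +0.2% after the sign flip", {
  f <- array(1000, c(4, 4, 30))
  f[, , 15:20] <- 998
  dff <- compute_dff(vsdi_movie(f, 1, 11, 10))
  expect_equal(dff$values[1, 1, 17], 0.2, tolerance = 1e-9)
  expect_equal(dff$values[1, 1, 5], 0, tolerance = 1e-9)
})

test_that("dF/F is invariant under global intensity scaling", {
  m <- small_movie(seed = 5, noise_sd = 0.5)
  d1 <- compute_dff(m)
  m2 <- m; m2$frames <- 2 * m$frames
  d2 <- compute_dff(m2)
  expect_equal(d1$values, d2$values, tolerance = 1e-10)
})

test_that("pixels with non-positive baseline are masked", {
  f <- array(1000, c(4, 4, 30))
  f[2, 3, ] <- 0
  dff <- compute_dff(vsdi_movie(f, 1, 11, 10))
  expect_true(all(is.na(dff$values[2, 3, ])))
  expect_equal(unname(dff$masked_pixels[1, ]), c(2L, 3L))
})

test_that("the temporal filter reproduces cubic time courses exactly", {
  nt <- 40
  tpoly <- seq_len(nt)
  cubic <- 0.5 + 0.1 * tpoly - 0.01 * tpoly^2 + 2e-4 * tpoly^3
  clean <- array(rep(cubic, each = 16), c(4, 4, nt))
  dff <- compute_dff(small_movie(h = 4, w = 4, nt = nt, dff_clean = NULL))
  dff$values <- clean
  out <- filter_movie(dff, spatial_n = 1L, temporal_n = 5L)
  expect_equal(out$values, clean, tolerance = 1e-9)
})

test_that("a constant movie is unchanged by filtering", {
  dff <- compute_dff(small_movie())
  dff$values[] <- 0.42
  out <- filter_movie(dff)
  expect_equal(out$values, array(0.42, dim(dff$values)), tolerance = 1e-12)
})

test_that("a spatial delta spreads exactly the kernel footprint", {
  dff <- compute_dff(small_movie())
  dff$values[] <- 0
  dff$values[5, 5, 20] <- 9
  out <- filter_movie(dff, spatial_n = 3L, temporal_n = 1L)
  expect_equal(out$values[5, 5, 20], 1, tolerance = 1e-12)
  expect_equal(sum(out$values[, , 20] > 0), 9L)
  expect_equal(sum(out$values), 9, tolerance = 1e-9)
})

test_that("oversized or even kernels are rejected", {
  dff <- compute_dff(small_movie(h = 4, w = 4))
  expect_error(filter_movie(dff, spatial_n = 5L), class = "ecs_malformed_input")
  dff2 <- compute_dff(small_movie())
  expect_error(filter_movie(dff2, temporal_n = 4L), class = "ecs_malformed_input")
})

test_that("roi integral follows hand arithmetic and linearity", {
  nt <- 200
  clean <- array(0, c(6, 6, nt))
  clean[, , 31:130] <- 0.1          # 0.1% for 100 frames of 1 ms
  dff <- compute_dff(small_movie(h = 6, w = 6, nt = nt, nb = 10, stim = 31,
                                 dff_clean = clean))
  roi <- cbind(1:3, 1:3)
  v <- roi_integral(dff, roi)
  expect_equal(v, 10, tolerance = 0.11)   # trapezoid edges only
  # zero trace
  dff0 <- compute_dff(small_movie(h = 6, w = 6, nt = nt, nb = 10, stim = 31))
  expect_equal(roi_integral(dff0, roi), 0)
  # doubling the amplitude doubles the integral
  dff2 <- dff; dff2$values <- 2 * dff$values
  expect_equal(roi_integral(dff2, roi), 2 * v, tolerance = 1e-9)
  # additive over disjoint windows
  expect_equal(roi_integral(dff, roi, c(31, 80)) +
                 roi_integral(dff, roi, c(80, nt)),
               roi_integral(dff, roi, c(31, nt)), tolerance = 1e-9)
  expect_error(roi_integral(dff, roi[0, , drop = FALSE]),
               class = "ecs_malformed_input")
})

test_that("activated area counts pixels strictly above threshold", {
  nt <- 60
  clean <- array(0, c(20, 20, nt))
  pick <- cbind(rep(1:10, each = 20), rep(1:20, 10))   # 200 pixels
  for (i in seq_len(nrow(pick))) clean[pick[i, 1], pick[i, 2], 20:30] <- 0.1
  dff <- compute_dff(small_movie(h = 20, w = 20, nt = nt, nb = 10, stim = 11,
                                 dff_clean = clean))
  expect_equal(activated_area(dff, 0.05), 200L)
  # all-zero movie
  dff0 <- compute_dff(small_movie(h = 20, w = 20, nt = nt, nb = 10, stim = 11))
  expect_equal(activated_area(dff0), 0L)
  # strictness: peak exactly at threshold is not counted
  expect_equal(activated_area(dff, 0.1), 0L)
  # monotone in amplitude and threshold
  dff2 <- dff; dff2$values <- 2 * dff$values
  expect_gte(activated_area(dff2, 0.05), activated_area(dff, 0.05))
  expect_lte(activated_area(dff, 0.08), activated_area(dff, 0.05))
})

test_that("paired-pulse ratio divides the two response amplitudes", {
  nt <- 150
  kern <- function(t0, amp, nt) {
    t <- seq_len(nt) - t0
    amp * ifelse(t < 0, 0, exp(-t / 8) - exp(-t / 1.5)) /
      max(exp(-(0:50) / 8) - exp(-(0:50) / 1.5))
  }
  mk <- function(a1, a2) {
    tr <- kern(51, a1, nt) + kern(76, a2, nt)
    clean <- array(rep(tr, each = 25), c(5, 5, nt))
    m <- small_movie(h = 5, w = 5, nt = nt, nb = 50, stim = 51,
                     dff_clean = clean)
    m$stim_frames <- c(51L, 76L)
    compute_dff(m)
  }
  blades <- roi_spec(exposed_blade = cbind(1:3, 1), enclosed_blade = cbind(1:3, 5))
  # identical responses -> PPR 1 (decay of pulse 1 is baseline-corrected away)
  r1 <- paired_pulse_ratio(mk(0.05, 0.05), blades)
  expect_equal(unname(r1$per_blade), c(1, 1), tolerance = 0.06)
  # amplitudes 0.05 then 0.04 -> 0.8
  r2 <- paired_pulse_ratio(mk(0.05, 0.04), blades)
  expect_equal(r2$slice_mean, 0.8, tolerance = 0.06)
  # first-pulse amplitude <= 0 is undefined
  expect_error(paired_pulse_ratio(mk(0, 0.04), blades),
               class = "ecs_undefined_ppr")
})

test_that("stripe profiles track the generating spatial pattern", {
  nt <- 60
  h <- 30; w <- 30
  rr <- matrix(seq_len(h), h, w)
  ccm <- matrix(seq_len(w), h, w, byrow = TRUE)
  # uniform scene -> flat profile
  clean <- array(0, c(h, w, nt)); clean[, , 20:40] <- 0.2
  dffu <- compute_dff(small_movie(h = h, w = w, nt = nt, nb = 10, stim = 11,
                                  dff_clean = clean))
  st <- stripe_spec(c(15, 2), cbind(15, 2:25))
  pu <- stripe_profile(dffu, st, "peak")
  expect_lt(diff(range(pu$value)), 1e-9)
  # Gaussian falloff from the electrode recovered at voxel centres
  sig <- 5
  Smap <- 0.5 * exp(-((rr - 15)^2 + (ccm - 2)^2) / (2 * sig^2))
  cleang <- array(0, c(h, w, nt))
  for (k in 20:40) cleang[, , k] <- Smap
  dffg <- compute_dff(small_movie(h = h, w = w, nt = nt, nb = 10, stim = 11,
                                  dff_clean = cleang))
  pg <- stripe_profile(dffg, st, "peak")
  expect_equal(pg$value, 0.5 * exp(-pg$distance^2 / (2 * sig^2)),
               tolerance = 1e-6)
  expect_true(all(diff(pg$value) < 0))   # monotone decay scene
  # stripe exiting the frame is truncated with a warning
  st2 <- stripe_spec(c(15, 2), cbind(15, 2:40))
  expect_warning(pt <- stripe_profile(dffg, st2, "peak"),
                 class = "ecs_stripe_truncated")
  expect_equal(nrow(pt), sum(2:40 <= w))
})
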