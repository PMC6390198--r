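test_that("a zero-amplitude scene yields blank movies and no activated pixels", {
  sc <- vsdi_scene(dims = c(40, 40, 120), stim_frame = 51,
                   rois = list(exposed_blade = list(center = c(15, 15),
                                                    sigma = 5, peak = 0),
                               enclosed_blade = list(center = c(30, 30),
                                                     sigma = 5, peak = 0)),
                   noise_sd = 0.3)
  trials <- generate_vsdi_movie(sc, n_trials = 8, seed = 2)
  expect_equal(attr(trials, "ground_truth")$activated_pixels, 0L)
  q <- quantify_vsdi(trials, attr(trials, "rois"))
  expect_equal(q$activated_pixels, 0L)
})

test_that("generation is deterministic given the seed", {
  sc <- vsdi_scene(dims = c(30, 30, 100),
                   rois = list(exposed_blade = list(center = c(10, 10),
                                                    sigma = 4, peak = 0.3),
                               enclosed_blade = list(center = c(22, 22),
                                                     sigma = 4, peak = 0.2)))
  a <- generate_vsdi_movie(sc, n_trials = 2, seed = 9)
  b <- generate_vsdi_movie(sc, n_trials = 2, seed = 9)
  expect_identical(a[[1]]$frames, b[[1]]$frames)
  expect_identical(a[[2]]$frames, b[[2]]$frames)
  c1 <- generate_vsdi_movie(sc, n_trials = 2, seed = 10)
  expect_false(identical(a[[1]]$frames, c1[[1]]$frames))
})

test_that("noise-free pipeline output matches the analytic closed forms", {
  sc <- vsdi_scene(dims = c(60, 60, 300),
                   rois = list(exposed_blade = list(center = c(20, 20),
                                                    sigma = 6, peak = 0.3),
                               enclosed_blade = list(center = c(42, 42),
                                                     sigma = 6, peak = 0.15)),
                   noise_sd = 0)
  trials <- generate_vsdi_movie(sc, n_trials = 1, seed = 1)
  gt <- attr(trials, "ground_truth")
  # discrete trapezoid truth vs continuous kernel integral: <= 1%
  expect_equal(unname(gt$integral), unname(gt$integral_analytic),
               tolerance = 0.01)
  # unfiltered pipeline on the noise-free movie reproduces the truth
  dff <- compute_dff(average_trials(trials))
  ints <- roi_integral(dff, attr(trials, "rois"))
  expect_equal(unname(ints), unname(gt$integral), tolerance = 0.002)
  expect_equal(activated_area(dff), gt$activated_pixels)
})

test_that("blade-asymmetry ratios are recovered through the full pipeline", {
  for (r_target in c(0.5, 1, 2)) {
    sc <- vsdi_scene(dims = c(60, 60, 300),
                     rois = list(exposed_blade = list(center = c(20, 20),
                                                      sigma = 6,
                                                      peak = 0.2 * r_target),
                                 enclosed_blade = list(center = c(42, 42),
                                                       sigma = 6, peak = 0.2)),
                     noise_sd = 1)
    trials <- generate_vsdi_movie(sc, n_trials = 8, seed = round(100 * r_target))
    q <- quantify_vsdi(trials, attr(trials, "rois"))
    ratio <- q$integral[["exposed_blade"]] / q$integral[["enclosed_blade"]]
    expect_equal(ratio, r_target, tolerance = 0.1)
  }
})

test_that("designed paired-pulse ratios are recovered within 5%", {
  for (ppr_t in c(0.8, 1.32)) {
    sc <- vsdi_scene(dims = c(60, 60, 300), n_pulses = 2, ppr = ppr_t,
                     rois = list(exposed_blade = list(center = c(20, 20),
                                                      sigma = 6, peak = 0.3),
                                 enclosed_blade = list(center = c(42, 42),
                                                       sigma = 6, peak = 0.25)),
                     noise_sd = 1)
    trials <- generate_vsdi_movie(sc, n_trials = 8, seed = round(10 * ppr_t))
    q <- quantify_vsdi(trials, attr(trials, "rois"))
    expect_equal(q$ppr$slice_mean, ppr_t, tolerance = 0.05)
  }
})
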