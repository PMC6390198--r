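#' Synthetic dentate-gyrus VSDI scene
#'
#' Describes a ground-truth imaging scene: Gaussian spatial footprints for
#' the exposed blade, enclosed blade and CA3, a difference-of-exponentials
#' temporal kernel (normalized to peak 1), one or two stimulus pulses, the
#' raw-fluorescence baseline and the per-trial noise. All quantities the
#' analysis pipeline measures (ROI integrals, peaks, paired-pulse ratio,
#' activated-pixel count) have closed forms in the kernel parameters and
#' are emitted as ground truth by [generate_vsdi_movie()].
#'
#' With two pulses, `ppr` is the target paired-pulse ratio *as measured*
#' by [paired_pulse_ratio()] (baseline-corrected mode); the generator
#' solves for the second-pulse amplitude scaling that produces it on the
#' noise-free trace, so the design value is recovered exactly up to noise.
#'
#' @param dims movie dimensions, `c(height, width, frames)`.
#' @param frame_interval_ms frame interval, ms.
#' @param stim_frame first stimulus frame (1-based; 51 = after 50 ms).
#' @param n_baseline_frames optical-baseline frames.
#' @param rois named list; each element `list(center = c(row, col),
#'   sigma = px, peak = %%dFF)`.
#' @param tau_rise,tau_decay kernel time constants, ms.
#' @param latency_ms onset latency after the stimulus frame, ms.
#' @param n_pulses 1 or 2.
#' @param pulse_interval_ms inter-pulse interval, ms.
#' @param ppr target measured paired-pulse ratio (two-pulse scenes).
#' @param baseline raw-fluorescence baseline level, counts.
#' @param noise_sd per-pixel, per-frame Gaussian noise, counts.
#' @param condition,stimulus metadata labels.
#' @return List of class `ecs_scene`.
#' @export
vsdi_scene <- function(dims = c(100, 100, 512), frame_interval_ms = 1,
                       stim_frame = 51L, n_baseline_frames = 50L,
                       rois = list(
                         exposed_blade = list(center = c(30, 32), sigma = 8,
                                              peak = 0.30),
                         enclosed_blade = list(center = c(70, 68), sigma = 8,
                                               peak = 0.24),
                         CA3 = list(center = c(25, 80), sigma = 4.5,
                                    peak = 0.08)),
                       tau_rise = 3, tau_decay = 40, latency_ms = 3,
                       n_pulses = 1L, pulse_interval_ms = 25,
                       ppr = 0.86, baseline = 1000, noise_sd = 1,
                       condition = "normal_ACSF",
                       stimulus = "single_0.2mA") {
  stopifnot(tau_decay > tau_rise, baseline > 0, n_pulses %in% 1:2)
  for (r in rois) {
    if (r$center[1] < 1 || r$center[1] > dims[1] ||
        r$center[2] < 1 || r$center[2] > dims[2])
      stop_ecs("malformed_input", "ROI footprint centre outside the frame")
  }
  structure(list(dims = dims, frame_interval_ms = frame_interval_ms,
                 stim_frame = as.integer(stim_frame),
                 n_baseline_frames = as.integer(n_baseline_frames),
                 rois = rois, tau_rise = tau_rise, tau_decay = tau_decay,
                 latency_ms = latency_ms, n_pulses = as.integer(n_pulses),
                 pulse_interval_ms = pulse_interval_ms, ppr = ppr,
                 baseline = baseline, noise_sd = noise_sd,
                 condition = condition, stimulus = stimulus),
            class = "ecs_scene")
}

# normalized difference-of-exponentials kernel sampled at t (ms since onset)
.doe_kernel <- function(t, tr, td) {
  tpk <- log(td / tr) * tr * td / (td - tr)
  pk <- exp(-tpk / td) - exp(-tpk / tr)
  k <- ifelse(t < 0, 0, exp(-t / td) - exp(-t / tr))
  k / pk
}

.scene_spatial <- function(scene) {
  d <- scene$dims
  S <- matrix(0, d[1], d[2])
  rr <- matrix(seq_len(d[1]), d[1], d[2])
  cc <- matrix(seq_len(d[2]), d[1], d[2], byrow = TRUE)
  for (r in scene$rois) {
    S <- S + r$peak *
      exp(-((rr - r$center[1])^2 + (cc - r$center[2])^2) / (2 * r$sigma^2))
  }
  S
}

# clean dF/F temporal profile (peak-normalized spatially) for pulse scales s
.scene_temporal <- function(scene, scales) {
  d <- scene$dims
  t <- (seq_len(d[3]) - scene$stim_frame) * scene$frame_interval_ms -
    scene$latency_ms
  k <- scales[1] * .doe_kernel(t, scene$tau_rise, scene$tau_decay)
  if (length(scales) > 1L)
    k <- k + scales[2] *
      .doe_kernel(t - scene$pulse_interval_ms, scene$tau_rise, scene$tau_decay)
  k
}

# second-pulse scale that makes the measured (baseline-corrected) PPR of the
# clean trace equal the target
.solve_ppr_scale <- function(scene) {
  s1 <- scene$stim_frame
  s2 <- s1 + round(scene$pulse_interval_ms / scene$frame_interval_ms)
  nt <- scene$dims[3]
  w2_end <- min(nt, s2 + (s2 - s1) - 1L)
  measure <- function(p) {
    tr <- .scene_temporal(scene, c(1, p))
    a1 <- max(tr[s1:(s2 - 1L)])
    (max(tr[s2:w2_end]) - tr[s2 - 1L]) / a1
  }
  stats::uniroot(function(p) measure(p) - scene$ppr,
                 lower = 0.01, upper = 5, tol = 1e-10)$root
}

#' Simulate VSDI trials from a scene
#'
#' Builds the noise-free dF/F stack from the scene's spatial footprints and
#' temporal kernel, converts it to raw fluorescence with the dye's sign
#' convention (fluorescence decreases on depolarization), and emits
#' `n_trials` movies with independent Gaussian noise. The attached
#' `ground_truth` records, in closed form: the per-ROI integral (both the
#' continuous-time kernel integral and its trapezoid discretization), the
#' per-ROI peak, the measured PPR of the clean trace, and the number of
#' pixels whose clean peak exceeds 0.05%.
#'
#' @param scene an [vsdi_scene()].
#' @param n_trials number of trials (8 in the standard protocol).
#' @param seed integer seed.
#' @return List of [vsdi_movie()]s with attributes `ground_truth`,
#'   `rois` (an [roi_spec()] of core-disk masks, radius sigma) and
#'   `scene`.
#' @export
generate_vsdi_movie <- function(scene, n_trials = 8L, seed = 1) {
  set.seed(seed)
  d <- scene$dims
  S <- .scene_spatial(scene)
  scales <- if (scene$n_pulses == 2L) c(1, .solve_ppr_scale(scene)) else 1
  k <- .scene_temporal(scene, scales)
  clean <- array(outer(S, k), d)   # %% dF/F, depolarization positive
  raw0 <- scene$baseline * (1 - clean / 100)   # dye dims on depolarization

  stim_frames <- scene$stim_frame
  if (scene$n_pulses == 2L)
    stim_frames <- c(stim_frames,
                     scene$stim_frame +
                       round(scene$pulse_interval_ms / scene$frame_interval_ms))
  movies <- lapply(seq_len(n_trials), function(i) {
    noisy <- raw0 + array(rnorm(prod(d), 0, scene$noise_sd), d)
    noisy[noisy < 0] <- 0
    vsdi_movie(noisy, scene$frame_interval_ms, stim_frames,
               scene$n_baseline_frames, scene$condition, scene$stimulus,
               trial_id = i)
  })

  # core-disk ROI masks (radius = sigma) for quantification
  rois <- lapply(scene$rois, function(r) {
    rr <- matrix(seq_len(d[1]), d[1], d[2])
    cc <- matrix(seq_len(d[2]), d[1], d[2], byrow = TRUE)
    which((rr - r$center[1])^2 + (cc - r$center[2])^2 <= r$sigma^2,
          arr.ind = TRUE)
  })
  rois <- do.call(roi_spec, rois)

  dt <- scene$frame_interval_ms
  Mclean <- matrix(clean, d[1] * d[2], d[3])
  post <- seq.int(scene$stim_frame, d[3])
  truth <- list(
    integral = vapply(names(rois), function(nm) {
      pix <- rois[[nm]]
      lin <- (pix[, 2] - 1L) * d[1] + pix[, 1]
      tr <- colMeans(Mclean[lin, , drop = FALSE])[post]
      sum((tr[-1] + tr[-length(tr)]) / 2) * dt
    }, numeric(1)),
    integral_analytic = vapply(names(rois), function(nm) {
      pix <- rois[[nm]]
      lin <- (pix[, 2] - 1L) * d[1] + pix[, 1]
      tr <- scene$tau_rise; td <- scene$tau_decay
      tpk <- log(td / tr) * tr * td / (td - tr)
      pk <- exp(-tpk / td) - exp(-tpk / tr)   # peak of the raw kernel
      mean(S[lin]) * sum(scales) * (td - tr) / pk
    }, numeric(1)),
    peak = vapply(names(rois), function(nm) {
      pix <- rois[[nm]]
      lin <- (pix[, 2] - 1L) * d[1] + pix[, 1]
      max(colMeans(Mclean[lin, , drop = FALSE]))
    }, numeric(1)),
    ppr = if (scene$n_pulses == 2L) scene$ppr else NA_real_,
    pulse_scales = scales,
    activated_pixels = sum(apply(Mclean[, post, drop = FALSE], 1L, max) > 0.05))

  structure(movies, ground_truth = truth, rois = rois, scene = scene)
}

#' One-call VSDI quantification pipeline
#'
#' Average the trials, compute dF/F, filter, and quantify: ROI integrals,
#' activated area, and (for two-pulse recordings) the paired-pulse ratio.
#'
#' @param movies list of [vsdi_movie()]s (one accepted too).
#' @param rois an [roi_spec()].
#' @param spatial_n,temporal_n filter sizes (see [filter_movie()]).
#' @param threshold activated-area threshold, %% dF/F.
#' @return List with `integral` (named), `activated_pixels`, `ppr`
#'   (or NULL), `dff` (the filtered `ecs_dff`).
#' @export
quantify_vsdi <- function(movies, rois, spatial_n = 3L, temporal_n = 5L,
                          threshold = 0.05) {
  if (inherits(movies, "ecs_vsdi")) movies <- list(movies)
  avg <- average_trials(movies)
  dff <- filter_movie(compute_dff(avg), spatial_n, temporal_n)
  out <- list(integral = roi_integral(dff, rois),
              activated_pixels = activated_area(dff, threshold),
              ppr = NULL, dff = dff)
  if (length(avg$stim_frames) >= 2L) {
    blades <- rois[grep("blade", names(rois))]
    if (length(blades) >= 1L)
      out$ppr <- paired_pulse_ratio(dff, structure(blades, class = "ecs_rois"))
  }
  out
}
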