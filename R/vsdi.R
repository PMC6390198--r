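#' Voltage-sensitive dye imaging movie container
#'
#' A raw-fluorescence stack (height x width x frames, nominally
#' 100 x 100 x 512 at 1.0 ms/frame) with its acquisition metadata: the
#' frames used for the optical baseline (the first 50 by default), the
#' stimulus frame(s), the pharmacological condition and the stimulus type.
#'
#' @param frames 3-D numeric array, height x width x time; intensities
#'   must be non-negative.
#' @param frame_interval_ms frame interval, ms.
#' @param stim_frames integer frame indices (1-based) of stimulus onsets.
#' @param n_baseline_frames number of leading frames averaged into the
#'   optical baseline.
#' @param condition `"normal_ACSF"` or `"bicuculline"`.
#' @param stimulus stimulus label (e.g. `"single_0.2mA"`).
#' @param trial_id trial identifier.
#' @return Object of class `ecs_vsdi`.
#' @export
vsdi_movie <- function(frames, frame_interval_ms = 1.0, stim_frames = 51L,
                       n_baseline_frames = 50L,
                       condition = c("normal_ACSF", "bicuculline"),
                       stimulus = "single_0.2mA", trial_id = 1L) {
  condition <- match.arg(condition)
  d <- dim(frames)
  if (length(d) != 3L)
    stop_ecs("malformed_input", "frames must be a 3-D array")
  if (any(frames < 0))
    stop_ecs("malformed_input", "intensities must be non-negative")
  if (n_baseline_frames >= d[3])
    stop_ecs("malformed_input", "baseline frames must precede the end of the movie")
  if (any(stim_frames < n_baseline_frames))
    stop_ecs("malformed_input", "stimulus must come after the baseline window")
  structure(list(frames = frames, frame_interval_ms = frame_interval_ms,
                 stim_frames = as.integer(stim_frames),
                 n_baseline_frames = as.integer(n_baseline_frames),
                 condition = condition, stimulus = stimulus,
                 trial_id = trial_id),
            class = "ecs_vsdi")
}

#' @export
print.ecs_vsdi <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<ecs_vsdi> %dx%d px, %d frames @ %g ms, stim %s, %s, trial %s\n",
              d[1], d[2], d[3], x$frame_interval_ms,
              paste(x$stim_frames, collapse = "/"), x$condition,
              paste(x$trial_id, collapse = ",")))
  invisible(x)
}

#' Average repeated trials of a VSDI recording
#'
#' Pixelwise arithmetic mean of movies with identical geometry and
#' stimulus metadata (nominally 8 recordings separated by 3 s, averaged to
#' reduce noise).
#'
#' @param movies list of [vsdi_movie()] objects.
#' @return A single `ecs_vsdi` whose `trial_id` lists the averaged trials.
#' @export
average_trials <- function(movies) {
  if (length(movies) == 0L) stop_ecs("malformed_input", "no movies")
  m1 <- movies[[1]]
  for (m in movies[-1]) {
    if (!identical(dim(m$frames), dim(m1$frames)))
      stop_ecs("malformed_input", "movie geometries differ")
    if (!identical(m$stim_frames, m1$stim_frames) ||
        !identical(m$frame_interval_ms, m1$frame_interval_ms) ||
        !identical(m$condition, m1$condition) ||
        !identical(m$stimulus, m1$stimulus))
      stop_ecs("malformed_input", "movie stimulus metadata differ")
  }
  acc <- m1$frames
  for (m in movies[-1]) acc <- acc + m$frames
  out <- m1
  out$frames <- acc / length(movies)
  out$trial_id <- vapply(movies, function(m) m$trial_id[1], m1$trial_id[1])
  out
}

#' Fractional fluorescence change (dF/F)
#'
#' Per pixel, \eqn{\Delta F/F(t) = s\,(F(t)-F_0)/F_0 \times 100\%} with
#' \eqn{F_0} the mean over the baseline frames. The sign `s` is -1 by
#' default because the dye dims on depolarization, making depolarization
#' positive in the output. Pixels with non-positive baseline are masked
#' (all-NA) and flagged.
#'
#' @param movie an [vsdi_movie()].
#' @param signflip flip the sign so depolarization is positive?
#' @return Object of class `ecs_dff`: list with `values` (array, %),
#'   `frame_interval_ms`, `stim_frames`, `n_baseline_frames`,
#'   `masked_pixels` (2-column index matrix), `provenance`.
#' @export
compute_dff <- function(movie, signflip = TRUE) {
  nb <- movie$n_baseline_frames
  f0 <- apply(movie$frames[, , seq_len(nb), drop = FALSE], c(1, 2), mean)
  bad <- which(f0 <= 0, arr.ind = TRUE)
  f0[f0 <= 0] <- NA_real_
  s <- if (signflip) -1 else 1
  vals <- s * 100 * sweep(sweep(movie$frames, c(1, 2), f0, "-"), c(1, 2), f0, "/")
  structure(list(values = vals,
                 frame_interval_ms = movie$frame_interval_ms,
                 stim_frames = movie$stim_frames,
                 n_baseline_frames = nb,
                 masked_pixels = bad,
                 provenance = list(signflip = signflip, baseline_frames = nb,
                                   filtered = FALSE)),
            class = "ecs_dff")
}

# Savitzky-Golay filter along the time dimension of a pixels x time matrix,
# with the proper asymmetric end filters (preserves polynomials up to the
# fit order everywhere, including the edges)
.sg_time_filter <- function(M, p, n) {
  Fm <- signal::sgolay(p = p, n = n)
  Fm <- matrix(as.numeric(Fm), n, n)
  half <- (n - 1L) %/% 2L
  nt <- ncol(M)
  out <- matrix(NA_real_, nrow(M), nt)
  # interior: convolution with the central row
  cc <- Fm[half + 1L, ]
  for (j in seq.int(half + 1L, nt - half)) {
    cols <- seq.int(j - half, j + half)
    out[, j] <- M[, cols, drop = FALSE] %*% cc
  }
  # edges: first/last rows of the projection matrix on the end windows
  head_w <- M[, seq_len(n), drop = FALSE]
  tail_w <- M[, seq.int(nt - n + 1L, nt), drop = FALSE]
  for (j in seq_len(half)) {
    out[, j] <- head_w %*% Fm[j, ]
    out[, nt - half + j] <- tail_w %*% Fm[half + 1L + j, ]
  }
  out
}

#' Spatial and temporal (cubic) filtering of a dF/F movie
#'
#' Spatial smoothing with a mean (box) or Gaussian kernel followed by an
#' order-3 local-polynomial (Savitzky-Golay) temporal filter. Spatial
#' edges are handled by reflection; the temporal filter uses the proper
#' asymmetric end windows, so a cubic-in-time signal is reproduced
#' exactly. NA (masked) pixels stay NA.
#'
#' @param dff an [compute_dff()] result.
#' @param spatial_n odd spatial kernel size in pixels (1 disables).
#' @param temporal_n odd temporal window in frames (1 disables).
#' @param spatial_kind `"mean"` or `"gaussian"`.
#' @param gaussian_sigma sigma of the Gaussian kernel, pixels.
#' @return The filtered `ecs_dff`.
#' @export
filter_movie <- function(dff, spatial_n = 3L, temporal_n = 5L,
                         spatial_kind = c("mean", "gaussian"),
                         gaussian_sigma = 1) {
  spatial_kind <- match.arg(spatial_kind)
  v <- dff$values
  d <- dim(v)
  if (spatial_n > min(d[1], d[2]) || temporal_n > d[3])
    stop_ecs("malformed_input", "kernel larger than the movie")
  if (spatial_n %% 2L == 0L || temporal_n %% 2L == 0L)
    stop_ecs("malformed_input", "kernel sizes must be odd")
  if (spatial_n > 1L) {
    half <- (spatial_n - 1L) %/% 2L
    k1 <- if (spatial_kind == "mean") rep(1, spatial_n) else
      exp(-((-half:half)^2) / (2 * gaussian_sigma^2))
    k2 <- outer(k1, k1)
    k2 <- k2 / sum(k2)
    # reflect-pad rows and columns, then shift-and-add
    ridx <- c(rev(seq_len(half) + 1L), seq_len(d[1]), d[1] - seq_len(half))
    cidx <- c(rev(seq_len(half) + 1L), seq_len(d[2]), d[2] - seq_len(half))
    vp <- v[ridx, cidx, , drop = FALSE]
    acc <- array(0, d)
    for (i in seq_len(spatial_n)) for (j in seq_len(spatial_n)) {
      acc <- acc + k2[i, j] *
        vp[seq_len(d[1]) + i - 1L, seq_len(d[2]) + j - 1L, , drop = FALSE]
    }
    v <- acc
  }
  if (temporal_n > 1L) {
    M <- matrix(v, d[1] * d[2], d[3])
    ok <- rowSums(is.na(M)) == 0L
    M[ok, ] <- .sg_time_filter(M[ok, , drop = FALSE], p = 3L, n = temporal_n)
    v <- array(M, d)
  }
  out <- dff
  out$values <- v
  out$provenance <- modifyList(dff$provenance,
                               list(filtered = TRUE, spatial_n = spatial_n,
                                    spatial_kind = spatial_kind,
                                    temporal_n = temporal_n))
  out
}
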