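#' Rheobase from an ordered series of depolarizing steps
#'
#' The rheobase is the amplitude of the first sweep in the increasing
#' series that contains at least one detected action potential.
#'
#' @param sweeps list of `rheobase_step` sweeps ordered by increasing
#'   amplitude with a constant increment.
#' @param config an [ephys_config()].
#' @return List with `rheobase` (pA; NA when not reached), `reached`,
#'   `sweep_index`, `max_tested` (pA).
#' @export
rheobase <- function(sweeps, config = ephys_config()) {
  amps <- vapply(sweeps, `[[`, numeric(1), "step_amplitude")
  if (is.unsorted(amps, strictly = TRUE))
    stop_ecs("malformed_input", "rheobase sweeps must be ordered by increasing amplitude")
  for (k in seq_along(sweeps)) {
    sw <- sweeps[[k]]
    idx <- detect_aps(sw, config)
    idx <- idx[sw$time[idx] >= sw$stim_onset & sw$time[idx] <= sw$stim_offset]
    if (length(idx) > 0)
      return(list(rheobase = amps[k], reached = TRUE, sweep_index = k,
                  max_tested = max(amps)))
  }
  list(rheobase = NA_real_, reached = FALSE, sweep_index = NA_integer_,
       max_tested = max(amps))
}

# interpolated level-crossing times around a peak (ms); returns width or NA
.width_at <- function(t_ms, v, ipk, level) {
  iu <- which(v[seq_len(ipk - 1L)] < level & v[seq_len(ipk - 1L) + 1L] >= level)
  if (length(iu) == 0L) return(NA_real_)
  iu <- max(iu)
  tu <- t_ms[iu] + (level - v[iu]) / (v[iu + 1L] - v[iu]) * (t_ms[iu + 1L] - t_ms[iu])
  nd <- length(v)
  cand <- seq.int(ipk, nd - 1L)
  idn <- cand[v[cand] >= level & v[cand + 1L] < level]
  if (length(idn) == 0L) return(NA_real_)
  idn <- min(idn)
  td <- t_ms[idn] + (v[idn] - level) / (v[idn] - v[idn + 1L]) * (t_ms[idn + 1L] - t_ms[idn])
  td - tu
}

# Savitzky-Golay smoothing of a window; returns smoothed values
.sg_smooth <- function(y, n_win) {
  n_win <- max(5L, n_win)
  if (n_win %% 2L == 0L) n_win <- n_win + 1L
  if (n_win >= length(y)) return(y)
  as.numeric(signal::sgolayfilt(y, p = 3, n = n_win))
}

#' Action-potential waveform features
#'
#' Measured on one detected AP (by default the first AP of the rheobase
#' trace). The threshold is the voltage at the maximum of the second
#' derivative of the locally-smoothed (cubic Savitzky-Golay) voltage in a
#' pre-peak window; amplitude is peak minus threshold; half-width is the
#' interpolated width at 50% of the amplitude; the fAHP is the minimum
#' directly after the peak and the DAP the post-fAHP maximum minus the
#' fAHP. fAHP and DAP are only measured for MEC cells, and the DAP is
#' reported missing when a following spike (doublet) falls inside the DAP
#' window.
#'
#' @param sweep the sweep containing the AP.
#' @param ap_index which detected AP to measure (default 1).
#' @param region `"MEC"` or `"LEC"`; LEC gates off fAHP/DAP.
#' @param config an [ephys_config()].
#' @return List with `threshold`, `amplitude`, `half_width`, `fAHP`, `DAP`,
#'   `peak_time`, `threshold_time`, `peak_voltage`, `dap_absent_reason`.
#' @export
ap_waveform_features <- function(sweep, ap_index = 1L,
                                 region = c("MEC", "LEC"),
                                 config = ephys_config()) {
  region <- match.arg(region)
  peaks <- detect_aps(sweep, config)
  if (ap_index > length(peaks))
    stop_ecs("malformed_input", "ap_index %d out of range (%d APs detected)",
             ap_index, length(peaks))
  ipk <- peaks[ap_index]
  v <- sweep$voltage
  tt <- sweep$time
  dt_ms <- 1000 / sweep$sample_rate
  nwin <- round(config$threshold_window_ms / dt_ms)
  i0 <- max(1L, ipk - nwin)
  if (ap_index > 1L) i0 <- max(i0, peaks[ap_index - 1L] + 1L)
  if (i0 >= ipk) stop_ecs("malformed_input", "empty threshold search window")
  seg <- seq.int(i0, ipk)
  sm <- .sg_smooth(v[seg], round(config$threshold_smooth_ms / dt_ms))
  d2 <- diff(diff(sm))
  if (length(d2) < 1L) stop_ecs("malformed_input", "threshold window too short")
  irel <- which.max(d2) + 1L           # second-difference center
  ithr <- seg[irel]
  threshold <- sm[irel]
  amplitude <- v[ipk] - threshold
  hw <- .width_at((tt - tt[1]) * 1000, v, ipk, threshold + amplitude / 2)
  fAHP <- NA_real_; DAP <- NA_real_; dap_absent <- NA_character_
  if (region == "MEC") {
    ifa <- seq.int(ipk + 1L, min(length(v), ipk + round(config$fahp_ms / dt_ms)))
    fAHP <- min(v[ifa])
    ifahp <- ifa[which.min(v[ifa])]
    idap <- seq.int(ifahp, min(length(v), ifahp + round(config$dap_ms / dt_ms)))
    doublet <- any(peaks > ipk & peaks <= max(idap))
    if (doublet) {
      dap_absent <- "doublet"
    } else {
      DAP <- max(v[idap]) - fAHP
    }
  }
  list(threshold = threshold, amplitude = amplitude, half_width = hw,
       fAHP = fAHP, DAP = DAP,
       peak_time = tt[ipk], threshold_time = tt[ithr],
       peak_voltage = v[ipk], dap_absent_reason = dap_absent)
}

#' Spike-train features from a depolarizing step
#'
#' Per-AP amplitude (peak minus per-AP threshold), per-AP width at 0 mV
#' (interpolated crossings; missing for spikes that stay below 0 mV),
#' interspike intervals, the ratio of the first two ISIs, and the
#' adaptation ratio (first ISI / last ISI).
#'
#' @param sweep a depolarizing step sweep (nominally +200 or +210 pA).
#' @param config an [ephys_config()].
#' @return List with `n_aps`, `per_ap_amplitude`, `per_ap_width_0mV` (ms),
#'   `isi` (ms), `isi1_over_isi2`, `adaptation_ratio`, `reason` (when the
#'   train is too short).
#' @export
spike_train_features <- function(sweep, config = ephys_config()) {
  peaks <- detect_aps(sweep, config)
  peaks <- peaks[sweep$time[peaks] >= sweep$stim_onset &
                 sweep$time[peaks] <= sweep$stim_offset]
  if (length(peaks) < 2L)
    return(list(n_aps = length(peaks), per_ap_amplitude = numeric(0),
                per_ap_width_0mV = numeric(0), isi = numeric(0),
                isi1_over_isi2 = NA_real_, adaptation_ratio = NA_real_,
                reason = "fewer than 2 APs"))
  t_ms <- (sweep$time - sweep$time[1]) * 1000
  v <- sweep$voltage
  amps <- vapply(seq_along(peaks), function(k) {
    f <- tryCatch(ap_waveform_features(sweep, k, region = "LEC", config = config),
                  error = function(e) NULL)
    if (is.null(f)) NA_real_ else f$amplitude
  }, numeric(1))
  w0 <- vapply(peaks, function(ipk) {
    if (v[ipk] <= 0) NA_real_ else .width_at(t_ms, v, ipk, 0)
  }, numeric(1))
  isi <- diff(t_ms[peaks])
  list(n_aps = length(peaks),
       per_ap_amplitude = amps, per_ap_width_0mV = w0, isi = isi,
       isi1_over_isi2 = if (length(isi) >= 2L) isi[1] / isi[2] else NA_real_,
       adaptation_ratio = if (length(isi) >= 2L) isi[1] / isi[length(isi)] else NA_real_,
       reason = NA_character_)
}

#' Firing frequency and post-step AHP versus injected current
#'
#' For each depolarizing step: the average firing frequency (spike count
#' divided by the step duration), the instantaneous frequency between the
#' two first APs (f0) and the two last APs (f_ss), and the post-step AHP
#' (post-offset minimum minus pre-stimulus baseline).
#'
#' @param sweeps list of step sweeps.
#' @param config an [ephys_config()]; `fi_range` and `ahp_range` select
#'   which currents contribute frequency and AHP values.
#' @return data.frame with columns `current`, `f_avg`, `f0`, `f_ss`,
#'   `post_step_AHP`, `n_aps`.
#' @export
fi_curve <- function(sweeps, config = ephys_config()) {
  rows <- lapply(sweeps, function(sw) {
    amp <- sw$step_amplitude
    dur_s <- sw$stim_offset - sw$stim_onset
    peaks <- detect_aps(sw, config)
    peaks <- peaks[sw$time[peaks] >= sw$stim_onset & sw$time[peaks] <= sw$stim_offset]
    isi <- diff(sw$time[peaks]) * 1000
    in_fi <- amp >= config$fi_range[1] & amp <= config$fi_range[2]
    in_ahp <- amp >= config$ahp_range[1] & amp <= config$ahp_range[2]
    ahp <- NA_real_
    if (in_ahp) {
      vb <- .baseline_v(sw, config)
      ipost <- .win_idx(sw, sw$stim_offset, sw$stim_offset + config$post_stim_ms / 1000)
      vsm <- .smooth_v(sw$voltage, sw$sample_rate, config$extremum_smooth_ms)
      ahp <- min(vsm[ipost]) - vb
    }
    data.frame(current = amp,
               f_avg = if (in_fi) length(peaks) / dur_s else NA_real_,
               f0 = if (in_fi && length(isi) >= 1L) 1000 / isi[1] else NA_real_,
               f_ss = if (in_fi && length(isi) >= 1L) 1000 / isi[length(isi)] else NA_real_,
               post_step_AHP = ahp,
               n_aps = length(peaks))
  })
  out <- do.call(rbind, rows)
  out[order(out$current), , drop = FALSE]
}
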