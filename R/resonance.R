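#' Subthreshold resonance from a ZAP (chirp) sweep
#'
#' The impedance magnitude profile is the spectral ratio of the voltage
#' response to the injected chirp current, smoothed with a running mean of
#' configurable bandwidth. The resonance frequency is the location of the
#' profile maximum inside the analyzed band; the cell is flagged
#' non-resonant when the maximum sits at the lower band edge. Traces
#' containing action potentials are rejected, mirroring the exclusion of
#' noisy/spiking ZAP recordings.
#'
#' @param sweep a `zap` sweep with the chirp in its `current` channel.
#' @param config an [ephys_config()]; `zap_band` (Hz) and `zap_smooth_hz`
#'   control the analysis.
#' @return List with `resonance_frequency` (Hz), `is_resonant`,
#'   `impedance` (data.frame frequency/magnitude_MOhm, smoothed), `method`.
#' @export
resonance_frequency <- function(sweep, config = ephys_config()) {
  if (sweep$kind != "zap")
    stop_ecs("malformed_input", "resonance needs a zap sweep")
  if (length(detect_aps(sweep, config)) > 0)
    stop_ecs("not_estimable",
             "action potentials in the ZAP trace; resonance not estimable")
  i <- .win_idx(sweep, sweep$stim_onset, sweep$stim_offset)
  v <- sweep$voltage[i] - mean(sweep$voltage[i])
  cc <- sweep$current[i] - mean(sweep$current[i])
  n <- length(v)
  fs <- sweep$sample_rate
  freq <- seq_len(n %/% 2) * fs / n   # positive frequencies, Hz
  Zmag <- Mod(fft(v)[seq_len(n %/% 2) + 1L] / fft(cc)[seq_len(n %/% 2) + 1L]) * 1000  # GOhm->MOhm
  band <- freq >= config$zap_band[1] & freq <= config$zap_band[2]
  f <- freq[band]; z <- Zmag[band]
  # running-mean smoothing over the configured bandwidth
  hw <- max(1L, round(config$zap_smooth_hz / 2 / (fs / n)))
  k <- 2L * hw + 1L
  zs <- as.numeric(stats::filter(c(rev(z[seq_len(hw)]), z, rev(tail(z, hw))),
                                 rep(1 / k, k), sides = 2L))
  zs <- zs[seq_along(z) + hw]
  imax <- which.max(zs)
  list(resonance_frequency = f[imax],
       is_resonant = imax > 1L,
       impedance = data.frame(frequency = f, magnitude_MOhm = zs),
       method = "spectral_ratio")
}

#' ZAP chirp current
#'
#' Sinusoidal current with linearly increasing frequency, used to probe
#' subthreshold resonance.
#'
#' @param duration_s chirp duration, s.
#' @param f0,f1 start and end frequency, Hz.
#' @param amplitude_pA peak amplitude, pA.
#' @param sample_rate Hz.
#' @return Numeric current vector, pA.
#' @export
zap_current <- function(duration_s = 15, f0 = 0, f1 = 20, amplitude_pA = 40,
                        sample_rate = 20000) {
  t <- seq(0, duration_s, by = 1 / sample_rate)
  amplitude_pA * sin(2 * pi * (f0 * t + (f1 - f0) * t^2 / (2 * duration_s)))
}
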