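# Constructed traces with exactly known properties, used across the suite.

# flat sweep at a given voltage
flat_sweep <- function(v = -70, dur_s = 1, fs = 10000, kind = "step",
                       step_amplitude = 0, stim_onset = 0.2,
                       stim_offset = 0.8) {
  n <- round(dur_s * fs)
  sweep_trace(seq_len(n) / fs, rep(v, n), 0,
              stim_onset = stim_onset, stim_offset = stim_offset,
              step_amplitude = step_amplitude, kind = kind)
}

# hyperpolarizing step with piecewise-linear segments hitting exact
# V_baseline / V_min / V_ss / V_max_post values
sag_sweep <- function(v_base = -65, v_min = -95, v_ss = -80,
                      v_post_max = NULL, fs = 10000) {
  if (is.null(v_post_max)) v_post_max <- v_base
  # 0-0.5 s baseline; step 0.5-1.5 s; post to 2.2 s
  t <- seq_len(round(2.2 * fs)) / fs
  v <- rep(v_base, length(t))
  seg <- function(from, to) which(t > from & t <= to)
  i1 <- seg(0.5, 0.54)                 # drop to v_min
  v[i1] <- v_base + (v_min - v_base) * seq_along(i1) / length(i1)
  v[seg(0.54, 0.56)] <- v_min          # hold the minimum (plateau)
  i2 <- seg(0.56, 0.75)                # relax to v_ss
  v[i2] <- v_min + (v_ss - v_min) * seq_along(i2) / length(i2)
  v[seg(0.75, 1.5)] <- v_ss
  i3 <- seg(1.5, 1.58)                 # rebound bump
  v[i3] <- v_ss + (v_post_max - v_ss) * seq_along(i3) / length(i3)
  v[seg(1.58, 1.6)] <- v_post_max      # hold the rebound maximum
  i4 <- seg(1.6, 1.7)
  v[i4] <- v_post_max + (v_base - v_post_max) * seq_along(i4) / length(i4)
  v[seg(1.7, 2.2)] <- v_base
  sweep_trace(t, v, 0, stim_onset = 0.5, stim_offset = 1.5,
              step_amplitude = -300, kind = "step")
}

# step sweep with spikes inserted at given times (s)
spiking_sweep <- function(spike_times, v_rest = -70, fs = 20000,
                          dur_s = 2, stim_onset = 0.5, stim_offset = 1.5,
                          wave = spike_waveform(dt_ms = 1000 / fs),
                          step_amplitude = 200) {
  n <- round(dur_s * fs)
  v <- rep(v_rest, n)
  v <- insert_spikes(v, round(spike_times * fs), wave)
  sweep_trace(seq_len(n) / fs, v, 0, stim_onset = stim_onset,
              stim_offset = stim_offset, step_amplitude = step_amplitude,
              kind = "step")
}

# index of the waveform peak inside spike_waveform output
wave_peak_offset <- function(wave) which.max(wave) - 1L

# subthreshold response of the 2-D linear membrane (leak g nS + slow
# conductance gw nS with relaxation tw ms, capacitance C pF) to a current
# vector (pA) -- independent closed-form-by-integration oracle used for
# resonance and passive tests
linear_membrane_response <- function(current, g, gw, tw, C, EL = -65,
                                     dt_ms = 0.05) {
  n <- length(current)
  x <- 0; w <- 0
  out <- numeric(n)
  for (i in seq_len(n)) {
    x <- x + dt_ms * (-g * x - gw * w + current[i]) / C
    w <- w + dt_ms * (x - w) / tw
    out[i] <- x
  }
  out + EL
}

# analytic impedance magnitude (MOhm) of the same 2-D linear membrane
linear_membrane_impedance <- function(f_hz, g, gw, tw, C) {
  w <- 2 * pi * f_hz / 1000
  1000 * Mod(1 / (g + 1i * w * C + gw / (1 + 1i * w * tw)))
}

# tiny VSDI movie: constant baseline with a known dF/F bump added
small_movie <- function(h = 10, w = 10, nt = 60, baseline = 1000,
                        nb = 10, stim = 11L, dff_clean = NULL,
                        noise_sd = 0, signflip = TRUE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  f <- array(baseline, c(h, w, nt))
  if (!is.null(dff_clean)) {
    s <- if (signflip) -1 else 1
    f <- baseline * (1 + s * dff_clean / 100)
  }
  if (noise_sd > 0) f <- f + array(rnorm(h * w * nt, 0, noise_sd), dim(f))
  vsdi_movie(f, 1, stim, nb)
}
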