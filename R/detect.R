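#' Detect action potentials in a current-clamp sweep
#'
#' Candidate spikes are local voltage maxima at or above `min_peak` whose
#' preceding depolarization (within the refractory window) reaches the
#' dV/dt onset criterion. Peaks closer together than the refractory window
#' are collapsed onto the earlier peak with a warning.
#'
#' @param sweep an [sweep_trace()] object.
#' @param config an [ephys_config()]; supplies `dvdt_threshold` (V/s),
#'   `min_peak` (mV) and `refractory_ms`.
#' @return Integer vector of strictly increasing peak sample indices
#'   (possibly empty).
#' @export
detect_aps <- function(sweep, config = ephys_config()) {
  v <- sweep$voltage
  n <- length(v)
  dt_ms <- 1000 / sweep$sample_rate
  # mV/ms == V/s
  dvdt <- c(diff(v) / dt_ms, 0)
  cand <- which(v >= config$min_peak)
  cand <- cand[cand > 1L & cand < n]
  cand <- cand[v[cand] >= v[cand - 1L] & v[cand] > v[cand + 1L]]
  if (length(cand) == 0L) return(integer(0))
  look <- max(1L, round(config$refractory_ms / dt_ms))
  ok <- vapply(cand, function(i) {
    j0 <- max(1L, i - look)
    max(dvdt[j0:i]) >= config$dvdt_threshold
  }, logical(1))
  cand <- cand[ok]
  if (length(cand) <= 1L) return(cand)
  # enforce refractory window: keep the earlier of any too-close pair
  keep <- cand[1L]
  dropped <- 0L
  for (i in cand[-1L]) {
    if ((i - keep[length(keep)]) * dt_ms >= config$refractory_ms) {
      keep <- c(keep, i)
    } else {
      dropped <- dropped + 1L
    }
  }
  if (dropped > 0L)
    warn_ecs("refractory_collapse",
             "%d peak(s) within the %g ms refractory window were dropped",
             dropped, config$refractory_ms)
  keep
}

#' Stereotyped action-potential waveform
#'
#' Builds a spike waveform (absolute mV, sampled at `dt_ms`) from shape
#' parameters: a fast rise from threshold to peak, repolarization to the
#' fAHP trough, an optional depolarizing afterpotential (DAP) hump, and a
#' decay to the reset voltage. Monotone cubic interpolation between knots
#' keeps each segment free of overshoot. Used by the cell simulator and by
#' tests that need traces with exactly known spike metrics.
#'
#' @param threshold spike onset voltage, mV.
#' @param peak spike peak voltage, mV.
#' @param fahp fAHP trough voltage, mV.
#' @param dap DAP amplitude above the fAHP, mV (0 suppresses the hump).
#' @param reset terminal voltage, mV.
#' @param t_rise,t_fall rise and fall times, ms.
#' @param t_dap time from fAHP to DAP peak, ms.
#' @param t_tail time from the last extremum to reset, ms.
#' @param dt_ms sample interval, ms.
#' @return Numeric vector of voltages, starting at `threshold`.
#' @export
spike_waveform <- function(threshold = -46, peak = 44, fahp = -58, dap = 0,
                           reset = -60, t_rise = 0.8, t_fall = 1.2,
                           t_dap = 2.5, t_tail = 8, dt_ms = 0.05) {
  kt <- c(0, t_rise, t_rise + t_fall)
  kv <- c(threshold, peak, fahp)
  if (dap > 0) {
    kt <- c(kt, kt[3] + t_dap, kt[3] + t_dap + t_tail)
    kv <- c(kv, fahp + dap, reset)
  } else {
    kt <- c(kt, kt[3] + t_tail)
    kv <- c(kv, reset)
  }
  # piecewise cubic smoothstep between knots: monotone within each segment,
  # zero slope at every knot (peak, trough and DAP are true local extrema)
  tt <- seq(0, max(kt), by = dt_ms)
  out <- numeric(length(tt))
  for (j in seq_len(length(kt) - 1L)) {
    sel <- tt >= kt[j] & tt <= kt[j + 1L]
    s <- (tt[sel] - kt[j]) / (kt[j + 1L] - kt[j])
    out[sel] <- kv[j] + (kv[j + 1L] - kv[j]) * (3 * s^2 - 2 * s^3)
  }
  out
}

#' Insert spike waveforms into a voltage trace
#'
#' Overwrites `voltage` with copies of `wave` starting at the given sample
#' indices; samples beyond the trace end are dropped. A convenience for
#' building ground-truth traces in tests.
#'
#' @param voltage numeric trace, mV.
#' @param at integer start indices.
#' @param wave waveform from [spike_waveform()].
#' @return Modified voltage vector.
#' @export
insert_spikes <- function(voltage, at, wave) {
  n <- length(voltage)
  for (i in at) {
    j <- seq.int(i, min(n, i + length(wave) - 1L))
    voltage[j] <- wave[seq_along(j)]
  }
  voltage
}
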