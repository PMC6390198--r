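#' Input resistance and anomalous rectification from subthreshold steps
#'
#' Least-squares fit of the no-intercept quadratic
#' \deqn{\Delta V = R_{N,0}\,\Delta I + c_{AR}\,\Delta I^2}
#' to steady-state voltage deflections of current steps that did not elicit
#' action potentials. \eqn{R_{N,0}} is the voltage-independent input
#' resistance and \eqn{c_{AR}} the coefficient of anomalous rectification.
#'
#' @param delta_i step amplitudes, pA.
#' @param delta_v steady-state voltage deflections, mV.
#' @return List with `R_N0` (MOhm), `c_AR` (mV/pA^2), `residual_norm` and
#'   `n_points`.
#' @export
fit_input_resistance <- function(delta_i, delta_v) {
  ok <- is.finite(delta_i) & is.finite(delta_v)
  delta_i <- delta_i[ok]; delta_v <- delta_v[ok]
  if (length(unique(delta_i)) < 3L)
    stop_ecs("insufficient_data",
             "need >= 3 distinct subthreshold step amplitudes, got %d",
             length(unique(delta_i)))
  X <- cbind(delta_i, delta_i^2)
  qrX <- qr(X)
  if (qrX$rank < 2L)
    stop_ecs("insufficient_data", "rank-deficient design for the quadratic fit")
  beta <- qr.coef(qrX, delta_v)
  res <- delta_v - X %*% beta
  list(R_N0 = unname(beta[1]) * 1000,  # mV/pA = GOhm -> MOhm
       c_AR = unname(beta[2]),
       residual_norm = sqrt(sum(res^2)),
       n_points = length(delta_i))
}

# window helpers (times in seconds on the sweep clock) ------------------------

.win_idx <- function(sweep, from_s, to_s) {
  which(sweep$time >= from_s - 1e-9 & sweep$time <= to_s + 1e-9)
}

.baseline_v <- function(sweep, config) {
  i <- .win_idx(sweep, sweep$stim_onset - config$baseline_ms / 1000,
                sweep$stim_onset)
  mean(sweep$voltage[head(i, -1L)])
}

.steady_v <- function(sweep, config) {
  i <- .win_idx(sweep, sweep$stim_offset - config$steady_state_ms / 1000,
                sweep$stim_offset)
  mean(sweep$voltage[i])
}

# running-mean smoothing used before extremum localization: the raw minimum
# of n noisy samples is biased by ~sigma*sqrt(2 log n)
.smooth_v <- function(v, sample_rate, width_ms) {
  k <- max(1L, round(width_ms / 1000 * sample_rate))
  if (k <= 1L) return(v)
  if (k %% 2L == 0L) k <- k + 1L
  pad <- (k - 1L) %/% 2L
  vs <- stats::filter(c(rep(v[1], pad), v, rep(v[length(v)], pad)),
                      rep(1 / k, k), sides = 2L)
  as.numeric(vs)[pad + seq_along(v)]
}

# robust double-exponential fit: grid of time-constant pairs, amplitudes by
# linear least squares, then Levenberg-Marquardt polish; best RSS wins.
# The window is block-averaged to <= 2 kHz first: decimation suppresses the
# sample noise that otherwise lets a spurious very slow component win.
.dexp_fit <- function(t_ms, y, bounds = c(0.1, 200)) {
  dt <- t_ms[2] - t_ms[1]
  dec <- max(1L, floor(0.5 / dt))
  if (dec > 1L) {
    nb <- floor(length(y) / dec)
    idx <- rep(seq_len(nb), each = dec)
    y <- as.numeric(tapply(y[seq_len(nb * dec)], idx, mean))
    t_ms <- as.numeric(tapply(t_ms[seq_len(nb * dec)], idx, mean))
  }
  best <- NULL
  tspan <- max(t_ms)
  t1s <- unique(pmin(pmax(c(1, 3, 8, 15), bounds[1]), bounds[2]))
  t2s <- unique(pmin(pmax(c(0.25, 0.6, 1) * tspan, bounds[1]), bounds[2]))
  for (t1 in t1s) for (t2 in t2s) {
    X <- cbind(1, exp(-t_ms / t1), exp(-t_ms / t2))
    cf <- tryCatch(qr.solve(X, y), error = function(e) NULL)
    if (is.null(cf)) next
    st <- list(y0 = cf[1], A1 = cf[2], t1 = t1, A2 = cf[3], t2 = t2)
    f <- tryCatch(
      minpack.lm::nlsLM(y ~ y0 + A1 * exp(-t_ms / t1) + A2 * exp(-t_ms / t2),
                        data = data.frame(t_ms = t_ms, y = y), start = st,
                        lower = c(-500, -500, bounds[1], -500, bounds[1]),
                        upper = c(500, 500, bounds[2], 500, bounds[2]),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(f)) next
    rss <- sum(resid(f)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = f, rss = rss)
  }
  best
}

#' Membrane time constant from a hyperpolarizing step
#'
#' Fits a double exponential to the onset of the voltage response of a
#' hyperpolarizing (nominally -300 pA) step and returns the larger of the
#' two fitted time constants. The fit window runs from stimulus onset over
#' `tau_fit_max_ms` (100 ms by default): for a sagging cell the
#' double-exponential passes through the voltage minimum and the early sag
#' relaxation, and it is that relaxation segment that makes the slower
#' component identifiable -- truncating the fit at the minimum leaves the
#' slow time constant ill-determined whenever the charging phase is fast.
#' If the double-exponential fit fails to converge the single-exponential
#' solution is returned with a downgrade flag.
#'
#' @param sweep a hyperpolarizing step sweep.
#' @param config an [ephys_config()].
#' @return List with `tau` (ms, the slower component), `components`
#'   (both taus, ms), `amplitudes` (mV), `residual_norm`, `downgraded`.
#' @export
membrane_time_constant <- function(sweep, config = ephys_config()) {
  if (sweep$step_amplitude >= 0)
    stop_ecs("malformed_input", "membrane time constant needs a hyperpolarizing step")
  i0 <- which.min(abs(sweep$time - sweep$stim_onset))
  iend <- max(.win_idx(sweep, sweep$stim_onset, sweep$stim_offset))
  imax <- i0 + round(config$tau_fit_max_ms / 1000 * sweep$sample_rate)
  iw <- seq.int(i0 + 1L, min(iend, imax))
  t_ms <- (sweep$time[iw] - sweep$stim_onset) * 1000
  y <- sweep$voltage[iw]
  best <- .dexp_fit(t_ms, y, config$tau_bounds)
  if (!is.null(best)) {
    cf <- coef(best$fit)
    taus <- sort(unname(cf[c("t1", "t2")]))
    amps <- unname(cf[c("A1", "A2")])[order(unname(cf[c("t1", "t2")]))]
    return(list(tau = taus[2], components = taus, amplitudes = amps,
                residual_norm = sqrt(best$rss), downgraded = FALSE))
  }
  # single-exponential fallback
  f1 <- tryCatch(
    minpack.lm::nlsLM(y ~ y0 + A1 * exp(-t_ms / t1),
                      data = data.frame(t_ms = t_ms, y = y),
                      start = list(y0 = y[length(y)], A1 = y[1] - y[length(y)],
                                   t1 = max(t_ms) / 3),
                      lower = c(-500, -500, config$tau_bounds[1]),
                      upper = c(500, 500, config$tau_bounds[2])),
    error = function(e) NULL)
  if (is.null(f1))
    stop_ecs("fit_failure", "time-constant fit did not converge")
  warn_ecs("fit_downgrade", "double-exponential fit failed; single exponential used")
  cf <- coef(f1)
  list(tau = unname(cf["t1"]), components = unname(cf["t1"]),
       amplitudes = unname(cf["A1"]),
       residual_norm = sqrt(sum(resid(f1)^2)), downgraded = TRUE)
}

#' Sag ratio and rebound potential from a hyperpolarizing step
#'
#' The sag ratio is
#' \deqn{(V_{baseline} - V_{ss}) / (V_{baseline} - V_{min})}
#' where \eqn{V_{min}} is the most negative voltage after stimulus onset and
#' \eqn{V_{ss}} the steady-state voltage at the end of the step; 1 means no
#' sag. The rebound is the maximal post-stimulus voltage minus baseline. If
#' a rebound spike occurs inside the post-stimulus window the rebound is
#' reported missing.
#'
#' @param sweep a hyperpolarizing step sweep (nominally -300 pA).
#' @param config an [ephys_config()].
#' @return List with `sag_ratio`, `rebound` (mV or NA), `V_baseline`,
#'   `V_min`, `V_ss`, `V_max_post` (mV) and `rebound_spike` (logical).
#' @export
sag_and_rebound <- function(sweep, config = ephys_config()) {
  vb <- .baseline_v(sweep, config)
  vsm <- .smooth_v(sweep$voltage, sweep$sample_rate, config$extremum_smooth_ms)
  istep <- .win_idx(sweep, sweep$stim_onset, sweep$stim_offset)
  vmin <- min(vsm[istep])
  vss <- .steady_v(sweep, config)
  if (vb <= vmin + 1e-9)
    stop_ecs("undefined_sag", "no hyperpolarization: V_baseline <= V_min")
  ipost <- .win_idx(sweep, sweep$stim_offset,
                    sweep$stim_offset + config$post_stim_ms / 1000)
  vmax_post <- max(vsm[ipost])
  post <- sweep
  post$voltage <- sweep$voltage[ipost]
  rebound_spike <- any(post$voltage >= config$min_peak) &&
    length(detect_aps(sweep, config)) > 0 &&
    any(sweep$time[detect_aps(sweep, config)] > sweep$stim_offset)
  list(sag_ratio = (vb - vss) / (vb - vmin),
       rebound = if (rebound_spike) NA_real_ else vmax_post - vb,
       V_baseline = vb, V_min = vmin, V_ss = vss, V_max_post = vmax_post,
       rebound_spike = rebound_spike)
}

#' Resting membrane potential from a spontaneous recording
#'
#' Arithmetic mean of the voltage over the full sweep (nominally 10 s of
#' zero-current recording). Spikes in the window trigger a warning but the
#' mean is still returned.
#'
#' @param sweep a `spontaneous` sweep.
#' @param config an [ephys_config()].
#' @return V_m in mV.
#' @export
resting_potential <- function(sweep, config = ephys_config()) {
  if (sweep$kind != "spontaneous")
    stop_ecs("malformed_input", "resting potential needs a spontaneous sweep")
  if (length(detect_aps(sweep, config)) > 0)
    warn_ecs("spike_contaminated", "spontaneous sweep contains spikes; mean returned anyway")
  mean(sweep$voltage)
}
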