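#' Analysis configuration for electrophysiology feature extraction
#'
#' All windows and thresholds used by the feature extractors live in one
#' object that is serialized verbatim into every output for provenance.
#' Defaults follow standard current-clamp practice; every value is
#' overridable.
#'
#' @param dvdt_threshold AP onset criterion on dV/dt, V/s.
#' @param min_peak minimum AP peak voltage, mV.
#' @param refractory_ms detection refractory window, ms.
#' @param baseline_ms pre-stimulus window for V_baseline, ms.
#' @param steady_state_ms steady-state window at the end of a step, ms.
#' @param post_stim_ms search window after stimulus offset for rebound and
#'   post-step AHP, ms.
#' @param fahp_ms search window after the AP peak for the fAHP, ms.
#' @param dap_ms search window after the fAHP for the DAP, ms.
#' @param threshold_window_ms pre-peak window searched for the
#'   second-derivative maximum, ms.
#' @param threshold_smooth_ms width of the local cubic-polynomial
#'   (Savitzky-Golay) smoother used before differentiation, ms.
#' @param tau_fit_max_ms cap on the double-exponential fit window measured
#'   from stimulus onset, ms.
#' @param extremum_smooth_ms running-mean width applied before locating
#'   voltage extrema (V_min, rebound maximum, post-step AHP minimum), ms;
#'   suppresses the selection bias of raw-sample extremes under noise.
#' @param tau_bounds lower/upper bounds for fitted time constants, ms.
#' @param zap_band analyzed frequency band for resonance, Hz.
#' @param zap_smooth_hz bandwidth of the impedance-profile smoother, Hz.
#' @param fi_range currents included in firing-frequency measures, pA.
#' @param ahp_range currents included in the post-step AHP measure, pA.
#' @param train_step_pA current step(s) used for spike-train features, pA.
#' @param qc_vm_max V_m exclusion bound, mV (cells with V_m above are excluded).
#' @param qc_amp_min AP amplitude exclusion bound, mV.
#' @param qc_bridge_max bridge balance exclusion bound, MOhm.
#'
#' @return A list of class `ecs_config`.
#' @export
ephys_config <- function(dvdt_threshold = 20, min_peak = -10, refractory_ms = 2,
                         baseline_ms = 100, steady_state_ms = 200,
                         post_stim_ms = 500, fahp_ms = 5, dap_ms = 20,
                         threshold_window_ms = 5, threshold_smooth_ms = 0.25,
                         tau_fit_max_ms = 100, tau_bounds = c(0.1, 200),
                         extremum_smooth_ms = 1,
                         zap_band = c(0.5, 20), zap_smooth_hz = 0.5,
                         fi_range = c(200, 500), ahp_range = c(50, 500),
                         train_step_pA = c(200, 210),
                         qc_vm_max = -57, qc_amp_min = 75, qc_bridge_max = 22) {
  structure(list(dvdt_threshold = dvdt_threshold, min_peak = min_peak,
                 refractory_ms = refractory_ms, baseline_ms = baseline_ms,
                 steady_state_ms = steady_state_ms, post_stim_ms = post_stim_ms,
                 fahp_ms = fahp_ms, dap_ms = dap_ms,
                 threshold_window_ms = threshold_window_ms,
                 threshold_smooth_ms = threshold_smooth_ms,
                 tau_fit_max_ms = tau_fit_max_ms, tau_bounds = tau_bounds,
                 extremum_smooth_ms = extremum_smooth_ms,
                 zap_band = zap_band, zap_smooth_hz = zap_smooth_hz,
                 fi_range = fi_range, ahp_range = ahp_range,
                 train_step_pA = train_step_pA,
                 qc_vm_max = qc_vm_max, qc_amp_min = qc_amp_min,
                 qc_bridge_max = qc_bridge_max),
            class = "ecs_config")
}

#' Serialize / restore a configuration
#'
#' Configurations round-trip losslessly through JSON so that every output
#' can carry the exact settings that produced it.
#'
#' @param config an `ecs_config` (or any named list of scalars/vectors).
#' @param path file path.
#' @return `read_config` returns an `ecs_config`.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(ephys_config, x)
}
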