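#' Extract the full feature set of one cell
#'
#' Runs every feature extractor on the appropriate protocol sweeps of a
#' recorded cell: input resistance and anomalous rectification from the
#' subthreshold members of the step family, membrane time constant, sag
#' ratio and rebound from the -300 pA step, resting potential from the
#' spontaneous sweep, rheobase from the 10-pA series, AP waveform features
#' from the first AP of the first spiking rheobase sweep, spike-train
#' features from the +200/210 pA step, the f-I curve, ZAP resonance, and
#' the quality-control verdict.
#'
#' @param cell an [cell_recording()] object.
#' @param config an [ephys_config()].
#' @return List of class `ecs_features` with `features` (one-row
#'   data.frame), `per_ap` (per-AP train metrics), `fi` (f-I data.frame),
#'   `impedance`, `qc`, and `provenance` (the config plus fit diagnostics).
#' @export
extract_features <- function(cell, config = ephys_config()) {
  steps <- sweeps_of(cell, kind = "step")
  rheo <- sweeps_of(cell, kind = "rheobase_step")
  zap <- sweeps_of(cell, kind = "zap")
  spont <- sweeps_of(cell, kind = "spontaneous")
  prov <- list(config = unclass(config))

  # input resistance from subthreshold steps (spiking sweeps excluded)
  rin <- NULL
  if (length(steps) >= 3) {
    sub <- Filter(function(sw) length(detect_aps(sw, config)) == 0, steps)
    di <- vapply(sub, `[[`, numeric(1), "step_amplitude")
    keep <- di != 0
    dv <- vapply(sub[keep], function(sw)
      .steady_v(sw, config) - .baseline_v(sw, config), numeric(1))
    rin <- tryCatch(fit_input_resistance(di[keep], dv), error = function(e) NULL)
  }

  # -300 pA members: tau, sag, rebound
  neg <- Filter(function(sw) sw$step_amplitude == -300, steps)
  tau <- sag <- NULL
  if (length(neg) >= 1) {
    tau <- tryCatch(membrane_time_constant(neg[[1]], config), error = function(e) NULL)
    sag <- tryCatch(sag_and_rebound(neg[[1]], config), error = function(e) NULL)
  }

  v_m <- if (length(spont) >= 1) resting_potential(spont[[1]], config) else NA_real_

  rh <- if (length(rheo) >= 1) rheobase(rheo, config) else NULL
  apf <- NULL
  if (!is.null(rh) && rh$reached) {
    apf <- tryCatch(
      ap_waveform_features(rheo[[rh$sweep_index]], 1L, region = cell$region,
                           config = config),
      error = function(e) NULL)
  }

  train <- NULL
  tr_sw <- Filter(function(sw) sw$step_amplitude %in% config$train_step_pA, steps)
  if (length(tr_sw) >= 1)
    train <- spike_train_features(tr_sw[[1]], config)

  fi <- if (length(steps) >= 1) {
    pos <- Filter(function(sw) sw$step_amplitude > 0, steps)
    if (length(pos) >= 1) fi_curve(pos, config) else NULL
  } else NULL

  res <- if (length(zap) >= 1)
    tryCatch(resonance_frequency(zap[[1]], config),
             error = function(e) { prov$zap_error <<- conditionMessage(e); NULL })
  else NULL

  qc <- qc_filter(v_m = v_m,
                  ap_amplitude = if (is.null(apf)) NA_real_ else apf$amplitude,
                  bridge_balance = cell$bridge_balance,
                  config = config)

  prov$tau_fit <- tau[c("components", "amplitudes", "residual_norm", "downgraded")]
  prov$rin_fit <- rin[c("residual_norm", "n_points")]
  prov$qc_reasons <- qc$reasons

  feats <- data.frame(
    cell_id = cell$cell_id, animal_id = cell$animal_id,
    genotype = cell$genotype, age_group = cell$age_group, sex = cell$sex,
    region = cell$region, setup = cell$setup,
    R_N0 = .nn(rin$R_N0), c_AR = .nn(rin$c_AR),
    tau = .nn(tau$tau),
    sag_ratio = .nn(sag$sag_ratio), rebound = .nn(sag$rebound),
    V_m = v_m,
    rheobase = if (is.null(rh)) NA_real_ else rh$rheobase,
    ap_threshold = .nn(apf$threshold), ap_amplitude = .nn(apf$amplitude),
    ap_half_width = .nn(apf$half_width),
    fAHP = .nn(apf$fAHP), DAP = .nn(apf$DAP),
    isi1_over_isi2 = .nn(train$isi1_over_isi2),
    adaptation_ratio = .nn(train$adaptation_ratio),
    resonance_frequency = .nn(res$resonance_frequency),
    is_resonant = if (is.null(res)) NA else res$is_resonant,
    qc_included = qc$included,
    stringsAsFactors = FALSE)

  structure(list(features = feats, per_ap = train, fi = fi,
                 impedance = if (is.null(res)) NULL else res$impedance,
                 qc = qc, provenance = prov),
            class = "ecs_features")
}

.nn <- function(x) if (is.null(x) || length(x) == 0) NA_real_ else x

#' Feature table for a list of cells
#'
#' @param cells list of [cell_recording()] objects.
#' @param config an [ephys_config()].
#' @return data.frame with one row per cell (the `features` rows of
#'   [extract_features()]).
#' @export
extract_feature_table <- function(cells, config = ephys_config()) {
  do.call(rbind, lapply(cells, function(cl) extract_features(cl, config)$features))
}
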