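#' Current-clamp sweep container
#'
#' A sweep is one time-aligned (time, command current, membrane voltage)
#' record for a single protocol element: a current step, a rheobase-series
#' step, a ZAP (chirp) stimulus, or a spontaneous (zero-current) recording.
#'
#' @param time numeric vector of sample times in seconds, uniformly spaced
#'   and strictly increasing.
#' @param voltage membrane voltage in mV, same length as `time`, all finite.
#' @param current command current in pA; a scalar is recycled.
#' @param stim_onset,stim_offset stimulus window in seconds;
#'   `stim_onset < stim_offset <= max(time)`.
#' @param step_amplitude step amplitude in pA (0 for spontaneous and ZAP).
#' @param kind one of `"step"`, `"rheobase_step"`, `"zap"`, `"spontaneous"`.
#'
#' @return An object of class `ecs_sweep`: a list with elements `time`,
#'   `voltage`, `current`, `sample_rate` (Hz), `stim_onset`, `stim_offset`,
#'   `step_amplitude`, `kind`.
#' @export
sweep_trace <- function(time, voltage, current = 0,
                        stim_onset, stim_offset,
                        step_amplitude = 0,
                        kind = c("step", "rheobase_step", "zap", "spontaneous")) {
  kind <- match.arg(kind)
  n <- length(time)
  if (n < 2L) stop_ecs("malformed_input", "a sweep needs at least 2 samples")
  if (length(voltage) != n)
    stop_ecs("malformed_input", "time and voltage lengths differ")
  if (!all(is.finite(voltage)))
    stop_ecs("malformed_input", "voltage must be finite everywhere")
  dt <- diff(time)
  if (any(dt <= 0)) stop_ecs("malformed_input", "time must be strictly increasing")
  dt0 <- (time[n] - time[1]) / (n - 1)
  if (max(abs(dt - dt0)) > dt0 + 1e-12)
    stop_ecs("malformed_input", "time must be uniform within one sample period")
  if (length(current) == 1L) current <- rep(current, n)
  if (length(current) != n)
    stop_ecs("malformed_input", "current must be scalar or match time")
  if (!(stim_onset < stim_offset && stim_offset <= time[n] + dt0 / 2))
    stop_ecs("malformed_input", "need stim_onset < stim_offset <= last time")
  structure(list(time = as.numeric(time), voltage = as.numeric(voltage),
                 current = as.numeric(current),
                 sample_rate = 1 / dt0,
                 stim_onset = stim_onset, stim_offset = stim_offset,
                 step_amplitude = step_amplitude, kind = kind),
            class = "ecs_sweep")
}

#' @export
print.ecs_sweep <- function(x, ...) {
  cat(sprintf("<ecs_sweep> %s, %.3f s at %.0f Hz, step %+g pA, stim [%g, %g] s\n",
              x$kind, x$time[length(x$time)] - x$time[1], x$sample_rate,
              x$step_amplitude, x$stim_onset, x$stim_offset))
  invisible(x)
}

#' All sweeps and metadata for one recorded cell
#'
#' The unit of quality control and feature extraction: every protocol sweep
#' recorded from one cell, together with the animal-level metadata consumed
#' by the cohort statistics.
#'
#' @param sweeps list of [sweep_trace()] objects.
#' @param cell_id,animal_id identifiers (character scalars).
#' @param genotype one of `"+/+"`, `"-/-"`, `"wt"`.
#' @param age_group,sex,region,setup character metadata; `region` is
#'   `"MEC"` or `"LEC"` and gates fAHP/DAP measurement.
#' @param bridge_balance bridge balance in MOhm (used by [qc_filter()]).
#'
#' @return An object of class `ecs_cell`.
#' @export
cell_recording <- function(sweeps, cell_id, animal_id,
                           genotype = c("+/+", "-/-", "wt"),
                           age_group = "1mo", sex = c("F", "M"),
                           region = c("MEC", "LEC"), setup = "rig1",
                           bridge_balance = NA_real_) {
  genotype <- match.arg(genotype)
  sex <- match.arg(sex)
  region <- match.arg(region)
  if (!all(vapply(sweeps, inherits, logical(1), "ecs_sweep")))
    stop_ecs("malformed_input", "sweeps must all be ecs_sweep objects")
  structure(list(sweeps = sweeps, cell_id = cell_id, animal_id = animal_id,
                 genotype = genotype, age_group = age_group, sex = sex,
                 region = region, setup = setup,
                 bridge_balance = bridge_balance),
            class = "ecs_cell")
}

#' @export
print.ecs_cell <- function(x, ...) {
  kinds <- table(vapply(x$sweeps, `[[`, character(1), "kind"))
  cat(sprintf("<ecs_cell> %s (animal %s, %s, %s, %s): %d sweeps [%s]\n",
              x$cell_id, x$animal_id, x$genotype, x$region, x$age_group,
              length(x$sweeps),
              paste(sprintf("%s:%d", names(kinds), kinds), collapse = ", ")))
  invisible(x)
}

#' Select sweeps of a cell by kind and/or amplitude
#'
#' @param cell an `ecs_cell`.
#' @param kind optional sweep kind filter.
#' @param amplitude optional step amplitude filter (pA, exact match).
#' @return list of matching `ecs_sweep` objects.
#' @export
sweeps_of <- function(cell, kind = NULL, amplitude = NULL) {
  s <- cell$sweeps
  if (!is.null(kind))
    s <- Filter(function(sw) sw$kind %in% kind, s)
  if (!is.null(amplitude))
    s <- Filter(function(sw) sw$step_amplitude %in% amplitude, s)
  s
}

# internal condition helpers -------------------------------------------------

stop_ecs <- function(class, msg, ...) {
  stop(structure(class = c(paste0("ecs_", class), "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}

warn_ecs <- function(class, msg, ...) {
  warning(structure(class = c(paste0("ecs_", class), "warning", "condition"),
                    list(message = sprintf(msg, ...), call = sys.call(-1))))
}
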