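#' Write a cell recording to sweep CSVs plus a JSON manifest
#'
#' Each sweep becomes one CSV (`time_s, current_pA, voltage_mV`); the
#' manifest records the cell and animal metadata, the sweep list with
#' kinds, amplitudes and stimulus windows, and an md5 checksum per file.
#'
#' @param cells an `ecs_cell` or list of them.
#' @param dir output directory (created if needed).
#' @param manifest_name manifest file name.
#' @return Invisibly, the manifest path.
#' @export
write_cell_recording <- function(cells, dir, manifest_name = "manifest.json") {
  if (inherits(cells, "ecs_cell")) cells <- list(cells)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  man_cells <- lapply(cells, function(cl) {
    sw_entries <- lapply(seq_along(cl$sweeps), function(i) {
      sw <- cl$sweeps[[i]]
      fn <- sprintf("%s_sweep%03d.csv", cl$cell_id, i)
      path <- file.path(dir, fn)
      write.csv(data.frame(time_s = sw$time, current_pA = sw$current,
                           voltage_mV = sw$voltage),
                path, row.names = FALSE)
      list(file = fn, kind = sw$kind, step_amplitude_pA = sw$step_amplitude,
           stim_onset_s = sw$stim_onset, stim_offset_s = sw$stim_offset,
           md5 = unname(tools::md5sum(path)))
    })
    list(cell_id = cl$cell_id, animal_id = cl$animal_id,
         genotype = cl$genotype, age_group = cl$age_group, sex = cl$sex,
         region = cl$region, setup = cl$setup,
         bridge_balance_MOhm = cl$bridge_balance, sweeps = sw_entries)
  })
  man <- list(schema_version = 1L, cells = man_cells)
  path <- file.path(dir, manifest_name)
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read cell recordings from a manifest
#'
#' Validates the manifest (unique ids, known genotype labels, files
#' present), reads every sweep CSV, checks units/columns and monotone
#' time, and rebuilds the [cell_recording()] objects.
#'
#' @param manifest_path path to a manifest written by
#'   [write_cell_recording()].
#' @param verify_checksums recompute and compare md5 sums?
#' @return List of `ecs_cell` objects.
#' @export
read_sweeps <- function(manifest_path, verify_checksums = FALSE) {
  man <- jsonlite::read_json(manifest_path)
  dir <- dirname(manifest_path)
  ids <- vapply(man$cells, `[[`, character(1), "cell_id")
  if (anyDuplicated(ids))
    stop_ecs("malformed_input", "duplicate cell ids in manifest")
  lapply(man$cells, function(mc) {
    if (!mc$genotype %in% c("+/+", "-/-", "wt"))
      stop_ecs("malformed_input", "unknown genotype '%s'", mc$genotype)
    sweeps <- lapply(mc$sweeps, function(ms) {
      path <- file.path(dir, ms$file)
      if (!file.exists(path))
        stop_ecs("missing_file", "sweep file not found: %s", path)
      if (verify_checksums && !identical(unname(tools::md5sum(path)), ms$md5))
        stop_ecs("checksum_mismatch", "checksum mismatch for %s", path)
      df <- read.csv(path)
      need <- c("time_s", "current_pA", "voltage_mV")
      if (!all(need %in% names(df)))
        stop_ecs("missing_column", "sweep file %s lacks column(s): %s", ms$file,
                 paste(setdiff(need, names(df)), collapse = ", "))
      sweep_trace(df$time_s, df$voltage_mV, df$current_pA,
                  stim_onset = ms$stim_onset_s, stim_offset = ms$stim_offset_s,
                  step_amplitude = ms$step_amplitude_pA, kind = ms$kind)
    })
    cell_recording(sweeps, cell_id = mc$cell_id, animal_id = mc$animal_id,
                   genotype = mc$genotype, age_group = mc$age_group,
                   sex = mc$sex, region = mc$region, setup = mc$setup,
                   bridge_balance = mc$bridge_balance_MOhm)
  })
}

#' Write / read a VSDI movie
#'
#' Two on-disk layouts share one JSON sidecar (dimensions, frame interval,
#' stimulus frames, condition, stimulus, trial): `raw` stores the stack as
#' little-endian doubles and round-trips bit-exactly; `tiff` stores one
#' 32-bit float page per frame (exact only to float precision). Frame
#' indices in the sidecar are 0-based.
#'
#' @param movie an [vsdi_movie()].
#' @param path data file path; the sidecar is `<path>.json`.
#' @param format `"raw"` or `"tiff"`.
#' @return `read_vsdi_movie` returns an `ecs_vsdi`.
#' @export
write_vsdi_movie <- function(movie, path, format = c("raw", "tiff")) {
  format <- match.arg(format)
  d <- dim(movie$frames)
  if (format == "raw") {
    con <- file(path, "wb")
    writeBin(as.numeric(movie$frames), con, size = 8, endian = "little")
    close(con)
  } else {
    pages <- lapply(seq_len(d[3]), function(i) movie$frames[, , i])
    tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  }
  sidecar <- list(height = d[1], width = d[2], frames = d[3],
                  frame_interval_ms = movie$frame_interval_ms,
                  stim_frames_0based = movie$stim_frames - 1L,
                  n_baseline_frames = movie$n_baseline_frames,
                  condition = movie$condition, stimulus = movie$stimulus,
                  trial_id = movie$trial_id, format = format)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_vsdi_movie
#' @param path data file path written by [write_vsdi_movie()].
#' @export
read_vsdi_movie <- function(path) {
  sc <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  d <- c(sc$height, sc$width, sc$frames)
  if (identical(sc$format, "raw")) {
    con <- file(path, "rb")
    x <- readBin(con, "numeric", n = prod(d), size = 8, endian = "little")
    close(con)
    if (length(x) != prod(d))
      stop_ecs("dimension_mismatch",
               "raw stack holds %d values but sidecar declares %d",
               length(x), prod(d))
    frames <- array(x, d)
  } else {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (length(pages) != d[3] || !identical(dim(pages[[1]]), d[1:2]))
      stop_ecs("dimension_mismatch",
               "TIFF geometry does not match the sidecar")
    frames <- array(unlist(pages), c(d[1], d[2], d[3]))
  }
  vsdi_movie(frames, sc$frame_interval_ms, sc$stim_frames_0based + 1L,
             sc$n_baseline_frames, sc$condition, sc$stimulus, sc$trial_id)
}

#' Write a results table as CSV with a stable column order
#'
#' @param rows data.frame.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_table <- function(rows, path) {
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
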