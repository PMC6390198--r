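#' End-to-end demonstration pipeline
#'
#' Chains the three stages on synthetic data: simulate model cells and
#' extract their features; simulate a VSDI scene and quantify it; simulate
#' a cohort and fit the mixed model. All artifacts (sweep CSVs + manifest,
#' movie + sidecar, feature and quantification tables, fit report, and the
#' serialized configuration) are written under `out_dir`.
#'
#' @param out_dir output directory.
#' @param seed integer seed driving every stage.
#' @param n_cells model cells per phenotype.
#' @param n_trials VSDI trials.
#' @param config an [ephys_config()].
#' @return Invisibly, 0 on success (errors propagate as conditions); a
#'   list of artifact paths is attached as attribute `artifacts`.
#' @export
run_pipeline <- function(out_dir, seed = 1, n_cells = 2, n_trials = 8,
                         config = ephys_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()

  # stage 1: cells -> features
  cells <- list()
  for (i in seq_len(n_cells)) {
    cells[[length(cells) + 1L]] <-
      generate_model_cell(phenotype_fan(), recovery_protocol(),
                          seed = seed + i,
                          cell_id = sprintf("fan%02d", i),
                          animal_id = sprintf("rat%02d", (i + 1L) %/% 2L))
    cells[[length(cells) + 1L]] <-
      generate_model_cell(phenotype_stellate(), recovery_protocol(),
                          seed = seed + 100 + i,
                          cell_id = sprintf("ste%02d", i),
                          animal_id = sprintf("rat%02d", 10L + (i + 1L) %/% 2L))
  }
  paths$manifest <- write_cell_recording(cells, file.path(out_dir, "cells"))
  cells2 <- read_sweeps(paths$manifest)
  feats <- extract_feature_table(cells2, config)
  paths$features <- write_table(feats, file.path(out_dir, "features.csv"))

  # stage 2: VSDI
  sc <- vsdi_scene()
  trials <- generate_vsdi_movie(sc, n_trials = n_trials, seed = seed)
  paths$movie <- write_vsdi_movie(trials[[1]],
                                  file.path(out_dir, "trial1.raw"))
  q <- quantify_vsdi(trials, attr(trials, "rois"))
  paths$vsdi <- write_table(
    data.frame(roi = names(q$integral), integral = unname(q$integral),
               activated_pixels = q$activated_pixels,
               condition = sc$condition, stimulus = sc$stimulus),
    file.path(out_dir, "vsdi_quantification.csv"))

  # stage 3: cohort statistics
  tab <- generate_cohort(cohort_spec(n_animals_per_genotype = 8,
                                     cells_per_animal = 4,
                                     effect_genotype = 0.03),
                         seed = seed)
  fit <- fit_lmm(tab, lmm_spec("sag_ratio", fixed = c("genotype", "age", "sex")))
  paths$fit <- write_table(fit$coefficients, file.path(out_dir, "lmm_fit.csv"))
  paths$emm <- write_table(fit$emm, file.path(out_dir, "lmm_emm.csv"))

  paths$config <- write_config(config, file.path(out_dir, "config.json"))
  out <- invisible(0L)
  attr(out, "artifacts") <- paths
  out
}
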