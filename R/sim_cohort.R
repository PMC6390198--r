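#' Specification of a synthetic multi-animal cohort
#'
#' Defines the hierarchical design used to exercise the mixed-model stage:
#' animals per genotype (balanced over sex, age and setup), cells per
#' animal, fixed-effect sizes, and the between-animal and residual
#' variance components. An optional repeated factor adds correlated
#' within-cell measurements with a chosen covariance structure.
#'
#' @param n_animals_per_genotype animals per genotype level.
#' @param cells_per_animal cells (or slices) per animal.
#' @param genotypes,ages,sexes,setups factor levels.
#' @param grand_mean response grand mean.
#' @param effect_genotype,effect_age,effect_sex,effect_setup additive shift
#'   of the second level of each factor.
#' @param sd_animal between-animal (random intercept) SD.
#' @param sd_residual residual SD.
#' @param response response column name.
#' @param repeated optional list describing a within-cell factor:
#'   `list(name, levels, structure = c("compound_symmetry", "diagonal"),
#'   rho, sds, level_effects)`; `sds` (length `levels`) is used by the
#'   diagonal structure, `rho` by compound symmetry, `level_effects` adds
#'   a fixed profile over the repeated levels.
#' @return List of class `ecs_cohort_spec`.
#' @export
cohort_spec <- function(n_animals_per_genotype = 10, cells_per_animal = 4,
                        genotypes = c("-/-", "+/+"),
                        ages = c("1mo", "3mo"), sexes = c("F", "M"),
                        setups = "rig1",
                        grand_mean = 0.6, effect_genotype = 0,
                        effect_age = 0, effect_sex = 0, effect_setup = 0,
                        sd_animal = 0.02, sd_residual = 0.04,
                        response = "sag_ratio", repeated = NULL) {
  stopifnot(sd_animal >= 0, sd_residual >= 0,
            n_animals_per_genotype >= 1, cells_per_animal >= 1)
  if (!is.null(repeated)) {
    repeated$structure <- match.arg(repeated$structure,
                                    c("compound_symmetry", "diagonal"))
    if (is.null(repeated$level_effects))
      repeated$level_effects <- rep(0, repeated$levels)
  }
  structure(list(n_animals_per_genotype = n_animals_per_genotype,
                 cells_per_animal = cells_per_animal,
                 genotypes = genotypes, ages = ages, sexes = sexes,
                 setups = setups, grand_mean = grand_mean,
                 effect_genotype = effect_genotype, effect_age = effect_age,
                 effect_sex = effect_sex, effect_setup = effect_setup,
                 sd_animal = sd_animal, sd_residual = sd_residual,
                 response = response, repeated = repeated),
            class = "ecs_cohort_spec")
}

.cycle <- function(levels, i) levels[(i - 1L) %% length(levels) + 1L]

#' Generate a cohort table with known ground truth
#'
#' Hierarchical draws: one random intercept per animal, then per-cell
#' responses = grand mean + fixed effects + animal effect + residual.
#' With a repeated factor, each cell contributes one row per level with
#' residuals drawn from the requested covariance structure. The seed
#' fully determines the output.
#'
#' @param spec an [cohort_spec()].
#' @param seed integer seed.
#' @return Long-format data.frame (class amended with attribute
#'   `ground_truth` holding the generating effects).
#' @export
generate_cohort <- function(spec, seed = 1) {
  set.seed(seed)
  rows <- list()
  an_i <- 0L
  for (g in spec$genotypes) {
    for (a in seq_len(spec$n_animals_per_genotype)) {
      an_i <- an_i + 1L
      animal <- sprintf("rat%03d", an_i)
      age <- .cycle(spec$ages, a)
      sex <- .cycle(spec$sexes, a + (a - 1L) %/% length(spec$sexes))
      setup <- .cycle(spec$setups, a)
      u <- rnorm(1, 0, spec$sd_animal)
      mu_a <- spec$grand_mean +
        spec$effect_genotype * (g == spec$genotypes[2]) +
        spec$effect_age * (age == spec$ages[min(2, length(spec$ages))] &&
                             length(spec$ages) > 1) +
        spec$effect_sex * (sex == spec$sexes[min(2, length(spec$sexes))] &&
                             length(spec$sexes) > 1) +
        spec$effect_setup * (setup == spec$setups[min(2, length(spec$setups))] &&
                               length(spec$setups) > 1) + u
      for (cl in seq_len(spec$cells_per_animal)) {
        cell <- sprintf("%s_c%02d", animal, cl)
        if (is.null(spec$repeated)) {
          y <- mu_a + rnorm(1, 0, spec$sd_residual)
          rows[[length(rows) + 1L]] <- data.frame(
            animal_id = animal, cell_id = cell, genotype = g, age = age,
            sex = sex, setup = setup, value = y)
        } else {
          rp <- spec$repeated
          k <- rp$levels
          Sig <- if (rp$structure == "compound_symmetry") {
            s2 <- spec$sd_residual^2
            s2 * ((1 - rp$rho) * diag(k) + rp$rho * matrix(1, k, k))
          } else {
            diag(rp$sds^2, k)
          }
          e <- drop(rnorm(k) %*% chol(Sig))
          y <- mu_a + rp$level_effects + e
          rows[[length(rows) + 1L]] <- data.frame(
            animal_id = animal, cell_id = cell, genotype = g, age = age,
            sex = sex, setup = setup,
            level = factor(seq_len(k)), value = y)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  # fix factor levels in the declared order (locale-independent)
  out$genotype <- factor(out$genotype, levels = spec$genotypes)
  out$age <- factor(out$age, levels = spec$ages)
  out$sex <- factor(out$sex, levels = spec$sexes)
  out$setup <- factor(out$setup, levels = spec$setups)
  names(out)[names(out) == "value"] <- spec$response
  if (!is.null(spec$repeated))
    names(out)[names(out) == "level"] <- spec$repeated$name
  attr(out, "ground_truth") <- list(
    grand_mean = spec$grand_mean, effect_genotype = spec$effect_genotype,
    effect_age = spec$effect_age, effect_sex = spec$effect_sex,
    effect_setup = spec$effect_setup, sd_animal = spec$sd_animal,
    sd_residual = spec$sd_residual, repeated = spec$repeated)
  out
}
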