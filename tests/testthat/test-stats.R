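test_that("delta-delta-Ct arithmetic and calls follow the definitions", {
  # sample identical to the homozygous reference
  r <- ddct_genotype(24, 20, 24, 20)
  expect_equal(r$ddct, 0)
  expect_equal(r$relative_quantity, 1)
  expect_identical(r$call, "homozygous")
  # one cycle higher target -> half the copies -> hemizygous
  r2 <- ddct_genotype(25, 20, 24, 20)
  expect_equal(r2$relative_quantity, 0.5)
  expect_identical(r2$call, "hemizygous")
  # undetermined target with detected normalizer -> negative
  r3 <- ddct_genotype(NA, 20, 24, 20)
  expect_identical(r3$call, "negative")
  expect_equal(r3$relative_quantity, 0)
})

test_that("relative quantity halves per unit of ddct", {
  for (d in seq(-3, 3, 0.5)) {
    r <- ddct_genotype(24 + d, 20, 24, 20)
    expect_equal(r$relative_quantity, 2^(-d), tolerance = 1e-12)
  }
})

test_that("with zero between-animal variance the fixed effects match OLS", {
  spec <- cohort_spec(n_animals_per_genotype = 6, cells_per_animal = 4,
                      sd_animal = 0, sd_residual = 0.05,
                      effect_genotype = 0.04)
  tab <- generate_cohort(spec, seed = 11)
  fit <- fit_lmm(tab, lmm_spec("sag_ratio", fixed = c("genotype", "age", "sex")))
  ols <- lm(sag_ratio ~ genotype + age + sex, data = tab)
  expect_equal(unname(fit$coefficients$estimate),
               unname(coef(ols)), tolerance = 1e-6)
})

test_that("marginal means are shift-equivariant and relabeling-invariant", {
  spec <- cohort_spec(n_animals_per_genotype = 5, cells_per_animal = 3,
                      effect_genotype = 0.03)
  tab <- generate_cohort(spec, seed = 3)
  ms <- lmm_spec("sag_ratio", fixed = c("genotype", "age", "sex"))
  f1 <- fit_lmm(tab, ms)
  tab2 <- tab
  tab2$sag_ratio <- tab$sag_ratio + 5
  f2 <- fit_lmm(tab2, ms)
  expect_equal(f2$emm$emmean, f1$emm$emmean + 5, tolerance = 1e-8)
  # relabel age levels (bijection) -> same genotype marginal means
  tab3 <- tab
  tab3$age <- factor(ifelse(tab$age == "1mo", "juvenile", "adult"))
  f3 <- fit_lmm(tab3, ms)
  expect_equal(sort(f3$emm$emmean), sort(f1$emm$emmean), tolerance = 1e-8)
})

test_that("marginal means agree with the reference-grid implementation", {
  skip_if_not_installed("emmeans")
  spec <- cohort_spec(n_animals_per_genotype = 6, cells_per_animal = 4,
                      effect_genotype = 0.04, sd_animal = 0.02)
  tab <- generate_cohort(spec, seed = 5)
  fit <- fit_lmm(tab, lmm_spec("sag_ratio", fixed = c("genotype", "age", "sex")))
  em <- emmeans::emmeans(fit$model, "genotype", data = tab)
  es <- as.data.frame(em)
  expect_equal(fit$emm$emmean, es$emmean, tolerance = 1e-8)
  expect_equal(fit$emm$se, es$SE, tolerance = 1e-6)
})

test_that("an injected genotype effect is estimated and tested", {
  spec <- cohort_spec(n_animals_per_genotype = 10, cells_per_animal = 4,
                      effect_genotype = 0.05, sd_animal = 0.01,
                      sd_residual = 0.02)
  tab <- generate_cohort(spec, seed = 7)
  fit <- fit_lmm(tab, lmm_spec("sag_ratio", fixed = c("genotype", "age", "sex")))
  ctr <- attr(fit$emm, "contrast")
  expect_equal(ctr$estimate, 0.05, tolerance = 0.3)
  expect_lt(fit$tests$p[fit$tests$term == "genotype"], 0.01)
})

test_that("covariance selection recovers the generating structure", {
  # compound-symmetry data
  cs_wins <- 0; diag_wins <- 0
  n_rep <- 20
  for (s in seq_len(n_rep)) {
    spec <- cohort_spec(n_animals_per_genotype = 6, cells_per_animal = 3,
                        sd_animal = 0.01, sd_residual = 0.05,
                        repeated = list(name = "ap_number", levels = 4,
                                        structure = "compound_symmetry",
                                        rho = 0.6))
    tab <- generate_cohort(spec, seed = 100 + s)
    ms <- lmm_spec("sag_ratio", fixed = c("genotype", "sex"),
                   repeated = "ap_number", subject = "cell_id")
    sel <- select_covariance(tab, ms,
                             candidates = c("compound_symmetry", "diagonal"))
    if (sel$chosen == "compound_symmetry") cs_wins <- cs_wins + 1
  }
  expect_gt(cs_wins, n_rep / 2)
  for (s in seq_len(n_rep)) {
    spec <- cohort_spec(n_animals_per_genotype = 6, cells_per_animal = 3,
                        sd_animal = 0.01, sd_residual = 0.05,
                        repeated = list(name = "ap_number", levels = 4,
                                        structure = "diagonal",
                                        sds = c(0.01, 0.03, 0.09, 0.27)))
    tab <- generate_cohort(spec, seed = 200 + s)
    ms <- lmm_spec("sag_ratio", fixed = c("genotype", "sex"),
                   repeated = "ap_number", subject = "cell_id")
    sel <- select_covariance(tab, ms,
                             candidates = c("compound_symmetry", "diagonal"))
    if (sel$chosen == "diagonal") diag_wins <- diag_wins + 1
  }
  expect_gt(diag_wins, n_rep / 2)
})

test_that("a single within-level collapses the candidates to the simpler one", {
  spec <- cohort_spec(n_animals_per_genotype = 5, cells_per_animal = 3,
                      repeated = list(name = "ap_number", levels = 1,
                                      structure = "compound_symmetry",
                                      rho = 0))
  tab <- generate_cohort(spec, seed = 2)
  ms <- lmm_spec("sag_ratio", fixed = c("genotype", "sex"),
                 repeated = "ap_number", subject = "cell_id")
  sel <- select_covariance(tab, ms,
                           candidates = c("compound_symmetry", "diagonal"))
  # with one level the structures are equivalent; a converged candidate is
  # still returned deterministically, preferring fewer covariance parameters
  expect_true(sel$chosen %in% c("compound_symmetry", "diagonal"))
  expect_equal(nrow(sel$criteria), 2L)
  conv <- intersect(c("compound_symmetry", "diagonal"), names(sel$fits))
  lls <- vapply(conv, function(nm) sel$fits[[nm]]$logLik, numeric(1))
  if (length(lls) == 2L) expect_equal(unname(diff(lls)), 0, tolerance = 1e-6)
})

test_that("fewer than two animals per genotype is insufficient", {
  spec <- cohort_spec(n_animals_per_genotype = 1, cells_per_animal = 4)
  tab <- generate_cohort(spec, seed = 1)
  expect_error(fit_lmm(tab, lmm_spec("sag_ratio", fixed = "genotype")),
               class = "ecs_insufficient_data")
})
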