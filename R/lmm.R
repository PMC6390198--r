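#' Model specification for nested cohort analyses
#'
#' Describes the linear mixed model used for cells-within-animals (or
#' ROIs-within-slices) designs: fixed factors with optional two-way
#' interactions, one random-intercept grouping, and an optional repeated
#' factor whose within-subject covariance structure is selectable.
#'
#' @param response name of the response column.
#' @param fixed character vector of fixed-factor column names
#'   (e.g. genotype, age, sex, setup, area, distance).
#' @param interactions list of character pairs, each an interaction among
#'   declared fixed factors.
#' @param random name of the random-intercept grouping column (animal id).
#' @param repeated optional name of the within-unit factor (AP number,
#'   injected current, blade, distance bin).
#' @param subject name of the unit carrying repeated measures (cell or
#'   slice id); required with `repeated`.
#' @param covariance covariance structure for the repeated measures:
#'   `"independent"`, `"diagonal"` (heterogeneous variances),
#'   `"compound_symmetry"`, or `"unstructured"`.
#' @return List of class `ecs_lmm_spec`.
#' @export
lmm_spec <- function(response, fixed = c("genotype", "age", "sex"),
                     interactions = list(), random = "animal_id",
                     repeated = NULL, subject = NULL,
                     covariance = c("independent", "diagonal",
                                    "compound_symmetry", "unstructured")) {
  covariance <- match.arg(covariance)
  for (ia in interactions)
    if (!all(ia %in% fixed))
      stop_ecs("malformed_input", "interaction terms must be declared fixed factors")
  if (!is.null(repeated) && is.null(subject))
    stop_ecs("malformed_input", "repeated measures require a subject column")
  structure(list(response = response, fixed = fixed,
                 interactions = interactions, random = random,
                 repeated = repeated, subject = subject,
                 covariance = covariance),
            class = "ecs_lmm_spec")
}

.lmm_formula <- function(spec) {
  rhs <- spec$fixed
  for (ia in spec$interactions) rhs <- c(rhs, paste(ia, collapse = ":"))
  as.formula(paste(spec$response, "~", paste(rhs, collapse = " + ")))
}

.cov_params <- function(structure, k) {
  if (k <= 1) return(1)   # all structures collapse to one variance
  switch(structure,
         independent = 1,
         compound_symmetry = 2,
         diagonal = k,
         unstructured = k * (k + 1) / 2)
}

# fixed simplicity order used as the final tie-break
.cov_order <- function(structure) {
  match(structure, c("independent", "compound_symmetry", "diagonal",
                     "unstructured"))
}

.lme_args <- function(spec, data) {
  corr <- NULL; wts <- NULL
  if (!is.null(spec$repeated) && spec$covariance != "independent") {
    grp <- paste(spec$random, spec$subject, sep = "/")
    if (spec$covariance == "compound_symmetry") {
      corr <- nlme::corCompSymm(form = as.formula(paste("~ 1 |", grp)))
    } else if (spec$covariance == "diagonal") {
      wts <- nlme::varIdent(form = as.formula(paste("~ 1 |", spec$repeated)))
    } else if (spec$covariance == "unstructured") {
      corr <- nlme::corSymm(form = as.formula(paste("~ .rep_ord |", grp)))
      wts <- nlme::varIdent(form = as.formula(paste("~ 1 |", spec$repeated)))
    }
  }
  list(correlation = corr, weights = wts)
}

.fit_lme_once <- function(data, spec, method = "REML") {
  fx <- .lmm_formula(spec)
  ex <- .lme_args(spec, data)
  fit <- nlme::lme(fixed = fx, data = data,
                   random = as.formula(paste("~ 1 |", spec$random)),
                   correlation = ex$correlation, weights = ex$weights,
                   method = method, na.action = stats::na.omit,
                   control = nlme::lmeControl(maxIter = 100, msMaxIter = 100,
                                              opt = "optim",
                                              returnObject = FALSE))
  # make the stored call self-contained (no references to local variables),
  # so downstream tools can re-evaluate it
  fit$call$fixed <- fx
  fit$call$correlation <- ex$correlation
  fit$call$weights <- ex$weights
  fit
}

#' Fit the nested linear mixed model
#'
#' Restricted-maximum-likelihood fit of the model in `spec` with a random
#' intercept per animal, marginal (Type III-style) F tests of the fixed
#' effects, and estimated marginal means per level of `emm_factor` at
#' balanced weights over the other fixed factors. Numerical optimization
#' is delegated to `nlme::lme`; model assembly, covariance-structure
#' candidates and marginal-mean contrasts are computed here. On
#' non-convergence the covariance structure is downgraded along
#' unstructured -> compound symmetry -> diagonal -> independent, with the
#' downgrade recorded.
#'
#' @param data long-format cohort table (one row per observation).
#' @param spec an [lmm_spec()].
#' @param emm_factor fixed factor for which marginal means are reported.
#' @param fallback downgrade covariance on non-convergence?
#' @param level confidence level for marginal-mean intervals.
#' @return List of class `ecs_lmm_fit` with elements `coefficients`
#'   (fixed-effect table), `tests` (marginal F tests), `emm`
#'   (marginal-mean table with SE and intervals), `varcomp`, `AIC`, `BIC`,
#'   `logLik`, `covariance_used`, `fallback_applied`, `model`.
#' @export
fit_lmm <- function(data, spec, emm_factor = "genotype",
                    fallback = TRUE, level = 0.95) {
  data <- as.data.frame(data)
  if (!spec$response %in% names(data))
    stop_ecs("malformed_input", "response column '%s' missing", spec$response)
  for (v in unique(c(spec$fixed, spec$random, spec$subject, spec$repeated)))
    if (!is.null(v)) {
      if (!v %in% names(data))
        stop_ecs("malformed_input", "column '%s' missing", v)
      if (v %in% c(spec$fixed, spec$random, spec$subject, spec$repeated))
        data[[v]] <- factor(data[[v]])
    }
  if ("genotype" %in% spec$fixed) {
    tab <- table(unique(data[c(spec$random, "genotype")])$genotype)
    if (any(tab < 2))
      stop_ecs("insufficient_data", "need >= 2 animals per genotype")
  }
  if (!is.null(spec$repeated))
    data$.rep_ord <- as.integer(data[[spec$repeated]])

  ladder <- c("unstructured", "compound_symmetry", "diagonal", "independent")
  chain <- ladder[match(spec$covariance, ladder):length(ladder)]
  if (!fallback) chain <- chain[1]
  fit <- NULL; used <- NULL
  for (cv in chain) {
    sp <- spec; sp$covariance <- cv
    fit <- tryCatch(.fit_lme_once(data, sp), error = function(e) NULL)
    if (!is.null(fit)) { used <- cv; break }
  }
  if (is.null(fit))
    stop_ecs("fit_failure", "mixed model did not converge for structure(s): %s",
             paste(chain, collapse = ", "))

  tt <- summary(fit)$tTable
  coefs <- data.frame(term = rownames(tt), estimate = tt[, "Value"],
                      se = tt[, "Std.Error"], df = tt[, "DF"],
                      t = tt[, "t-value"], p = tt[, "p-value"],
                      row.names = NULL)
  tests <- tryCatch({
    an <- anova(fit, type = "marginal")
    data.frame(term = rownames(an), num_df = an$numDF, den_df = an$denDF,
               F = an$`F-value`, p = an$`p-value`, row.names = NULL)
  }, error = function(e) NULL)

  emm <- .emm_balanced(fit, data, spec, emm_factor, level = level)

  vc <- tryCatch(nlme::VarCorr(fit), error = function(e) NULL)
  structure(list(coefficients = coefs, tests = tests, emm = emm,
                 varcomp = vc, AIC = AIC(fit), BIC = BIC(fit),
                 logLik = as.numeric(stats::logLik(fit)),
                 covariance_used = used,
                 fallback_applied = !identical(used, spec$covariance),
                 model = fit),
            class = "ecs_lmm_fit")
}

# estimated marginal means at equal weights over the other fixed factors
.emm_balanced <- function(fit, data, spec, emm_factor, level = 0.95) {
  if (!emm_factor %in% spec$fixed) return(NULL)
  lv <- lapply(spec$fixed, function(v) levels(data[[v]]))
  names(lv) <- spec$fixed
  grid <- expand.grid(lv, stringsAsFactors = TRUE)
  tm <- stats::delete.response(terms(.lmm_formula(spec)))
  X <- model.matrix(tm, grid)
  beta <- nlme::fixef(fit)
  X <- X[, names(beta), drop = FALSE]
  V <- vcov(fit)
  tgt <- grid[[emm_factor]]
  # denominator df for the contrast: df of the emm factor's marginal test,
  # falling back to the smallest coefficient df
  an <- tryCatch(anova(fit, type = "marginal"), error = function(e) NULL)
  df <- if (!is.null(an) && emm_factor %in% rownames(an))
    an[emm_factor, "denDF"] else min(summary(fit)$tTable[, "DF"])
  alpha <- 1 - level
  rows <- lapply(levels(tgt), function(g) {
    L <- colMeans(X[tgt == g, , drop = FALSE])
    est <- sum(L * beta)
    se <- sqrt(drop(t(L) %*% V %*% L))
    data.frame(level = g, emmean = est, se = se, df = df,
               lower = est - qt(1 - alpha / 2, df) * se,
               upper = est + qt(1 - alpha / 2, df) * se)
  })
  emm <- do.call(rbind, rows)
  # pairwise contrast of the first two levels (the genotype effect)
  if (nlevels(tgt) >= 2) {
    g1 <- levels(tgt)[1]; g2 <- levels(tgt)[2]
    L1 <- colMeans(X[tgt == g1, , drop = FALSE])
    L2 <- colMeans(X[tgt == g2, , drop = FALSE])
    Ld <- L2 - L1
    est <- sum(Ld * beta); se <- sqrt(drop(t(Ld) %*% V %*% Ld))
    attr(emm, "contrast") <- data.frame(
      contrast = paste(g2, "-", g1), estimate = est, se = se, df = df,
      lower = est - qt(1 - alpha / 2, df) * se,
      upper = est + qt(1 - alpha / 2, df) * se)
  }
  attr(emm, "factor") <- emm_factor
  emm
}

#' @export
print.ecs_lmm_fit <- function(x, ...) {
  cat(sprintf("<ecs_lmm_fit> AIC %.1f, covariance: %s%s\n", x$AIC,
              x$covariance_used,
              if (x$fallback_applied) " (fallback)" else ""))
  if (!is.null(x$tests)) {
    cat("Marginal F tests:\n")
    print(x$tests, digits = 4)
  }
  if (!is.null(x$emm)) {
    cat(sprintf("Estimated marginal means (%s):\n", attr(x$emm, "factor")))
    print(x$emm, digits = 4)
  }
  invisible(x)
}

#' Select a repeated-measures covariance structure by information criteria
#'
#' Fits every candidate structure and returns the converged candidate with
#' the smallest information criterion; ties are broken toward the simpler
#' structure (fewer covariance parameters).
#'
#' @param data cohort table.
#' @param spec an [lmm_spec()] with a repeated factor.
#' @param candidates character vector of structures to compare.
#' @param criterion `"AIC"` or `"BIC"`.
#' @return List with `chosen`, `criteria` (data.frame structure/AIC/BIC/
#'   converged), and `fits` (the converged `ecs_lmm_fit`s).
#' @export
select_covariance <- function(data, spec,
                              candidates = c("compound_symmetry", "unstructured"),
                              criterion = c("AIC", "BIC")) {
  criterion <- match.arg(criterion)
  if (length(candidates) < 2)
    stop_ecs("malformed_input", "need >= 2 candidate structures")
  k <- if (!is.null(spec$repeated)) nlevels(factor(data[[spec$repeated]])) else 1
  fits <- list(); crit <- data.frame()
  for (cv in candidates) {
    sp <- spec; sp$covariance <- cv
    f <- tryCatch(fit_lmm(data, sp, fallback = FALSE), error = function(e) NULL)
    fits[[cv]] <- f
    crit <- rbind(crit, data.frame(
      structure = cv,
      n_cov_params = .cov_params(cv, k),
      AIC = if (is.null(f)) NA_real_ else f$AIC,
      BIC = if (is.null(f)) NA_real_ else f$BIC,
      converged = !is.null(f)))
  }
  ok <- crit[crit$converged, ]
  if (nrow(ok) == 0)
    stop_ecs("fit_failure", "no candidate covariance structure converged; tried: %s",
             paste(candidates, collapse = ", "))
  ok <- ok[order(ok[[criterion]], ok$n_cov_params, .cov_order(ok$structure)), ]
  list(chosen = ok$structure[1], criteria = crit, fits = fits)
}
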