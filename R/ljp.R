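#' Limiting equivalent conductivities of common ions
#'
#' Limiting (infinite-dilution) equivalent conductivities at 25 degrees C in
#' S cm^2 per equivalent, with ionic charges, for the species that occur in
#' standard patch-clamp solutions. Inorganic values are the usual
#' electrochemical reference values; organic anions (gluconate, HEPES,
#' phosphocreatine, ATP, GTP) use published mobility estimates of the kind
#' shipped with standard junction-potential calculators.
#'
#' @return data.frame with columns `species`, `charge`, `lambda`.
#' @export
ion_mobility_table <- function() {
  data.frame(
    species = c("K", "Na", "Li", "Cs", "choline", "Ca", "Mg",
                "Cl", "Br", "F", "HCO3", "H2PO4", "SO4", "NO3",
                "acetate", "gluconate", "HEPES", "MES",
                "phosphocreatine", "ATP", "GTP", "EGTA",
                "glucose", "mannitol", "sucrose"),
    charge = c(1, 1, 1, 1, 1, 2, 2,
               -1, -1, -1, -1, -1, -2, -1,
               -1, -1, -1, -1,
               -2, -2, -2, -2,
               0, 0, 0),
    lambda = c(73.50, 50.11, 38.68, 77.2, 38.7, 59.50, 53.06,
               76.35, 78.1, 55.4, 44.50, 36.00, 80.0, 71.46,
               40.9, 24.40, 22.05, 26.8,
               25.0, 24.0, 24.0, 24.0,
               0, 0, 0),
    stringsAsFactors = FALSE)
}

#' Ionic composition of a solution
#'
#' Builds a solution record from named species concentrations (mM). Species
#' must appear in the mobility table (or be supplied through `extra`);
#' neutral species are carried but ignored by the junction computation.
#'
#' @param ... named concentrations in mM, e.g. `K = 130, Cl = 10`.
#' @param temperature solution temperature, degrees C.
#' @param extra optional data.frame with columns `species`, `charge`,
#'   `lambda` appended to the mobility table.
#' @return Object of class `ecs_solution`: data.frame with `species`,
#'   `conc_mM`, `charge`, `lambda`, plus a `temperature` attribute.
#' @export
solution <- function(..., temperature = 25, extra = NULL) {
  conc <- c(...)
  if (is.null(names(conc)) || any(names(conc) == ""))
    stop_ecs("malformed_input", "all concentrations must be named")
  if (any(conc < 0)) stop_ecs("malformed_input", "concentrations must be >= 0")
  tab <- ion_mobility_table()
  if (!is.null(extra)) tab <- rbind(tab, extra)
  unknown <- setdiff(names(conc), tab$species)
  if (length(unknown) > 0)
    stop_ecs("malformed_input", "unknown species: %s", paste(unknown, collapse = ", "))
  m <- tab[match(names(conc), tab$species), ]
  structure(data.frame(species = m$species, conc_mM = as.numeric(conc),
                       charge = m$charge, lambda = m$lambda,
                       stringsAsFactors = FALSE),
            temperature = temperature, class = c("ecs_solution", "data.frame"))
}

#' Liquid junction potential by the generalized Henderson equation
#'
#' Computes the stationary junction potential of the bath relative to the
#' pipette solution:
#' \deqn{E = \frac{RT}{F}\;
#'   \frac{\sum_i \mathrm{sgn}(z_i)\lambda_i (c_i^{bath}-c_i^{pip})}
#'        {\sum_i |z_i|\lambda_i (c_i^{bath}-c_i^{pip})}\;
#'   \ln\frac{\sum_i |z_i|\lambda_i c_i^{pip}}
#'           {\sum_i |z_i|\lambda_i c_i^{bath}}}
#' with \eqn{\lambda_i} the limiting equivalent conductivity and \eqn{z_i}
#' the charge. The sign convention (bath minus pipette) makes the usual
#' K-gluconate-internal versus ACSF junction positive. Neutral species are
#' ignored. The potential is antisymmetric under swapping the solutions.
#'
#' @param pipette,bath [solution()] objects.
#' @param temperature degrees C; defaults to the solutions' temperature
#'   attribute when they agree, else 25.
#' @return List with `ljp_mV` (signed, bath minus pipette), `magnitude_mV`
#'   and `temperature`.
#' @export
liquid_junction_potential <- function(pipette, bath, temperature = NULL) {
  if (is.null(temperature)) {
    tp <- attr(pipette, "temperature"); tb <- attr(bath, "temperature")
    temperature <- if (!is.null(tp) && !is.null(tb) && isTRUE(all.equal(tp, tb))) tp else 25
  }
  all_sp <- union(pipette$species, bath$species)
  cp <- setNames(rep(0, length(all_sp)), all_sp)
  cb <- cp
  cp[pipette$species] <- pipette$conc_mM
  cb[bath$species] <- bath$conc_mM
  tab <- rbind(pipette[c("species", "charge", "lambda")],
               bath[c("species", "charge", "lambda")])
  tab <- tab[!duplicated(tab$species), ]
  z <- setNames(tab$charge, tab$species)[all_sp]
  lam <- setNames(tab$lambda, tab$species)[all_sp]
  chg <- z != 0 & lam > 0
  if (!any(chg & (cp > 0 | cb > 0)))
    stop_ecs("undefined_junction", "no charged species present")
  z <- z[chg]; lam <- lam[chg]; cp <- cp[chg]; cb <- cb[chg]
  RT_F <- 8.31446 * (273.15 + temperature) / 96485.33 * 1000  # mV
  dc <- cb - cp
  s_p <- sum(abs(z) * lam * cp)
  s_b <- sum(abs(z) * lam * cb)
  den <- sum(abs(z) * lam * dc)
  e <- if (abs(den) < 1e-12) {
    0
  } else {
    RT_F * sum(sign(z) * lam * dc) / den * log(s_p / s_b)
  }
  list(ljp_mV = e, magnitude_mV = abs(e), temperature = temperature)
}

#' Example patch-clamp solutions
#'
#' `internal_kgluconate()` is a standard K-gluconate pipette internal
#' (120 mM K-gluconate, 10 mM KCl, 10 mM HEPES, 4 mM MgATP, 10 mM
#' Na2-phosphocreatine, 0.3 mM GTP) decomposed into ionic species;
#' `recording_acsf()` is the matching recording ACSF (126 mM NaCl, 3 mM
#' KCl, 1.5 mM MgCl2, 1.6 mM CaCl2, 10 mM glucose, 1.2 mM NaH2PO4, 26 mM
#' NaHCO3). HEPES (pKa 7.5) is taken 35% ionized at intracellular pH;
#' MgATP contributes Mg(2+) and ATP(2-). Both carry temperature 34, the
#' bath temperature at which such recordings are made.
#'
#' @return A [solution()] object.
#' @export
internal_kgluconate <- function() {
  solution(K = 130,          # 120 K-gluconate + 10 KCl
           gluconate = 120,
           Cl = 10,
           HEPES = 10 * 0.35,
           Mg = 4, ATP = 4,  # 4 MgATP
           Na = 20, phosphocreatine = 10,  # 10 Na2-phosphocreatine
           GTP = 0.3,
           temperature = 34)
}

#' @rdname internal_kgluconate
#' @export
recording_acsf <- function() {
  solution(Na = 126 + 1.2 + 26,   # NaCl + NaH2PO4 + NaHCO3
           Cl = 126 + 3 + 3 + 3.2,  # NaCl + KCl + 2xMgCl2 + 2xCaCl2
           K = 3,
           Mg = 1.5, Ca = 1.6,
           H2PO4 = 1.2, HCO3 = 26,
           glucose = 10,
           temperature = 34)
}
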