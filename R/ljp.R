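## Henderson liquid-junction-potential calculator.
##
## Mobilities are limiting equivalent ionic conductivities (S cm^2 per
## equivalent, 25 C) bundled in inst/extdata/ion_mobility.csv; only ratios
## enter the Henderson expression so the absolute unit cancels. Gluconate --
## the slow anion that dominates the junction potential of K-gluconate
## internals -- uses the value standard in the electrophysiology
## junction-potential literature.

FARADAY <- 96485.33212   # C/mol
GAS_R <- 8.314462618     # J/(mol K)

#' Bundled limiting ionic mobility table
#'
#' @return Data frame with columns `ion`, `z` (signed valence) and `lambda`
#'   (limiting equivalent conductivity, relative units).
#' @export
ion_mobility_table <- function() {
  path <- system.file("extdata", "ion_mobility.csv", package = "spinephys",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

## salt -> ion stoichiometry (per mM of salt). Neutral osmolytes dissolve to
## nothing ionic. MgATP is carried as Mg2+ + MgATP2- (the dominant complexed
## species at pH 7.3); HEPES contributes its anion fraction at pH 7.3
## (pKa 7.55).
HEPES_ANION_FRACTION <- 1 / (1 + 10^(7.55 - 7.3))

salt_dictionary <- function() {
  list(
    "K-gluconate" = c(K = 1, gluconate = -1),
    "KCl"         = c(K = 1, Cl = -1),
    "NaCl"        = c(Na = 1, Cl = -1),
    "CsCl"        = c(Cs = 1, Cl = -1),
    "NaHCO3"      = c(Na = 1, HCO3 = -1),
    "NaH2PO4"     = c(Na = 1, H2PO4 = -1),
    "MgCl2"       = c(Mg = 1, Cl = -2),
    "CaCl2"       = c(Ca = 1, Cl = -2),
    "MgSO4"       = c(Mg = 1, SO4 = -1),
    "HEPES"       = c(HEPES = -HEPES_ANION_FRACTION),
    "EGTA"        = c(EGTA = -1),
    "Mg2ATP"      = c(Mg = 1, ATP = -1),
    "MgATP"       = c(Mg = 1, ATP = -1),
    "Na3GTP"      = c(Na = 3, GTP = -1),
    "Na2GTP"      = c(Na = 2, GTP = -1),
    "KOH"         = c(K = 1, OH = -1),
    "NaOH"        = c(Na = 1, OH = -1),
    "glucose"     = c(),
    "sucrose"     = c()
  )
}

#' Dissociate a salt recipe into an ionic solution
#'
#' Strong electrolytes dissociate fully; HEPES contributes its pH-7.3 anion
#' fraction; glucose and sucrose are neutral. If `balance_with` names a
#' cation, enough of it is added to cancel any net negative charge --
#' emulating titration to pH (e.g. KOH for a potassium-gluconate internal).
#' Electroneutrality is then checked with 5% slack for unmodelled titrants.
#'
#' @param recipe Named numeric vector of salt concentrations in mM, names
#'   drawn from the bundled dictionary (see errors for the list).
#' @param temperature_K Absolute temperature, stored on the solution.
#' @param balance_with Optional cation name (e.g. `"K"`) used to restore
#'   electroneutrality, or `NULL`.
#' @param mobility Mobility table; defaults to [ion_mobility_table()].
#' @return An object of class `"ion_solution"`: data frame of `ion`, `z`,
#'   `lambda`, `conc_mM` plus a `temperature_K` attribute.
#' @export
dissociate_recipe <- function(recipe, temperature_K = 295.15,
                              balance_with = NULL,
                              mobility = ion_mobility_table()) {
  dict <- salt_dictionary()
  unknown <- setdiff(names(recipe), names(dict))
  if (length(unknown)) {
    stop("unknown salt(s): ", paste(unknown, collapse = ", "),
         "; known salts: ", paste(names(dict), collapse = ", "),
         call. = FALSE)
  }
  if (any(recipe < 0)) stop("concentrations must be >= 0", call. = FALSE)
  conc <- numeric(0)
  for (salt in names(recipe)) {
    st <- dict[[salt]]
    for (ion in names(st)) {
      conc[ion] <- (if (ion %in% names(conc)) conc[ion] else 0) +
        recipe[[salt]] * abs(st[[ion]])
    }
  }
  ions <- names(conc)
  z <- mobility$z[match(ions, mobility$ion)]
  lam <- mobility$lambda[match(ions, mobility$ion)]
  if (anyNA(z)) {
    stop("no mobility entry for ion(s): ",
         paste(ions[is.na(z)], collapse = ", "), call. = FALSE)
  }
  net <- sum(z * conc)
  if (!is.null(balance_with) && net < 0) {
    zi <- mobility$z[match(balance_with, mobility$ion)]
    add <- -net / zi
    if (balance_with %in% ions) {
      conc[balance_with] <- conc[balance_with] + add
    } else {
      conc[balance_with] <- add
      ions <- names(conc)
      z <- mobility$z[match(ions, mobility$ion)]
      lam <- mobility$lambda[match(ions, mobility$ion)]
    }
    net <- sum(z * conc)
  }
  if (abs(net) > 0.05 * sum(abs(z) * conc)) {
    stop(sprintf(
      "solution violates electroneutrality beyond 5%% slack (net %.2f mEq/L)",
      net), call. = FALSE)
  }
  sol <- data.frame(ion = ions, z = z, lambda = lam, conc_mM = unname(conc),
                    stringsAsFactors = FALSE)
  attr(sol, "temperature_K") <- temperature_K
  class(sol) <- c("ion_solution", class(sol))
  sol
}

#' Henderson liquid junction potential
#'
#' Classical Henderson equation in its generalised-valence form, with ion
#' mobilities represented by limiting equivalent conductivities:
#' \deqn{V = \frac{RT}{F}\,
#'   \frac{\sum_i \mathrm{sgn}(z_i)\,u_i\,(c_i^b - c_i^p)}
#'        {\sum_i |z_i|\,u_i\,(c_i^b - c_i^p)}\,
#'   \ln\frac{\sum_i |z_i|\,u_i\,c_i^p}{\sum_i |z_i|\,u_i\,c_i^b}}
#' Returned in the bath-minus-pipette convention, which is positive for the
#' usual potassium-gluconate internal against ACSF -- the sign-free value
#' electrophysiologists quote as "the LJP".
#'
#' @param pipette,bath [dissociate_recipe()] solutions.
#' @param temperature_K Temperature; defaults to the pipette solution's.
#' @return Potential in mV, with a per-ion contribution breakdown in the
#'   `"contributions"` attribute.
#' @export
henderson_ljp <- function(pipette, bath,
                          temperature_K = attr(pipette, "temperature_K")) {
  stopifnot(inherits(pipette, "ion_solution"), inherits(bath, "ion_solution"))
  ions <- union(pipette$ion, bath$ion)
  cp <- pipette$conc_mM[match(ions, pipette$ion)]; cp[is.na(cp)] <- 0
  cb <- bath$conc_mM[match(ions, bath$ion)]; cb[is.na(cb)] <- 0
  src <- rbind(pipette[c("ion", "z", "lambda")], bath[c("ion", "z", "lambda")])
  z <- src$z[match(ions, src$ion)]
  u <- src$lambda[match(ions, src$ion)]
  sp <- sum(abs(z) * u * cp)
  sb <- sum(abs(z) * u * cb)
  if (sp <= 0 || sb <= 0) {
    stop("both solutions must have non-zero ionic strength", call. = FALSE)
  }
  d <- cb - cp
  num <- sum(sign(z) * u * d)
  den <- sum(abs(z) * u * d)
  rt_f <- 1000 * GAS_R * temperature_K / FARADAY  # mV
  v <- if (abs(den) < 1e-12 && abs(num) < 1e-12) {
    0
  } else {
    rt_f * (num / den) * log(sp / sb)
  }
  contrib <- data.frame(ion = ions, z = z, lambda = u,
                        pipette_mM = cp, bath_mM = cb,
                        numerator = sign(z) * u * d,
                        denominator = abs(z) * u * d,
                        stringsAsFactors = FALSE)
  attr(v, "contributions") <- contrib
  v
}

#' Junction potential of the study's potassium-gluconate internal vs ACSF
#'
#' Convenience wrapper dissociating the standard recording solutions: a
#' 135 mM potassium-gluconate internal (8 NaCl, 10 HEPES, 0.1 EGTA,
#' 2 Mg2ATP, 0.3 Na3GTP, titrated with KOH) against a bicarbonate-buffered
#' ACSF (118 NaCl, 25 NaHCO3, 10 glucose, 2.5 KCl, 1 NaH2PO4, 1 MgCl2,
#' 2.5 CaCl2).
#'
#' @param temperature_C Temperature in Celsius (default 22, room temperature).
#' @return Junction potential in mV (bath minus pipette).
#' @export
kgluconate_acsf_ljp <- function(temperature_C = 22) {
  tk <- temperature_C + 273.15
  internal <- dissociate_recipe(
    c("K-gluconate" = 135, "NaCl" = 8, "HEPES" = 10, "EGTA" = 0.1,
      "Mg2ATP" = 2, "Na3GTP" = 0.3),
    temperature_K = tk, balance_with = "K")
  acsf <- dissociate_recipe(
    c("NaCl" = 118, "NaHCO3" = 25, "glucose" = 10, "KCl" = 2.5,
      "NaH2PO4" = 1, "MgCl2" = 1, "CaCl2" = 2.5),
    temperature_K = tk)
  henderson_ljp(internal, acsf, temperature_K = tk)
}
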