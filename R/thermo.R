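# Reaction bioenergetics at fermentation conditions.
#
# Pipeline: formation-table sum at 298.15 K -> Gibbs-Helmholtz
# compensation to the working temperature -> biological-standard-state
# correction, which replaces the 1 M proton standard state by the
# stated pH. The pH correction is evaluated at its own (configurable)
# temperature: the conventional biological-standard tables use
# 298.15 K, where one proton per pH unit is worth
# R*T*ln(10) = 5.708 kJ mol^-1.

.R_KJ <- 8.314462618e-3 # kJ mol^-1 K^-1

#' Gibbs-Helmholtz temperature compensation
#'
#' Transforms a standard reaction Gibbs energy from a reference
#' temperature to another, assuming a temperature-independent reaction
#' enthalpy:
#' `dG(T) = dG(T_ref) * T/T_ref + dH * (1 - T/T_ref)`.
#'
#' @param dg0_ref Reaction Gibbs energy at `t_ref` (kJ mol^-1).
#' @param dh0_ref Reaction enthalpy at `t_ref` (kJ mol^-1).
#' @param t_ref Reference temperature (K), default 298.15.
#' @param t Target temperature (K).
#' @return kJ mol^-1 at temperature `t`.
#' @export
gibbs_helmholtz <- function(dg0_ref, dh0_ref, t_ref = 298.15, t) {
  if (any(c(t_ref, t) <= 0)) stop("temperatures must be positive (K)")
  dg0_ref * (t / t_ref) + dh0_ref * (1 - t / t_ref)
}

#' Biological-standard-state pH correction
#'
#' Moves the proton standard state from 1 M to the stated pH:
#' `dG' = dG + n_H+ * R * T_corr * ln(10) * (-pH)`.
#' Producing protons (`n_H+ > 0`) at pH > 0 lowers the reaction Gibbs
#' energy.
#'
#' @param dg0 Uncorrected reaction Gibbs energy (kJ mol^-1).
#' @param n_protons Signed net proton production of the reaction.
#' @param ph Target pH.
#' @param t_corr Temperature at which the correction term is evaluated
#'   (K); default 298.15, the convention under which one proton per pH
#'   unit is 5.708 kJ mol^-1.
#' @return kJ mol^-1.
#' @export
ph_correction <- function(dg0, n_protons, ph, t_corr = 298.15) {
  dg0 + n_protons * .R_KJ * t_corr * log(10) * (-ph)
}

#' Thermodynamic evaluation conditions
#'
#' @param temperature Working temperature (K), default 308.15 (35 C).
#' @param ph pH of the biological standard state, default 7.
#' @param proton_correction_temperature Temperature used inside the pH
#'   correction term (K), default 298.15 (see [ph_correction()]).
#' @return Object of class `thermo_conditions`.
#' @export
thermo_conditions <- function(temperature = 308.15, ph = 7,
                              proton_correction_temperature = 298.15) {
  stopifnot(temperature > 0, ph >= 0, ph <= 14,
            proton_correction_temperature > 0)
  structure(
    list(
      temperature = temperature, ph = ph,
      proton_correction_temperature = proton_correction_temperature
    ),
    class = "thermo_conditions"
  )
}

#' Biologically corrected reaction Gibbs energy
#'
#' Composes [delta_g0()], [delta_h0()], [gibbs_helmholtz()] and
#' [ph_correction()] for a balanced reaction. When the reaction produces
#' no net protons the pH-corrected value equals the
#' temperature-compensated one.
#'
#' @param rx A balanced `ferm_reaction`.
#' @param conditions A [thermo_conditions()] object.
#' @param table Compound table.
#' @return Object of class `thermo_result` with fields `dG0_298`,
#'   `dH0_298`, `dG0_T`, `dG0prime_T` (all kJ mol^-1) and `net_protons`.
#' @examples
#' rx <- parse_reaction("CH3CH2OH + H2O -> CH3COO- + H+ + 2 H2")
#' delta_g_biological(rx, thermo_conditions(308.15, ph = 7))
#' @export
delta_g_biological <- function(rx, conditions = thermo_conditions(),
                               table = compound_table()) {
  stopifnot(inherits(conditions, "thermo_conditions"))
  dg298 <- delta_g0(rx, table)
  dh298 <- delta_h0(rx, table)
  dg_t <- gibbs_helmholtz(dg298, dh298, 298.15, conditions$temperature)
  np <- net_protons(rx)
  dgp_t <- ph_correction(dg_t, np, conditions$ph,
                         conditions$proton_correction_temperature)
  structure(
    list(
      reaction = rx,
      dG0_298 = dg298, dH0_298 = dh298,
      dG0_T = dg_t, dG0prime_T = dgp_t,
      net_protons = np,
      temperature = conditions$temperature, ph = conditions$ph,
      proton_correction_temperature = conditions$proton_correction_temperature
    ),
    class = "thermo_result"
  )
}

#' @export
print.thermo_result <- function(x, ...) {
  cat("Reaction: ", x$reaction$label, "\n", sep = "")
  cat(sprintf("  dG0 (298.15 K):        %8.1f kJ/mol\n", x$dG0_298))
  cat(sprintf("  dH0 (298.15 K):        %8.1f kJ/mol\n", x$dH0_298))
  cat(sprintf("  dG0 (%.2f K):        %8.1f kJ/mol\n", x$temperature, x$dG0_T))
  cat(sprintf("  dG0' (%.2f K, pH %g): %8.1f kJ/mol  (net H+ = %g)\n",
              x$temperature, x$ph, x$dG0prime_T, x$net_protons))
  invisible(x)
}

#' Canonical sugar fermentation pathway reactions
#'
#' The four catabolic routes the package models, written with
#' dissociated acids (anion + proton):
#' * `ethanol`: glucose -> 2 ethanol + 2 CO2
#' * `acetate_h2`: ethanol + H2O -> acetate- + H+ + 2 H2
#' * `butyrate`: glucose -> butyrate- + H+ + 2 CO2 + 2 H2
#' * `homoacetate`: glucose -> 3 acetate- + 3 H+
#'
#' @return Named list of `ferm_reaction` objects.
#' @export
pathway_reactions <- function() {
  list(
    ethanol = parse_reaction(
      "C6H12O6 -> 2 CH3CH2OH + 2 CO2",
      label = "glucose -> 2 ethanol + 2 CO2"
    ),
    acetate_h2 = parse_reaction(
      "CH3CH2OH + H2O -> CH3COO- + H+ + 2 H2",
      label = "ethanol + H2O -> acetate- + H+ + 2 H2"
    ),
    butyrate = parse_reaction(
      "C6H12O6 -> CH3(CH2)2COO- + H+ + 2 CO2 + 2 H2",
      label = "glucose -> butyrate- + H+ + 2 CO2 + 2 H2"
    ),
    homoacetate = parse_reaction(
      "C6H12O6 -> 3 CH3COO- + 3 H+",
      label = "glucose -> 3 acetate- + 3 H+"
    )
  )
}

#' Energy table for the built-in pathway set
#'
#' Evaluates all pathway reactions at the given temperature for one or
#' more pH values.
#'
#' @param ph Vector of pH values (default `c(7, 6)`).
#' @param temperature Working temperature (K), default 308.15.
#' @param t_corr pH-correction temperature (K), default 298.15.
#' @return data.frame with one row per pathway x pH.
#' @export
pathway_energy_table <- function(ph = c(7, 6), temperature = 308.15,
                                 t_corr = 298.15) {
  rxs <- pathway_reactions()
  rows <- list()
  for (nm in names(rxs)) {
    for (p in ph) {
      res <- delta_g_biological(
        rxs[[nm]],
        thermo_conditions(temperature, p, t_corr)
      )
      rows[[length(rows) + 1L]] <- data.frame(
        pathway = nm, label = rxs[[nm]]$label, pH = p,
        dG0_298 = res$dG0_298, dG0_T = res$dG0_T,
        dG0prime_T = res$dG0prime_T, net_protons = res$net_protons
      )
    }
  }
  do.call(rbind, rows)
}
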