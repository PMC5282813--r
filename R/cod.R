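# COD unit engine: theoretical oxygen demand from combustion
# stoichiometry, gas volume <-> COD conversion, biomass <-> COD.
# COD is the package's common currency; every conversion routes
# through the elemental composition so factors stay consistent.

#' Theoretical oxygen demand per gram of substance
#'
#' O2 demand for full oxidation to CO2 and H2O, with organic nitrogen
#' left as NH3 (the COD convention: no nitrification). For anions the
#' conjugate acid's formula is used (one H added per negative charge).
#'
#' For `CxHyOzNn`: `mol O2 = x + y/4 - z/2 - 3n/4`; the per-gram value
#' is `32 * mol O2 / molar mass`.
#'
#' @param formula Formula string or element-count vector (C, H, O, N
#'   only).
#' @param charge Elementary charge of the species (<= 0).
#' @return g_COD per g of substance.
#' @examples
#' thod_per_gram("CH4")     # ~4 g_COD/g
#' thod_per_gram("C6H12O6") # 192/180.16
#' @export
thod_per_gram <- function(formula, charge = 0) {
  f <- .thod_formula(formula, charge)
  32 * .thod_o2_mol(f) / sum(f * atomic_masses[names(f)])
}

#' Theoretical oxygen demand per mole
#'
#' @inheritParams thod_per_gram
#' @return g_COD per mol of substance (64 for CH4, 16 for H2, 0 for
#'   CO2).
#' @export
thod_per_mol <- function(formula, charge = 0) {
  32 * .thod_o2_mol(.thod_formula(formula, charge))
}

.thod_formula <- function(formula, charge) {
  f <- parse_formula(formula)
  unsupported <- setdiff(names(f), c("C", "H", "O", "N"))
  if (length(unsupported) > 0) {
    stop("ThOD unsupported for element(s): ",
         paste(unsupported, collapse = ", "))
  }
  if (charge > 0) stop("ThOD is defined for neutral or anionic species")
  if (charge < 0) f["H"] <- (if ("H" %in% names(f)) f[["H"]] else 0) - charge
  f
}

.thod_o2_mol <- function(f) {
  g <- function(el) if (el %in% names(f)) f[[el]] else 0
  o2 <- g("C") + g("H") / 4 - g("O") / 2 - 3 * g("N") / 4
  max(o2, 0)
}

#' COD conversion factors
#'
#' The two fixed factors used in mass-balance accounting: CH4 at
#' 4 g_COD per g (the rounded convention; the elemental value is
#' 64/16.043) and biomass volatile suspended solids (VSS) at
#' 1.2 g_COD per g.
#'
#' @param cod_per_g_ch4 g_COD per g CH4.
#' @param cod_per_g_vss g_COD per g VSS.
#' @return Object of class `conversion_factors`.
#' @export
conversion_factors <- function(cod_per_g_ch4 = 4, cod_per_g_vss = 1.2) {
  stopifnot(cod_per_g_ch4 > 0, cod_per_g_vss > 0)
  structure(
    list(cod_per_g_ch4 = cod_per_g_ch4, cod_per_g_vss = cod_per_g_vss),
    class = "conversion_factors"
  )
}

#' Convert a gas volume (rate) to COD
#'
#' `volume / molar_volume` moles of gas times its per-mole oxygen
#' demand. CO2 carries no COD by definition. The default molar volume
#' of 22.4 L mol^-1 (0 C, 1 atm) is the convention under which 1 g_COD
#' of CH4 occupies 0.35 L.
#'
#' @param volume Gas volume in mL (per L reactor, per day for rates).
#' @param species One of `"CH4"`, `"H2"`, `"CO2"`.
#' @param molar_volume L mol^-1, default 22.4.
#' @return g_COD (per L per day when `volume` is a rate). Vectorised
#'   over `volume`.
#' @examples
#' gas_to_cod(211.3, "CH4") # 0.60 g_COD/L/d
#' @export
gas_to_cod <- function(volume, species = c("CH4", "H2", "CO2"),
                       molar_volume = 22.4) {
  species <- match.arg(species)
  if (any(volume < 0)) stop("gas volume must be non-negative")
  stopifnot(molar_volume > 0)
  volume / 1000 / molar_volume * thod_per_mol(species)
}

#' Theoretical CH4 volume from removed COD
#'
#' Inverse of [gas_to_cod()] for methane: `cod * molar_volume / 64`,
#' i.e. 0.35 L CH4 per g_COD at 22.4 L mol^-1.
#'
#' @param cod_removed g_COD removed (>= 0).
#' @param molar_volume L mol^-1, default 22.4.
#' @return L of CH4.
#' @export
cod_to_ch4_volume <- function(cod_removed, molar_volume = 22.4) {
  if (any(cod_removed < 0)) stop("cod_removed must be non-negative")
  cod_removed * molar_volume / thod_per_mol("CH4")
}

#' Convert a VSS rate to COD
#'
#' @param vss g VSS per L per day (>= 0).
#' @param factors A [conversion_factors()] object.
#' @return g_COD per L per day.
#' @export
vss_to_cod <- function(vss, factors = conversion_factors()) {
  if (any(vss < 0)) stop("vss must be non-negative")
  vss * factors$cod_per_g_vss
}

#' COD factors of the free volatile fatty acids
#'
#' Per-gram ThOD of the free (protonated) acids, computed from the
#' packaged anion formulas rather than tabulated, so there is a single
#' source of truth: acetic 1.066, propionic 1.512, butyric 1.816
#' g_COD/g, etc.
#'
#' @param species Anion names present in the compound table.
#' @return Named numeric vector, g_COD per g free acid.
#' @export
vfa_cod_factors <- function(species = c("acetate", "propionate", "butyrate")) {
  vapply(species, function(nm) {
    rec <- find_compound(nm)
    thod_per_gram(rec$formula, rec$charge)
  }, numeric(1))
}
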