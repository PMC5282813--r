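# Acid-base speciation of VFAs, NaCl <-> conductivity mapping, water
# class assignment, and the estimated VFA contribution to conductivity.

#' Anionic fraction of a weak acid (Henderson-Hasselbalch)
#'
#' `1 / (1 + 10^(pKa - pH))`. At pH 7 with the effective VFA pKa of 4.8
#' about 99% of the acids are dissociated; at pH 6 about 6% shift back
#' to the free-acid form.
#'
#' @param ph pH (vectorised).
#' @param pka Acid dissociation constant, default 4.8 (effective value
#'   for the C2-C6 volatile fatty acids).
#' @return Fraction in (0, 1).
#' @export
anionic_fraction <- function(ph, pka = 4.8) {
  stopifnot(all(pka > 0), all(pka < 14))
  1 / (1 + 10^(pka - ph))
}

#' Salinity scale: NaCl <-> conductivity anchors and water classes
#'
#' The default anchors map NaCl (g L^-1) to conductivity (mS cm^-1)
#' along the classic ecosystem ladder (fresh rivers through brine
#' lakes); class bounds place fresh below 0.47, brackish from 0.47 up
#' to 20, saline from 20 through 47, and brine strictly above
#' 47 mS cm^-1. The saline/brackish cut at 20 and the brine cut at 47
#' follow the operational definition used for fermentation media; the
#' anchor table itself leaves a gap between 2.8 and 38, so bounds are
#' configurable.
#'
#' @param anchors Two-column matrix-like of (NaCl g/L, mS/cm) pairs,
#'   strictly increasing in both coordinates.
#' @param class_bounds Named numeric thresholds `fresh`, `brackish`,
#'   `saline`: upper bounds of the first three classes.
#' @return Object of class `salinity_scale`.
#' @export
salinity_scale <- function(
    anchors = cbind(
      nacl_g_L = c(0.01, 0.5, 1, 3, 40, 50, 100, 350),
      cond_mS_cm = c(0.01, 0.47, 0.94, 2.8, 38, 47, 94, 329)
    ),
    class_bounds = c(fresh = 0.47, brackish = 20, saline = 47)) {
  anchors <- as.matrix(anchors)
  stopifnot(
    ncol(anchors) == 2,
    all(diff(anchors[, 1]) > 0), all(diff(anchors[, 2]) > 0),
    length(class_bounds) == 3, all(diff(class_bounds) > 0)
  )
  structure(
    list(anchors = anchors, class_bounds = class_bounds),
    class = "salinity_scale"
  )
}

#' @export
print.salinity_scale <- function(x, ...) {
  cat("Salinity scale:", nrow(x$anchors), "anchors;",
      "class bounds (mS/cm):",
      paste(sprintf("%s<%g", names(x$class_bounds), x$class_bounds),
            collapse = ", "),
      "brine>", x$class_bounds[[3]], "\n")
  invisible(x)
}

#' Map NaCl concentration to conductivity
#'
#' Piecewise-linear interpolation over the scale anchors. Outside the
#' anchor range the end-segment slope is continued (with a warning):
#' in particular the mapping stays near-proportional through 0, so
#' 0 g/L maps to ~0 mS/cm.
#'
#' @param nacl NaCl in g L^-1 (vectorised, >= 0).
#' @param scale A [salinity_scale()].
#' @return Conductivity in mS cm^-1.
#' @export
nacl_to_conductivity <- function(nacl, scale = salinity_scale()) {
  if (any(nacl < 0)) stop("nacl must be non-negative")
  .interp_clamped(nacl, scale$anchors[, 1], scale$anchors[, 2])
}

#' Map conductivity back to NaCl-equivalent concentration
#'
#' Inverse of [nacl_to_conductivity()] by interpolation on the same
#' anchors.
#'
#' @param cond Conductivity in mS cm^-1 (>= 0).
#' @param scale A [salinity_scale()].
#' @return NaCl-equivalent in g L^-1.
#' @export
conductivity_to_nacl <- function(cond, scale = salinity_scale()) {
  if (any(cond < 0)) stop("conductivity must be non-negative")
  .interp_clamped(cond, scale$anchors[, 2], scale$anchors[, 1])
}

.interp_clamped <- function(x, xs, ys) {
  out <- stats::approx(xs, ys, xout = x, rule = 2)$y
  lo <- x < xs[1]
  hi <- x > xs[length(xs)]
  if (any(lo | hi)) {
    warning("value(s) outside anchor range; extrapolating with end-segment slope")
    n <- length(xs)
    s1 <- (ys[2] - ys[1]) / (xs[2] - xs[1])
    s2 <- (ys[n] - ys[n - 1]) / (xs[n] - xs[n - 1])
    out[lo] <- ys[1] + (x[lo] - xs[1]) * s1
    out[hi] <- ys[n] + (x[hi] - xs[n]) * s2
  }
  out
}

#' Classify a conductivity into a water class
#'
#' Bands are right-open at the brine boundary: brine iff strictly above
#' the top bound (default 47 mS cm^-1), saline includes the bound.
#'
#' @param cond Conductivity in mS cm^-1 (vectorised, >= 0).
#' @param scale A [salinity_scale()].
#' @return Ordered factor with levels fresh < brackish < saline < brine.
#' @examples
#' classify_salinity(c(1.6, 33, 68.8))
#' @export
classify_salinity <- function(cond, scale = salinity_scale()) {
  if (any(cond < 0)) stop("conductivity must be non-negative")
  b <- scale$class_bounds
  cls <- ifelse(cond < b[[1]], "fresh",
         ifelse(cond < b[[2]], "brackish",
         ifelse(cond <= b[[3]], "saline", "brine")))
  factor(cls, levels = c("fresh", "brackish", "saline", "brine"),
         ordered = TRUE)
}

#' Limiting molar ionic conductivities
#'
#' Infinite-dilution molar conductivities (S cm^2 mol^-1, 25 C) for the
#' ions involved in VFA-bearing media. Values for Na+, acetate,
#' propionate and butyrate are handbook constants; valerate and
#' caproate are extrapolated down the homologous series and flagged as
#' estimates.
#'
#' @format Named numeric vector.
#' @export
limiting_ionic_conductivities <- c(
  Na = 50.1, K = 73.5,
  acetate = 40.9, propionate = 35.8, butyrate = 32.6,
  valerate = 31.0, caproate = 29.5
)

#' Estimated VFA contribution to conductivity
#'
#' Kohlrausch-law estimate: for each acid species, the anionic fraction
#' times the molar concentration times the summed limiting
#' conductivities of the anion and its counter ion. This is an
#' order-of-magnitude estimate (no ionic-strength correction); in
#' fermentation effluents carrying ~30 g_COD/L of mixed VFAs at pH 7 it
#' lands in the high-teens-to-mid-twenties mS cm^-1 range.
#'
#' @param vfa_profile Named vector of concentrations in g_COD L^-1 over
#'   acid species present in the compound table (`acetate`,
#'   `propionate`, `butyrate`, ...).
#' @param ph Medium pH.
#' @param pka Effective pKa (scalar, default 4.8) or per-species named
#'   vector.
#' @param counter_ion Name of the counter cation (default `"Na"`).
#' @return Conductivity estimate in mS cm^-1, with attribute
#'   `"estimate"` set to `TRUE`.
#' @export
vfa_conductivity_contribution <- function(vfa_profile, ph, pka = 4.8,
                                          counter_ion = "Na") {
  if (length(vfa_profile) == 0) {
    return(structure(0, estimate = TRUE))
  }
  stopifnot(!is.null(names(vfa_profile)), all(vfa_profile >= 0))
  if (!counter_ion %in% names(limiting_ionic_conductivities)) {
    stop("unknown counter ion: ", counter_ion)
  }
  kappa <- 0
  for (nm in names(vfa_profile)) {
    if (!nm %in% names(limiting_ionic_conductivities)) {
      stop("unknown VFA species: ", nm)
    }
    rec <- find_compound(nm)
    acid_mass <- molar_mass(parse_formula(rec$formula)) +
      abs(rec$charge) * atomic_masses[["H"]]
    cod_factor <- thod_per_gram(rec$formula, rec$charge)
    c_mol <- vfa_profile[[nm]] / cod_factor / acid_mass # mol/L of acid
    pka_i <- if (length(pka) > 1) pka[[nm]] else pka
    frac <- anionic_fraction(ph, pka_i)
    lambda <- limiting_ionic_conductivities[[nm]] +
      limiting_ionic_conductivities[[counter_ion]]
    # kappa [mS/cm] = Lambda [S cm^2/mol] * c [mol/L]
    kappa <- kappa + frac * c_mol * lambda
  }
  structure(kappa, estimate = TRUE)
}
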