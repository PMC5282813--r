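# Reactions: stoichiometric maps over compound records, parsed from a
# plain-text equation syntax. Reactants carry negative coefficients,
# products positive; protons are explicit species so that charge
# balance can be enforced.

#' Construct a reaction from a stoichiometry map
#'
#' @param stoichiometry Named numeric vector of signed coefficients over
#'   compound names (reactants negative, products positive).
#' @param label Free-text label.
#' @param table Compound table used to resolve names.
#' @return An object of class `ferm_reaction`.
#' @seealso [parse_reaction()], [check_balance()]
#' @export
reaction <- function(stoichiometry, label = "", table = compound_table()) {
  stopifnot(is.numeric(stoichiometry), !is.null(names(stoichiometry)))
  stoichiometry <- stoichiometry[stoichiometry != 0]
  if (!any(stoichiometry < 0) || !any(stoichiometry > 0)) {
    stop("a reaction needs at least one reactant and one product")
  }
  for (nm in names(stoichiometry)) find_compound(nm, table)
  structure(
    list(stoichiometry = stoichiometry, label = label),
    class = "ferm_reaction"
  )
}

#' Parse a plain-text reaction equation
#'
#' Equations use `->` between sides and ` + ` between terms, with
#' optional numeric coefficients, e.g.
#' `"C6H12O6 -> 3 CH3COO- + 3 H+"`. Tokens are resolved against
#' compound names, aliases and formulas.
#'
#' @param text Equation string.
#' @param label Label stored on the reaction (defaults to the text).
#' @param table Compound table.
#' @return A `ferm_reaction`.
#' @examples
#' parse_reaction("C6H12O6 -> 2 CH3CH2OH + 2 CO2")
#' @export
parse_reaction <- function(text, label = text, table = compound_table()) {
  sides <- strsplit(text, "->", fixed = TRUE)[[1]]
  if (length(sides) != 2) {
    stop("equation must contain exactly one '->': ", text, call. = FALSE)
  }
  parse_side <- function(side, sign) {
    terms <- strsplit(side, " + ", fixed = TRUE)[[1]]
    terms <- trimws(terms)
    terms <- terms[nzchar(terms)]
    if (length(terms) == 0) stop("empty reaction side in: ", text, call. = FALSE)
    out <- numeric(0)
    for (term in terms) {
      m <- regexec("^([0-9]*\\.?[0-9]+)?\\s*(.+)$", term)[[1]]
      parts <- regmatches(term, list(m))[[1]]
      coef <- if (nzchar(parts[2])) as.numeric(parts[2]) else 1
      nm <- find_compound(parts[3], table)$name
      out[nm] <- (if (nm %in% names(out)) out[[nm]] else 0) + sign * coef
    }
    out
  }
  lhs <- parse_side(sides[1], -1)
  rhs <- parse_side(sides[2], +1)
  st <- lhs
  for (nm in names(rhs)) {
    st[nm] <- (if (nm %in% names(st)) st[[nm]] else 0) + rhs[[nm]]
  }
  reaction(st, label = label, table = table)
}

#' Element and charge balance report for a reaction
#'
#' A reaction is balanced iff every per-element residual and the charge
#' residual are within `tol` (protons are counted explicitly).
#'
#' @param rx A `ferm_reaction`.
#' @param table Compound table.
#' @param tol Balance tolerance (default 1e-9).
#' @return List with `elements` (named residuals), `charge`, `balanced`.
#' @export
check_balance <- function(rx, table = compound_table(), tol = 1e-9) {
  stopifnot(inherits(rx, "ferm_reaction"))
  elements <- numeric(0)
  charge <- 0
  for (nm in names(rx$stoichiometry)) {
    coef <- rx$stoichiometry[[nm]]
    rec <- find_compound(nm, table)
    f <- parse_formula(rec$formula)
    for (el in names(f)) {
      elements[el] <- (if (el %in% names(elements)) elements[[el]] else 0) +
        coef * f[[el]]
    }
    charge <- charge + coef * rec$charge
  }
  list(
    elements = elements,
    charge = charge,
    balanced = all(abs(elements) <= tol) && abs(charge) <= tol
  )
}

.assert_balanced <- function(rx, table = compound_table()) {
  bal <- check_balance(rx, table)
  if (!bal$balanced) {
    stop(
      "reaction is not balanced (element residuals: ",
      paste(sprintf("%s=%g", names(bal$elements), bal$elements), collapse = ", "),
      "; charge residual: ", format(bal$charge), ")",
      call. = FALSE
    )
  }
  invisible(rx)
}

#' Standard reaction Gibbs energy at 298.15 K
#'
#' Sum of signed stoichiometric coefficients times the formation Gibbs
#' energies of the participating species.
#'
#' @param rx A balanced `ferm_reaction`.
#' @param table Compound table.
#' @return kJ mol^-1.
#' @export
delta_g0 <- function(rx, table = compound_table()) {
  .assert_balanced(rx, table)
  sum(vapply(
    names(rx$stoichiometry),
    function(nm) rx$stoichiometry[[nm]] * find_compound(nm, table)$dGf0_kJ_mol,
    numeric(1)
  ))
}

#' Standard reaction enthalpy at 298.15 K
#'
#' @inheritParams delta_g0
#' @return kJ mol^-1.
#' @export
delta_h0 <- function(rx, table = compound_table()) {
  .assert_balanced(rx, table)
  sum(vapply(
    names(rx$stoichiometry),
    function(nm) rx$stoichiometry[[nm]] * find_compound(nm, table)$dHf0_kJ_mol,
    numeric(1)
  ))
}

#' Net proton production of a reaction
#'
#' Signed coefficient of the explicit proton species (0 if absent).
#'
#' @param rx A `ferm_reaction`.
#' @return Signed numeric count.
#' @export
net_protons <- function(rx) {
  st <- rx$stoichiometry
  if ("proton" %in% names(st)) st[["proton"]] else 0
}

#' Reverse a reaction
#'
#' @param rx A `ferm_reaction`.
#' @return The reaction with all coefficients negated.
#' @export
reverse_reaction <- function(rx) {
  reaction(-rx$stoichiometry, label = paste("reverse of", rx$label))
}

#' Stoichiometric linear combination of two reactions
#'
#' Useful for Hess-additivity checks: `a * rx1 + b * rx2`.
#'
#' @param rx1,rx2 Reactions.
#' @param a,b Multipliers.
#' @param label Label for the combination.
#' @return A `ferm_reaction`.
#' @export
combine_reactions <- function(rx1, rx2, a = 1, b = 1, label = "") {
  st <- a * rx1$stoichiometry
  for (nm in names(rx2$stoichiometry)) {
    st[nm] <- (if (nm %in% names(st)) st[[nm]] else 0) + b * rx2$stoichiometry[[nm]]
  }
  reaction(st, label = label)
}

#' @export
print.ferm_reaction <- function(x, ...) {
  st <- x$stoichiometry
  fmt <- function(v) {
    coef <- abs(v)
    ifelse(coef == 1, names(v), paste(format(coef, trim = TRUE), names(v)))
  }
  lhs <- fmt(st[st < 0])
  rhs <- fmt(st[st > 0])
  cat(paste(lhs, collapse = " + "), "->", paste(rhs, collapse = " + "), "\n")
  if (nzchar(x$label) && x$label != "") cat("label:", x$label, "\n")
  invisible(x)
}
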