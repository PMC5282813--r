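# Compound table and chemical formula utilities.
#
# The packaged table holds standard Gibbs energies and enthalpies of
# formation at 298.15 K for the species taking part in the fermentation
# pathways of interest (sugar -> ethanol / acetate / propionate /
# butyrate, plus H2, CO2, CH4, H2O and the proton). Aqueous species use
# the 1 M standard state, gases 1 atm; acids are carried as anions with
# the proton an explicit species (dGf0 = 0 by convention).

.vfaferm_env <- new.env(parent = emptyenv())

#' Atomic masses used throughout the package
#'
#' Standard atomic weights (g mol^-1) for the elements the package
#' handles in formulas and theoretical-oxygen-demand arithmetic.
#'
#' @format Named numeric vector.
#' @export
atomic_masses <- c(
  C = 12.011, H = 1.008, O = 15.999, N = 14.007,
  Na = 22.990, Cl = 35.453, P = 30.974, S = 32.06
)

#' Parse a molecular formula into an element count map
#'
#' Accepts simple Hill-style formulas such as `"C6H12O6"` or `"CH4"`,
#' with optional parenthesised repeat groups (`"CH3(CH2)2COOH"`). Charge
#' symbols are not part of a formula; charges are carried separately.
#'
#' @param x A formula string, or an already-parsed named numeric vector
#'   (returned unchanged).
#' @return Named numeric vector of positive element counts.
#' @examples
#' parse_formula("C6H12O6")
#' @export
parse_formula <- function(x) {
  if (is.numeric(x)) {
    if (is.null(names(x)) || any(x <= 0)) {
      stop("formula count map must be named with positive counts")
    }
    return(x)
  }
  stopifnot(is.character(x), length(x) == 1L)
  s <- gsub("\\s", "", x)
  # expand parenthesised groups, e.g. (CH2)2
  while (grepl("(", s, fixed = TRUE)) {
    m <- regexpr("\\(([A-Za-z0-9]+)\\)([0-9]*)", s)
    if (m == -1L) stop("unbalanced parentheses in formula: ", x)
    frag <- regmatches(s, m)
    inner <- sub("\\(([A-Za-z0-9]+)\\)([0-9]*)", "\\1", frag)
    n <- sub("\\(([A-Za-z0-9]+)\\)([0-9]*)", "\\2", frag)
    n <- if (nzchar(n)) as.integer(n) else 1L
    regmatches(s, m) <- paste(rep(inner, n), collapse = "")
  }
  if (!grepl("^([A-Z][a-z]?[0-9]*)+$", s)) {
    stop("cannot parse formula: ", x)
  }
  tokens <- regmatches(s, gregexpr("[A-Z][a-z]?[0-9]*", s))[[1]]
  counts <- numeric(0)
  for (tok in tokens) {
    el <- sub("[0-9]*$", "", tok)
    n <- sub("^[A-Za-z]+", "", tok)
    n <- if (nzchar(n)) as.numeric(n) else 1
    counts[el] <- if (el %in% names(counts)) counts[[el]] + n else n
  }
  counts
}

#' Molar mass of a formula
#'
#' @param formula Formula string or named element-count vector.
#' @return Molar mass in g mol^-1.
#' @export
molar_mass <- function(formula) {
  f <- parse_formula(formula)
  unknown <- setdiff(names(f), names(atomic_masses))
  if (length(unknown) > 0) {
    stop("no atomic mass for element(s): ", paste(unknown, collapse = ", "))
  }
  sum(f * atomic_masses[names(f)])
}

#' The packaged compound thermodynamic table
#'
#' Standard formation Gibbs energies and enthalpies (kJ mol^-1, 298.15 K)
#' for the fermentation species, read from the TSV shipped in
#' `extdata/compounds.tsv`. Values follow the classic anaerobic
#' bioenergetics tables (Thauer-style); provenance is recorded per row in
#' the `source` column.
#'
#' @param path Optional path to an alternative table with the same
#'   columns (`name`, `formula`, `phase`, `charge`, `dGf0_kJ_mol`,
#'   `dHf0_kJ_mol`, `aliases`, `source`).
#' @return A data.frame, one row per compound.
#' @export
compound_table <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.vfaferm_env$compounds)) return(.vfaferm_env$compounds)
    path <- system.file("extdata", "compounds.tsv", package = "vfaferm")
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    tab <- .validate_compound_table(tab)
    .vfaferm_env$compounds <- tab
    return(tab)
  }
  .validate_compound_table(utils::read.delim(path, stringsAsFactors = FALSE))
}

.validate_compound_table <- function(tab) {
  need <- c("name", "formula", "phase", "charge", "dGf0_kJ_mol", "dHf0_kJ_mol")
  missing <- setdiff(need, names(tab))
  if (length(missing) > 0) {
    stop("compound table lacks column(s): ", paste(missing, collapse = ", "))
  }
  stopifnot(
    all(is.finite(tab$dGf0_kJ_mol)), all(is.finite(tab$dHf0_kJ_mol)),
    all(tab$phase %in% c("aq", "g", "l"))
  )
  for (i in seq_len(nrow(tab))) parse_formula(tab$formula[i])
  tab
}

#' Look up a compound record
#'
#' Resolves a token against compound names, equation aliases (e.g.
#' `"CH3COO-"`) and raw formulas.
#'
#' @param token Compound name, alias or formula string.
#' @param table Compound table (defaults to the packaged one).
#' @return One-row data.frame.
#' @export
find_compound <- function(token, table = compound_table()) {
  token <- trimws(token)
  hit <- which(table$name == token)
  if (length(hit) == 0 && "aliases" %in% names(table)) {
    hit <- which(vapply(
      strsplit(table$aliases, "|", fixed = TRUE),
      function(a) token %in% a, logical(1)
    ))
  }
  if (length(hit) == 0) hit <- which(table$formula == token)
  if (length(hit) == 0) {
    stop("unknown compound: '", token, "'", call. = FALSE)
  }
  table[hit[1], , drop = FALSE]
}
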