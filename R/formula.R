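#' Monoisotopic atomic masses
#'
#' Masses (Da) of the most abundant isotope of each supported element,
#' IUPAC/AME2020 values truncated to the precision carried through all
#' downstream m/z arithmetic.
#'
#' @format Named numeric vector, one entry per element symbol.
#' @keywords internal
.monoisotopic <- c(
  C  = 12,            # exact by definition
  H  = 1.00782503,
  N  = 14.00307401,
  O  = 15.99491462,
  S  = 31.97207117,
  Fe = 55.93493633,
  P  = 30.97376200,
  Na = 22.98976928,
  K  = 38.96370649,
  Cl = 34.96885268
)

#' Fundamental charge-carrier masses (Da)
#' @keywords internal
.proton_mass <- 1.00727646
.electron_mass <- 0.00054858

#' Parse a molecular formula string
#'
#' Converts a Hill-style formula such as `"C34H50N6O11"` into a named
#' integer vector of element counts. An element symbol with no trailing
#' number has an implicit count of 1.
#'
#' @param text Single formula string: element symbols (one uppercase letter,
#'   optionally one lowercase letter) each followed by an optional integer.
#' @return A named integer vector of class `molecular_formula`.
#' @examples
#' parse_formula("C34H50N6O11")  # petrobactin
#' parse_formula("H2O")
#' @export
parse_formula <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- trimws(text)
  if (!nzchar(text)) {
    out <- integer(0)
    class(out) <- "molecular_formula"
    return(out)
  }
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", text, perl = TRUE)[[1]]
  tokens <- regmatches(text, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(text)) {
    covered <- paste(tokens, collapse = "")
    bad <- substr(text, nchar(covered) + 1L, nchar(text))
    stop("malformed formula near '", bad, "' in '", text, "'")
  }
  sym <- sub("[0-9]*$", "", tokens)
  cnt <- sub("^[A-Za-z]+", "", tokens)
  cnt <- ifelse(cnt == "", 1L, as.integer(cnt))
  unknown <- setdiff(sym, names(.monoisotopic))
  if (length(unknown)) {
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "),
         " (supported: ", paste(names(.monoisotopic), collapse = ", "), ")")
  }
  out <- tapply(cnt, factor(sym, levels = unique(sym)), sum)
  out <- stats::setNames(as.integer(out), names(out))
  class(out) <- "molecular_formula"
  out
}

#' Neutral monoisotopic mass of a formula
#'
#' @param formula A `molecular_formula` (see [parse_formula()]) or a formula
#'   string, or a named numeric vector of element counts.
#' @return Neutral monoisotopic mass in Da.
#' @examples
#' monoisotopic_mass("C34H50N6O11")  # 718.353757
#' @export
monoisotopic_mass <- function(formula) {
  if (is.character(formula)) formula <- parse_formula(formula)
  if (length(formula) == 0L) return(0)
  if (is.null(names(formula)) || any(!nzchar(names(formula))))
    stop("formula must be a named count vector")
  unknown <- setdiff(names(formula), names(.monoisotopic))
  if (length(unknown))
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
  if (any(formula < 0)) stop("element counts must be non-negative")
  sum(unclass(formula) * .monoisotopic[names(formula)])
}

# Adduct table: m/z = (M * n_M + delta) / charge. All deltas are exact
# composition arithmetic: protons for added/removed charges, atom masses for
# exchanged atoms, one electron mass per net positive charge where a neutral
# atom (Fe) carries the charge.
.adducts <- list(
  "[M+H]+"     = list(delta = .proton_mass,     charge = 1),
  "[M+2H]2+"   = list(delta = 2 * .proton_mass, charge = 2),
  "[M-H]-"     = list(delta = -.proton_mass,    charge = 1),
  # Fe(III) complex detected as a singly charged ion: neutral M loses two H
  # atoms, gains one Fe atom, loses one electron.
  # delta = Fe - 2 H - e- = +53.918738 Da
  "[M+Fe-2H]+" = list(
    delta = unname(.monoisotopic["Fe"] - 2 * .monoisotopic["H"] - .electron_mass),
    charge = 1)
)

#' Supported adduct names
#' @return Character vector of adduct names accepted by [adduct_mz()].
#' @export
supported_adducts <- function() names(.adducts)

#' Theoretical adduct m/z
#'
#' Computes the m/z of an ionized form of a neutral molecule. Charge is
#' carried by added/removed protons (1.00727646 Da each), except for the
#' ferric complex `[M+Fe-2H]+` where Fe(III) substitutes protons and the
#' electron deficit is accounted explicitly.
#'
#' @param neutral_mass Neutral monoisotopic mass (Da); vectorized.
#' @param adduct One of [supported_adducts()].
#' @return m/z in Th (full precision; round only for display).
#' @examples
#' adduct_mz(monoisotopic_mass("C34H50N6O11"), "[M+H]+")  # 719.361
#' @export
adduct_mz <- function(neutral_mass, adduct) {
  stopifnot(is.numeric(neutral_mass), length(adduct) == 1L)
  a <- .adducts[[adduct]]
  if (is.null(a)) {
    stop("unsupported adduct '", adduct, "'; supported: ",
         paste(names(.adducts), collapse = ", "))
  }
  (neutral_mass + a$delta) / a$charge
}

#' Built-in siderophore reference table
#'
#' A small reference of known siderophore structures with molecular
#' formulas, used for m/z screening. Petrobactin carries the four
#' diagnostic MS2 fragment ions reported for its collision spectra.
#'
#' @return Data frame with columns `name`, `formula`, `neutral_mass`,
#'   and `ms2` (semicolon-joined reference fragment m/z, or `NA`).
#' @export
siderophore_reference <- function() {
  tab <- data.frame(
    name = c("petrobactin", "petrobactin derivative",
             "ferrioxamine B", "aerobactin"),
    formula = c("C34H50N6O11", "C32H46N6O11",
                "C25H48N6O8", "C22H36N4O13"),
    ms2 = c("194;282;438;565", NA, NA, NA),
    stringsAsFactors = FALSE
  )
  tab$neutral_mass <- vapply(tab$formula, monoisotopic_mass, numeric(1))
  tab[, c("name", "formula", "neutral_mass", "ms2")]
}

#' Read a siderophore reference table
#'
#' Reads a TSV with columns `name` and `formula` (optional `ms2`,
#' optional `neutral_mass`). Masses are always recomputed from the
#' formulas; a supplied mass column is validated against the recomputed
#' value and a disagreement beyond 1e-3 Da raises a warning naming the
#' compound (the recomputed value wins).
#'
#' @param path TSV file path.
#' @return Data frame as in [siderophore_reference()].
#' @export
read_siderophore_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("name", "formula") %in% names(tab)))
    stop("reference table needs 'name' and 'formula' columns")
  mass <- vapply(tab$formula, monoisotopic_mass, numeric(1))
  if ("neutral_mass" %in% names(tab)) {
    off <- which(abs(tab$neutral_mass - mass) > 1e-3)
    if (length(off))
      warning("reference mass column disagrees with formula for: ",
              paste(tab$name[off], collapse = ", "), "; recomputed values used")
  }
  tab$neutral_mass <- unname(mass)
  if (!"ms2" %in% names(tab)) tab$ms2 <- NA_character_
  tab[, c("name", "formula", "neutral_mass", "ms2")]
}
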