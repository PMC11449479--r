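#' Monoisotopic masses of the isotopes used in the labeling experiment
#'
#' Light-isotope masses (1H, 12C, 14N, 16O) drive all neutral monoisotopic
#' mass calculations; the heavy shifts per atom follow from 13C and 15N.
#' Cells fully labeled on \[13C\]glucose and \[15N\]ammonium chloride are
#' assumed 100 % enriched, so a "heavy" moiety replaces every C and N.
#'
#' @format Named numeric vector of monoisotopic masses (Da).
#' @export
ISOTOPE_MASSES <- c(
  H1  = 1.0078250319,
  C12 = 12.0,
  C13 = 13.0033548378,
  N14 = 14.0030740052,
  N15 = 15.0001088984,
  O16 = 15.9949146221
)

#' @rdname ISOTOPE_MASSES
#' @export
DELTA_C13 <- unname(ISOTOPE_MASSES["C13"] - ISOTOPE_MASSES["C12"])

#' @rdname ISOTOPE_MASSES
#' @export
DELTA_N15 <- unname(ISOTOPE_MASSES["N15"] - ISOTOPE_MASSES["N14"])

# light-isotope mass per element symbol
.element_masses <- c(
  C = unname(ISOTOPE_MASSES["C12"]),
  H = unname(ISOTOPE_MASSES["H1"]),
  N = unname(ISOTOPE_MASSES["N14"]),
  O = unname(ISOTOPE_MASSES["O16"])
)

#' Elemental compositions
#'
#' An elemental composition is a named integer vector of non-negative atom
#' counts per element symbol (C, H, N, O and any further symbols with a known
#' monoisotopic mass). Compositions add and subtract element-wise;
#' subtraction below zero is a structural error, not a warning, because it
#' means a condensation was counted for atoms that are not there.
#'
#' @param ... Element counts, e.g. `composition(C = 12, H = 26, N = 6, O = 3)`.
#' @return Named integer vector of class `lpp_composition`.
#' @examples
#' composition(C = 12, H = 26, N = 6, O = 3)
#' comp_add(composition(H = 2, O = 1), composition(H = 2, O = 1))
#' @export
composition <- function(...) {
  x <- c(...)
  if (length(x) == 0)
    return(structure(integer(0), names = character(0),
                     class = "lpp_composition"))
  if (is.null(names(x)) || any(names(x) == ""))
    stop("composition() needs named element counts")
  if (any(x < 0)) stop("element counts must be non-negative")
  if (any(x != round(x))) stop("element counts must be integers")
  structure(as.integer(round(x)), names = names(x), class = "lpp_composition")
}

as_composition <- function(x) {
  if (inherits(x, "lpp_composition")) return(x)
  do.call(composition, as.list(x))
}

#' @param a,b Compositions (or named count vectors).
#' @rdname composition
#' @export
comp_add <- function(a, b) {
  a <- as_composition(a); b <- as_composition(b)
  els <- union(names(a), names(b))
  out <- setNames(integer(length(els)), els)
  out[names(a)] <- out[names(a)] + a
  out[names(b)] <- out[names(b)] + b
  structure(out, class = "lpp_composition")
}

#' @rdname composition
#' @export
comp_subtract <- function(a, b) {
  a <- as_composition(a); b <- as_composition(b)
  els <- union(names(a), names(b))
  out <- setNames(integer(length(els)), els)
  out[names(a)] <- out[names(a)] + a
  out[names(b)] <- out[names(b)] - b
  if (any(out < 0))
    stop("composition subtraction yields negative count for ",
         paste(els[out < 0], collapse = ", "))
  structure(out, class = "lpp_composition")
}

#' @param k Non-negative integer multiplier.
#' @rdname composition
#' @export
comp_scale <- function(a, k) {
  a <- as_composition(a)
  if (k < 0 || k != round(k)) stop("k must be a non-negative integer")
  structure(as.integer(a * k), names = names(a), class = "lpp_composition")
}

#' @export
print.lpp_composition <- function(x, ...) {
  cat(format_formula(x), " (", format(monoisotopic_mass(x), nsmall = 4),
      " Da)\n", sep = "")
  invisible(x)
}

#' Parse a molecular formula string into a composition
#'
#' Accepts element symbols (one capital letter plus optional lowercase)
#' followed by optional integer counts, e.g. `"C8H15NO6"`.
#'
#' @param x Formula string.
#' @return A [composition()].
#' @examples
#' parse_formula("C8H15NO6")
#' @export
parse_formula <- function(x) {
  stopifnot(is.character(x), length(x) == 1)
  m <- gregexpr("[A-Z][a-z]?[0-9]*", x)[[1]]
  toks <- regmatches(x, list(m))[[1]]
  if (length(toks) == 0 || sum(attr(m, "match.length")) != nchar(x))
    stop("cannot parse formula: ", x)
  els <- sub("[0-9]*$", "", toks)
  cnt <- as.integer(sub("^[A-Za-z]+", "", paste0(toks, "")))
  cnt[is.na(cnt)] <- 1L
  out <- tapply(cnt, els, sum)
  do.call(composition, as.list(out))
}

format_formula <- function(comp) {
  comp <- as_composition(comp)
  comp <- comp[comp > 0]
  ord <- c(intersect(c("C", "H", "N", "O"), names(comp)),
           setdiff(names(comp), c("C", "H", "N", "O")))
  paste0(ord, ifelse(comp[ord] > 1, comp[ord], ""), collapse = "")
}

#' Neutral monoisotopic mass of a composition
#'
#' Sum of atom counts times light-isotope monoisotopic masses. Tabulated
#' values in this package are neutral masses; converting to an m/z is the
#' display transform `(mass + k * 1.007276) / k` for charge k.
#'
#' @param comp A [composition()] or named count vector.
#' @return Mass in Da.
#' @examples
#' monoisotopic_mass(parse_formula("H2O"))
#' @export
monoisotopic_mass <- function(comp) {
  comp <- as_composition(comp)
  if (length(comp) == 0) return(0)
  unknown <- setdiff(names(comp), names(.element_masses))
  if (length(unknown))
    stop("unsupported element(s): ", paste(unknown, collapse = ", "))
  sum(comp * .element_masses[names(comp)])
}

#' Mass shift of full 13C/15N labeling
#'
#' The mass added when every carbon is 13C and every nitrogen is 15N
#' (full metabolic enrichment): `nC * (m13C - m12C) + nN * (m15N - m14N)`.
#' Condensation water losses carry no C or N, so the heavy shift of a
#' moiety depends only on the summed C and N counts of its residues.
#'
#' @param comp A [composition()].
#' @return Shift in Da.
#' @examples
#' heavy_shift(parse_formula("C6H14N4O2")) # Arg: 10.01 Da
#' @export
heavy_shift <- function(comp) {
  comp <- as_composition(comp)
  nC <- if ("C" %in% names(comp)) comp[["C"]] else 0
  nN <- if ("N" %in% names(comp)) comp[["N"]] else 0
  nC * DELTA_C13 + nN * DELTA_N15
}

#' Round half away from zero
#'
#' Published muropeptide tables round 2-decimal masses half-up, whereas base
#' `round()` rounds half-to-even; the difference matters on values such as
#' x.xx5.
#'
#' @param x Numeric.
#' @param digits Decimal places.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
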