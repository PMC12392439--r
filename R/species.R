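#' @useDynLib etsnocv, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Unit conversions. Internal units are Hartree and Bohr throughout;
# user-facing geometry input is in Angstrom, reports are in kcal/mol.
HARTREE_TO_KCAL <- 627.5094740631
ANGSTROM_TO_BOHR <- 1 / 0.529177210903

ELEMENT_SYMBOLS <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne",
  "Na", "Mg", "Al", "Si", "P", "S", "Cl", "Ar"
)

symbol_to_Z <- function(sym) {
  z <- match(sym, ELEMENT_SYMBOLS)
  if (anyNA(z)) stop("unknown element symbol(s): ",
                     paste(sym[is.na(z)], collapse = ", "))
  z
}

#' Define a molecular species
#'
#' A species is a set of nuclei plus a total charge and spin multiplicity;
#' it defines one self-consistent-field problem. Coordinates are accepted in
#' Angstrom and stored internally in Bohr.
#'
#' @param symbols character vector of element symbols (or integer atomic
#'   numbers).
#' @param coords numeric matrix (n x 3) of Cartesian coordinates in Angstrom.
#' @param charge integer total charge.
#' @param multiplicity positive integer spin multiplicity 2S+1.
#' @return an object of class `nocv_species`.
#' @examples
#' he <- nocv_species("He", matrix(0, 1, 3))
#' @export
nocv_species <- function(symbols, coords, charge = 0L, multiplicity = 1L) {
  Z <- if (is.numeric(symbols)) as.integer(symbols) else symbol_to_Z(symbols)
  coords <- matrix(as.numeric(coords), ncol = 3)
  stopifnot(nrow(coords) == length(Z))
  if (!all(is.finite(coords))) stop("non-finite coordinates")
  nelec <- sum(Z) - as.integer(charge)
  if (nelec < 0) stop("negative electron count")
  mult <- as.integer(multiplicity)
  if (mult < 1) stop("multiplicity must be a positive integer")
  if (mult - 1L > nelec) stop("multiplicity ", mult, " impossible for ",
                              nelec, " electrons")
  if ((nelec - (mult - 1L)) %% 2L != 0L)
    stop("electron count ", nelec, " inconsistent with multiplicity ", mult)
  na <- (nelec + mult - 1L) / 2L
  structure(list(
    Z = Z, symbols = ELEMENT_SYMBOLS[Z],
    xyz = coords * ANGSTROM_TO_BOHR,  # Bohr
    charge = as.integer(charge), multiplicity = mult,
    nelec = nelec, nalpha = as.integer(na), nbeta = as.integer(nelec - na)
  ), class = "nocv_species")
}

#' @export
print.nocv_species <- function(x, ...) {
  cat(sprintf("<nocv_species> %d atoms, charge %+d, multiplicity %d, %d electrons\n",
              length(x$Z), x$charge, x$multiplicity, x$nelec))
  invisible(x)
}

nuclear_repulsion <- function(Z, xyz) {
  n <- length(Z)
  if (n < 2) return(0)
  e <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    e <- e + Z[i] * Z[j] / sqrt(sum((xyz[i, ] - xyz[j, ])^2))
  }
  e
}

# Cross-fragment nuclear repulsion sum_{X in A} sum_{Y in B} Z_X Z_Y / R_XY.
nuclear_repulsion_cross <- function(ZA, xyzA, ZB, xyzB) {
  e <- 0
  for (i in seq_along(ZA)) for (j in seq_along(ZB)) {
    e <- e + ZA[i] * ZB[j] / sqrt(sum((xyzA[i, ] - xyzB[j, ])^2))
  }
  e
}
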