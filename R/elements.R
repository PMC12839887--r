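## Element bookkeeping: atomic numbers, Bragg-Slater radii (radial grid
## scales), covalent radii (bond perception).  Radii in angstrom here,
## converted to bohr where used.

.ELEMENTS <- data.frame(
  symbol = c("H",  "He", "Li", "Be", "B",  "C",  "N",  "O",  "F",  "Ne",
             "Na", "Mg", "Al", "Si", "P",  "S",  "Cl", "Ar", "K",  "Ca",
             "Br", "I"),
  Z      = c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10,
             11, 12, 13, 14, 15, 16, 17, 18, 19, 20,
             35, 53),
  # Bragg-Slater empirical radii (angstrom); H set to 0.35 as is customary
  # for density-integration radial scales.
  bragg_slater = c(0.35, 0.28, 1.45, 1.05, 0.85, 0.70, 0.65, 0.60, 0.50, 0.38,
                   1.80, 1.50, 1.25, 1.10, 1.00, 1.00, 1.00, 0.71, 2.20, 1.80,
                   1.15, 1.40),
  # single-bond covalent radii (angstrom)
  covalent = c(0.31, 0.28, 1.28, 0.96, 0.84, 0.76, 0.71, 0.66, 0.57, 0.58,
               1.66, 1.41, 1.21, 1.11, 1.07, 1.05, 1.02, 1.06, 2.03, 1.76,
               1.20, 1.39),
  stringsAsFactors = FALSE
)

.element_row <- function(symbol) {
  i <- match(symbol, .ELEMENTS$symbol)
  if (anyNA(i)) {
    stop("unknown element symbol(s): ",
         paste(unique(symbol[is.na(i)]), collapse = ", "), call. = FALSE)
  }
  .ELEMENTS[i, , drop = FALSE]
}

.element_Z <- function(symbol) .element_row(symbol)$Z

.element_symbol <- function(Z) {
  i <- match(Z, .ELEMENTS$Z)
  if (anyNA(i)) stop("no symbol tabulated for Z = ",
                     paste(Z[is.na(i)], collapse = ", "), call. = FALSE)
  .ELEMENTS$symbol[i]
}

#' Define a molecular geometry
#'
#' Builds the atom table used throughout the package: element symbols,
#' Cartesian positions in bohr, and (effective) nuclear charges.  For
#' pseudopotential-bearing elements pass the effective charge explicitly via
#' `Z`.
#'
#' @param element character vector of element symbols.
#' @param xyz numeric matrix (n x 3) of positions in bohr.
#' @param Z optional integer vector of nuclear charges; defaults to the
#'   element's atomic number.
#' @return a data frame of class `"atoms"` with columns `element`, `x`, `y`,
#'   `z`, `Z`.
#' @examples
#' atoms("H", matrix(c(0, 0, 0), 1))
#' @export
atoms <- function(element, xyz, Z = NULL) {
  xyz <- matrix(as.numeric(xyz), ncol = 3)
  stopifnot(length(element) == nrow(xyz))
  if (!all(is.finite(xyz))) stop("atom positions must be finite")
  if (is.null(Z)) Z <- .element_Z(element)
  Z <- as.integer(Z)
  if (any(Z < 1)) stop("nuclear_charge must be >= 1")
  out <- data.frame(element = as.character(element),
                    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                    Z = Z, stringsAsFactors = FALSE)
  class(out) <- c("atoms", "data.frame")
  out
}

.atom_positions <- function(atoms) {
  as.matrix(atoms[, c("x", "y", "z")])
}
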