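## Promolecular references: spherically averaged free-atom radial densities
## rho0_A(r) used by the Hirshfeld stockholder weights and by the relative
## (reference-dependent) functionals.
##
## The bundled reference is an analytic single-zeta Slater-type shell fit
## generated from Slater's screening rules, which keeps the normalization
## 4*pi Int rho0 r^2 dr = N exact in closed form.  User-supplied radial
## tables (e.g. from atomic DFT runs) plug in through
## `reference_from_tables()` with the same interface, and toy Gaussian atoms
## through `gaussian_reference()`.

# ---- Slater-rule shell structure -------------------------------------------

# groups in Slater's grouping; filled in energetic order
.slater_groups <- function(Z) {
  caps <- c("1s" = 2, "2sp" = 8, "3sp" = 8, "3d" = 10, "4sp" = 8,
            "4d" = 10, "5sp" = 8)
  nq   <- c("1s" = 1, "2sp" = 2, "3sp" = 3, "3d" = 3, "4sp" = 4,
            "4d" = 4, "5sp" = 5)
  fill_order <- c("1s", "2sp", "3sp", "4sp", "3d", "4d", "5sp")
  # refill 4sp after 3d completes (Ga..Kr), 5sp after 4d: handled by
  # two-pass fill: first 2 electrons of (n)sp before (n-1)d, then d, then
  # the rest of (n)sp.
  occ <- c("1s" = 0, "2sp" = 0, "3sp" = 0, "3d" = 0, "4sp" = 0,
           "4d" = 0, "5sp" = 0)
  left <- Z
  take <- function(g, k) {
    k <- min(k, caps[[g]] - occ[[g]], left)
    occ[[g]] <<- occ[[g]] + k
    left <<- left - k
  }
  take("1s", 2); take("2sp", 8); take("3sp", 8)
  take("4sp", 2); take("3d", 10); take("4sp", 6)
  take("5sp", 2); take("4d", 10); take("5sp", 6)
  if (left > 0) stop("Slater-rule reference only tabulated up to Z = 54")
  g <- names(occ)[occ > 0]
  data.frame(group = g, n = nq[g], occ = occ[g], is_d = grepl("d", g),
             stringsAsFactors = FALSE)
}

.slater_nstar <- c(`1` = 1, `2` = 2, `3` = 3, `4` = 3.7, `5` = 4.0)

# Slater screening constant for one electron of group i
.slater_zeta <- function(Z) {
  g <- .slater_groups(Z)
  zeta <- numeric(nrow(g))
  for (i in seq_len(nrow(g))) {
    same <- g$occ[i] - 1
    sigma <- same * if (g$group[i] == "1s") 0.30 else 0.35
    if (g$is_d[i]) {
      inner <- sum(g$occ[-i][g$n[-i] < g$n[i] |
                              (g$n[-i] == g$n[i] & !g$is_d[-i])])
      sigma <- sigma + 1.00 * inner
    } else {
      nm1 <- sum(g$occ[g$n == g$n[i] - 1])
      deep <- sum(g$occ[g$n < g$n[i] - 1])
      sigma <- sigma + 0.85 * nm1 + 1.00 * deep
    }
    zeta[i] <- (Z - sigma) / .slater_nstar[[as.character(g$n[i])]]
  }
  g$zeta <- zeta
  g$nstar <- .slater_nstar[as.character(g$n)]
  g
}

# radial shell density rho(r) = C r^m exp(-beta r), spherically averaged,
# normalized so 4 pi Int rho r^2 dr = occ
.shell_funs <- function(occ, nstar, zeta) {
  m <- 2 * nstar - 2
  beta <- 2 * zeta
  C <- occ * beta^(2 * nstar + 1) / (4 * pi * gamma(2 * nstar + 1))
  list(
    rho = function(r) C * r^m * exp(-beta * r),
    d1 = function(r) {
      if (m == 0) return(-beta * C * exp(-beta * r))
      r <- pmax(r, 1e-300)
      C * exp(-beta * r) * (m * r^(m - 1) - beta * r^m)
    },
    d2 = function(r) {
      if (m == 0) return(beta^2 * C * exp(-beta * r))
      r <- pmax(r, 1e-300)
      C * exp(-beta * r) *
        (m * (m - 1) * r^(m - 2) - 2 * beta * m * r^(m - 1) + beta^2 * r^m)
    },
    occ = occ)
}

.sum_radial <- function(shells) {
  list(
    rho = function(r) Reduce(`+`, lapply(shells, function(s) s$rho(r))),
    d1 = function(r) Reduce(`+`, lapply(shells, function(s) s$d1(r))),
    d2 = function(r) Reduce(`+`, lapply(shells, function(s) s$d2(r))))
}

# ---- reference constructors ------------------------------------------------

.new_reference <- function(elements, type) {
  structure(list(elements = elements, type = type),
            class = "promolecular_reference")
}

#' Bundled free-atom reference densities
#'
#' Spherically averaged neutral-atom radial densities from single-zeta
#' Slater-type shells (Slater's screening rules).  Exactly normalized to the
#' element electron count.  Intended as a self-contained stand-in for
#' DFT-quality atomic densities; swap in your own tables with
#' [reference_from_tables()] when quantitative reference atoms are needed.
#'
#' @param elements element symbols to include.
#' @return object of class `"promolecular_reference"`.
#' @examples
#' ref <- promolecular_reference(c("H", "O"))
#' @export
promolecular_reference <- function(elements = c("H", "C", "N", "O", "F",
                                                "S", "Cl", "Br")) {
  el <- lapply(elements, function(sym) {
    Z <- .element_Z(sym)
    g <- .slater_zeta(Z)
    shells <- lapply(seq_len(nrow(g)), function(i) {
      .shell_funs(g$occ[i], g$nstar[i], g$zeta[i])
    })
    tot <- .sum_radial(shells)
    list(rho0 = tot$rho, d1 = tot$d1, d2 = tot$d2,
         n_electrons = Z, shells = shells)
  })
  names(el) <- elements
  .new_reference(el, "slater")
}

#' Gaussian reference atoms (toy systems)
#'
#' One normalized Gaussian per element label; used by the synthetic toy
#' molecules, for which the promolecule then has closed form.
#'
#' @param alpha named numeric vector of exponents per element label.
#' @param n_electrons named numeric vector of electron counts per label.
#' @return object of class `"promolecular_reference"`.
#' @export
gaussian_reference <- function(alpha, n_electrons) {
  stopifnot(length(alpha) == length(n_electrons),
            !is.null(names(alpha)), all(alpha > 0))
  el <- lapply(seq_along(alpha), function(i) {
    a <- alpha[[i]]; N <- n_electrons[[i]]
    A <- N * (a / pi)^1.5
    list(rho0 = function(r) A * exp(-a * r^2),
         d1 = function(r) -2 * a * r * A * exp(-a * r^2),
         d2 = function(r) A * exp(-a * r^2) * (4 * a^2 * r^2 - 2 * a),
         n_electrons = N,
         shells = list(list(
           rho = function(r) A * exp(-a * r^2),
           d1 = function(r) -2 * a * r * A * exp(-a * r^2),
           occ = N)))
  })
  names(el) <- names(alpha)
  .new_reference(el, "gaussian")
}

#' Load reference atoms from plain-text radial tables
#'
#' Each file holds two whitespace-separated columns: radius (bohr) and
#' spherically averaged density (e-/bohr^3).  Interpolation is a cubic
#' spline in log-density versus r (positivity-preserving, smooth gradients)
#' with linear log-tail extrapolation.
#'
#' @param files named character vector `c(El = path, ...)`.
#' @param n_electrons optional named electron counts; defaults to the
#'   element's atomic number.
#' @return object of class `"promolecular_reference"`.
#' @export
reference_from_tables <- function(files, n_electrons = NULL) {
  stopifnot(!is.null(names(files)))
  el <- lapply(names(files), function(sym) {
    tab <- utils::read.table(files[[sym]], col.names = c("r", "rho"))
    if (any(tab$rho < 0)) stop("negative reference density for ", sym)
    if (is.unsorted(tab$r, strictly = TRUE)) stop("radii must increase: ", sym)
    s <- stats::splinefun(tab$r, log(pmax(tab$rho, 1e-300)),
                          method = "natural")
    rho0 <- function(r) exp(s(r))
    d1 <- function(r) exp(s(r)) * s(r, deriv = 1)
    d2 <- function(r) exp(s(r)) * (s(r, deriv = 1)^2 + s(r, deriv = 2))
    N <- if (!is.null(n_electrons)) n_electrons[[sym]] else .element_Z(sym)
    list(rho0 = rho0, d1 = d1, d2 = d2, n_electrons = N,
         shells = list(list(rho = rho0, d1 = d1, occ = N)))
  })
  names(el) <- names(files)
  .new_reference(el, "table")
}

#' @export
print.promolecular_reference <- function(x, ...) {
  cat("<promolecular_reference> [", x$type, "] elements: ",
      paste(names(x$elements), collapse = ", "), "\n", sep = "")
  invisible(x)
}

.ref_element <- function(ref, sym) {
  e <- ref$elements[[sym]]
  if (is.null(e)) stop("element ", sym,
                       " missing from the promolecular reference",
                       call. = FALSE)
  e
}

# ---- promolecule -----------------------------------------------------------

#' Superposition-of-free-atoms (promolecular) density
#'
#' Sums the reference radial densities placed at the molecular geometry.
#' Gradients/Laplacians come from the radial derivatives by the chain rule.
#' Atomic shells are exposed as orbital densities of the field.
#'
#' @param atoms an [atoms()] table.
#' @param ref a `"promolecular_reference"`.
#' @return a [density_field()].
#' @export
build_promolecule <- function(atoms, ref) {
  stopifnot(inherits(atoms, "atoms"), inherits(ref, "promolecular_reference"))
  els <- lapply(atoms$element, .ref_element, ref = ref)
  centers <- .atom_positions(atoms)
  atom_field <- function(i) {
    e <- els[[i]]
    ctr <- centers[i, ]
    rho <- function(points) {
      d <- .delta(points, ctr); e$rho0(sqrt(rowSums(d^2)))
    }
    grad <- function(points) {
      d <- .delta(points, ctr)
      r <- pmax(sqrt(rowSums(d^2)), 1e-14)
      (e$d1(r) / r) * d
    }
    laplacian <- function(points) {
      d <- .delta(points, ctr)
      r <- pmax(sqrt(rowSums(d^2)), 1e-14)
      e$d2(r) + 2 * e$d1(r) / r
    }
    orbs <- lapply(e$shells, function(sh) {
      list(rho = function(points) {
        d <- .delta(points, ctr); sh$rho(sqrt(rowSums(d^2)))
      },
      grad = function(points) {
        d <- .delta(points, ctr)
        r <- pmax(sqrt(rowSums(d^2)), 1e-14)
        (sh$d1(r) / r) * d
      })
    })
    density_field(rho, grad, laplacian, e$n_electrons, orbitals = orbs)
  }
  sum_fields(lapply(seq_len(nrow(atoms)), atom_field))
}

#' Rescale a reference field to a target electron count
#'
#' Applies one uniform scaling factor so the field integrates to `target_N`
#' on the given grid; required before relative entropies, which assume equal
#' normalization of density and reference (Gibbs inequality).
#'
#' @param ref_field a [density_field()].
#' @param target_N target electron count (> 0).
#' @param grid quadrature grid used to measure the current integral.
#' @return the scaled [density_field()], with attribute `"scale"`.
#' @export
normalize_reference <- function(ref_field, target_N, grid) {
  stopifnot(inherits(ref_field, "density_field"), target_N > 0)
  I <- grid_integrate(ref_field$rho(grid$points), grid)
  if (!is.finite(I) || I <= 0) {
    stop("reference field integrates to ", format(I),
         "; cannot normalize", call. = FALSE)
  }
  out <- scale_field(ref_field, target_N / I)
  attr(out, "scale") <- target_N / I
  out
}
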