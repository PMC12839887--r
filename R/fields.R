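## Analytic model densities.  A `density_field` bundles closures for the
## density, its gradient and Laplacian (and optionally occupation-weighted
## orbital densities with their gradients); `evaluate_field()` realizes them
## on a grid as a `field_sample`, the single carrier of rho, grad rho,
## laplacian and orbital densities used by every functional.

#' Construct a model density field
#'
#' @param rho function(points n x 3) -> density vector (e-/bohr^3).
#' @param grad function(points) -> n x 3 gradient matrix.
#' @param laplacian function(points) -> Laplacian vector.
#' @param n_electrons declared electron count (integral of `rho`).
#' @param orbitals optional list of orbital components, each a list with
#'   elements `rho` and `grad` (occupation-weighted, so orbital densities sum
#'   to the total density).
#' @return object of class `"density_field"`.
#' @export
density_field <- function(rho, grad, laplacian, n_electrons,
                          orbitals = NULL) {
  stopifnot(is.function(rho), is.function(grad), is.function(laplacian))
  structure(list(rho = rho, grad = grad, laplacian = laplacian,
                 n_electrons = n_electrons, orbitals = orbitals),
            class = "density_field")
}

#' @export
print.density_field <- function(x, ...) {
  cat("<density_field> N =", format(x$n_electrons),
      if (!is.null(x$orbitals)) paste0("(", length(x$orbitals), " orbitals)"),
      "\n")
  invisible(x)
}

.delta <- function(points, center) {
  sweep(matrix(as.numeric(points), ncol = 3), 2, as.numeric(center), "-")
}

#' Normalized Gaussian model density
#'
#' `rho(r) = N (alpha/pi)^{3/2} exp(-alpha |r - c|^2)` with exact analytic
#' gradient and Laplacian; integrates to `n_electrons`.  Registered as a
#' single (occupation-weighted) orbital density so kinetic-energy-density
#' functionals apply.
#'
#' @param n_electrons electron count N > 0.
#' @param alpha Gaussian exponent (bohr^-2), > 0.
#' @param center 3-vector, bohr.
#' @return a [density_field()].
#' @export
gaussian_density <- function(n_electrons, alpha, center = c(0, 0, 0)) {
  if (!is.numeric(alpha) || alpha <= 0) stop("alpha must be > 0")
  if (n_electrons <= 0) stop("n_electrons must be > 0")
  A <- n_electrons * (alpha / pi)^1.5
  rho <- function(points) {
    d <- .delta(points, center)
    A * exp(-alpha * rowSums(d^2))
  }
  grad <- function(points) {
    d <- .delta(points, center)
    (-2 * alpha * A * exp(-alpha * rowSums(d^2))) * d
  }
  laplacian <- function(points) {
    d <- .delta(points, center)
    r2 <- rowSums(d^2)
    A * exp(-alpha * r2) * (4 * alpha^2 * r2 - 6 * alpha)
  }
  density_field(rho, grad, laplacian, n_electrons,
                orbitals = list(list(rho = rho, grad = grad)))
}

#' Slater 1s model density (nuclear cusp oracle)
#'
#' `rho(r) = (Z^3/pi) exp(-2 Z |r - c|)`; integrates to 1.  Its Fisher
#' information is exactly `4 Z^2` in the analytic limit.
#'
#' @param Z orbital exponent (> 0); for a hydrogenic 1s orbital, the nuclear
#'   charge.
#' @param center 3-vector, bohr.
#' @return a [density_field()].
#' @export
slater_1s_density <- function(Z, center = c(0, 0, 0)) {
  if (!is.numeric(Z) || Z <= 0) stop("Z must be > 0")
  A <- Z^3 / pi
  rho <- function(points) {
    d <- .delta(points, center)
    A * exp(-2 * Z * sqrt(rowSums(d^2)))
  }
  grad <- function(points) {
    d <- .delta(points, center)
    r <- pmax(sqrt(rowSums(d^2)), 1e-300)
    (-2 * Z * A * exp(-2 * Z * r) / r) * d
  }
  laplacian <- function(points) {
    d <- .delta(points, center)
    r <- pmax(sqrt(rowSums(d^2)), 1e-300)
    A * exp(-2 * Z * r) * (4 * Z^2 - 4 * Z / r)
  }
  density_field(rho, grad, laplacian, 1,
                orbitals = list(list(rho = rho, grad = grad)))
}

#' Superpose model density fields
#'
#' Sums densities, gradients and Laplacians; concatenates orbital lists.
#'
#' @param ... [density_field()] objects (or a single list of them).
#' @return a [density_field()].
#' @export
sum_fields <- function(...) {
  fields <- list(...)
  if (length(fields) == 1L && !inherits(fields[[1]], "density_field")) {
    fields <- fields[[1]]
  }
  stopifnot(length(fields) >= 1,
            all(vapply(fields, inherits, TRUE, "density_field")))
  rho <- function(points) {
    Reduce(`+`, lapply(fields, function(f) f$rho(points)))
  }
  grad <- function(points) {
    Reduce(`+`, lapply(fields, function(f) f$grad(points)))
  }
  laplacian <- function(points) {
    Reduce(`+`, lapply(fields, function(f) f$laplacian(points)))
  }
  orbs <- unlist(lapply(fields, function(f) f$orbitals), recursive = FALSE)
  density_field(rho, grad, laplacian,
                sum(vapply(fields, function(f) f$n_electrons, 0)),
                orbitals = if (length(orbs)) orbs)
}

#' Uniformly rescale a density field
#'
#' @param field a [density_field()].
#' @param scale multiplicative factor applied to the density (and to every
#'   orbital density).
#' @return a [density_field()].
#' @export
scale_field <- function(field, scale) {
  stopifnot(inherits(field, "density_field"), is.finite(scale))
  orbs <- NULL
  if (!is.null(field$orbitals)) {
    orbs <- lapply(field$orbitals, function(o) {
      list(rho = local({o0 <- o; function(p) scale * o0$rho(p)}),
           grad = local({o0 <- o; function(p) scale * o0$grad(p)}))
    })
  }
  density_field(function(p) scale * field$rho(p),
                function(p) scale * field$grad(p),
                function(p) scale * field$laplacian(p),
                scale * field$n_electrons, orbitals = orbs)
}

#' Evaluate a density field on a grid
#'
#' @param field a [density_field()] (a `field_sample` passes through).
#' @param grid a [build_molecular_grid()] object, or an n x 3 point matrix.
#' @return object of class `"field_sample"`: `rho`, `grad` (n x 3),
#'   `laplacian`, optional `orbital_rho` (list of `list(rho, grad)`),
#'   `n_electrons`.
#' @export
evaluate_field <- function(field, grid) {
  if (inherits(field, "field_sample")) return(field)
  stopifnot(inherits(field, "density_field"))
  pts <- if (inherits(grid, "molecular_grid")) grid$points else
    matrix(as.numeric(grid), ncol = 3)
  orb <- NULL
  if (!is.null(field$orbitals)) {
    orb <- lapply(field$orbitals, function(o) {
      list(rho = o$rho(pts), grad = o$grad(pts))
    })
  }
  structure(list(rho = field$rho(pts), grad = field$grad(pts),
                 laplacian = field$laplacian(pts), orbital_rho = orb,
                 n_electrons = field$n_electrons, n_points = nrow(pts)),
            class = "field_sample")
}

.as_sample <- function(field, grid) evaluate_field(field, grid)
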