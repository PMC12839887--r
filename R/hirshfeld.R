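## Hirshfeld stockholder partition: omega_A(r) = rho0_A(r) / sum_B rho0_B(r),
## rho_A(r) = omega_A(r) rho(r).  Below the promolecule floor the stockholder
## ratio is 0/0 in the exponential tails; such points are assigned wholly to
## the nearest atom, which leaves integrals unchanged.

#' Hirshfeld stockholder partition of a molecular density
#'
#' @param field a [density_field()] or `field_sample` aligned with `grid`.
#' @param atoms an [atoms()] table.
#' @param ref a `"promolecular_reference"` covering every element present.
#' @param grid a [build_molecular_grid()] object.
#' @param floor promolecule floor below which points fall back to
#'   nearest-atom assignment (default 1e-30).
#' @return object of class `"hirshfeld_partition"`: `weights` (points x
#'   atoms sharing matrix), `atomic_rho`, `atomic_ref_rho`, promolecule
#'   values/gradient/Laplacian, the field sample, and per-atom populations.
#' @export
hirshfeld_partition <- function(field, atoms, ref, grid, floor = 1e-30) {
  stopifnot(inherits(atoms, "atoms"), inherits(grid, "molecular_grid"))
  sample <- .as_sample(field, grid)
  if (sample$n_points != length(grid$weights)) {
    stop("field sample and grid are not aligned point-for-point")
  }
  pts <- grid$points
  npt <- nrow(pts)
  nat <- nrow(atoms)
  centers <- .atom_positions(atoms)

  R0 <- matrix(0, npt, nat)          # per-atom reference densities
  gradP <- matrix(0, npt, 3)         # promolecule gradient
  lapP <- numeric(npt)               # promolecule Laplacian
  D <- matrix(0, npt, nat)           # distances for nearest-atom fallback
  for (a in seq_len(nat)) {
    e <- .ref_element(ref, atoms$element[a])
    d <- .delta(pts, centers[a, ])
    r <- pmax(sqrt(rowSums(d^2)), 1e-14)
    D[, a] <- r
    R0[, a] <- e$rho0(r)
    d1 <- e$d1(r)
    gradP <- gradP + (d1 / r) * d
    lapP <- lapP + e$d2(r) + 2 * d1 / r
  }
  P <- rowSums(R0)
  W <- matrix(0, npt, nat)
  ok <- P > floor
  if (any(ok)) W[ok, ] <- R0[ok, , drop = FALSE] / P[ok]
  if (any(!ok)) {
    if (any(!ok & sample$rho > 1e-8)) {
      stop("promolecule vanishes on a region of significant density (",
           sum(!ok & sample$rho > 1e-8), " points): numerical partition ",
           "failure", call. = FALSE)
    }
    nearest <- max.col(-D[!ok, , drop = FALSE], ties.method = "first")
    W[cbind(which(!ok), nearest)] <- 1
  }
  atomic_rho <- W * sample$rho
  pops <- as.numeric(crossprod(atomic_rho, grid$weights))
  structure(list(weights = W, atomic_rho = atomic_rho, atomic_ref_rho = R0,
                 promolecule = list(rho = P, grad = gradP, laplacian = lapP),
                 sample = sample, populations = pops,
                 atoms = atoms, floor = floor),
            class = "hirshfeld_partition")
}

#' @export
print.hirshfeld_partition <- function(x, ...) {
  cat("<hirshfeld_partition> ", nrow(x$weights), " points, ",
      ncol(x$weights), " atoms\n", sep = "")
  cat("populations:", paste(sprintf("%s %.4f", x$atoms$element,
                                    x$populations), collapse = ", "), "\n")
  invisible(x)
}
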