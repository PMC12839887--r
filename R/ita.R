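## The eleven information-theoretic (ITA) functionals of the electron
## density, evaluated by quadrature.  All quantities are in atomic units;
## logarithms are natural except the relative Renyi entropy, which uses
## log10 as conventionally printed.  A density floor (default 1e-12
## e-/bohr^3) regularizes logarithms and ratios: integrands are set to 0
## below it, consistent with the rho*ln(rho) -> 0 limit.

.DENSITY_FLOOR <- 1e-12

.check_rho <- function(rho) {
  if (min(rho) < -1e-10) {
    stop("density has negative values beyond tolerance (min = ",
         format(min(rho)), ")", call. = FALSE)
  }
  invisible(TRUE)
}

#' Canonical ITA descriptor names
#'
#' Fixed ordering used everywhere a descriptor vector or table appears.
#' @return character vector of length 11.
#' @export
ita_names <- function() {
  c("S_S", "I_F", "S_GBP", "E2", "E3", "rR2", "rR3", "I_G",
    "G1", "G2", "G3")
}

#' Shannon entropy of the electron density
#'
#' `S_S = -Int rho ln(rho) dr`; measures spatial delocalization.
#'
#' @param field [density_field()] or `field_sample`.
#' @param grid quadrature grid.
#' @param floor density floor for the logarithm.
#' @return entropy in atomic units.
#' @export
shannon_entropy <- function(field, grid, floor = .DENSITY_FLOOR) {
  s <- .as_sample(field, grid)
  .check_rho(s$rho)
  f <- ifelse(s$rho > floor, -s$rho * log(pmax(s$rho, floor)), 0)
  grid_integrate(f, grid)
}

#' Fisher information of the electron density
#'
#' `I_F = Int |grad rho|^2 / rho dr`; gauges sharpness/localization.
#'
#' @inheritParams shannon_entropy
#' @return Fisher information in atomic units (non-negative).
#' @export
fisher_information <- function(field, grid, floor = .DENSITY_FLOOR) {
  s <- .as_sample(field, grid)
  .check_rho(s$rho)
  g2 <- rowSums(s$grad^2)
  f <- ifelse(s$rho > floor, g2 / pmax(s$rho, floor), 0)
  grid_integrate(f, grid)
}

#' Kinetic energy densities
#'
#' Positive-definite orbital form `t = sum_i |grad rho_i|^2 / (8 rho_i)
#' - (1/8) lap rho` (integrates to the non-interacting kinetic energy `T_S`)
#' and the Thomas-Fermi density `t_TF = c_K rho^{5/3}` with
#' `c_K = (3/10) (3 pi^2)^{2/3}`.
#'
#' @inheritParams shannon_entropy
#' @return object of class `"kinetic_densities"`: pointwise `t`, `t_tf`, and
#'   total `T_S` (hartree).
#' @export
kinetic_energy_densities <- function(field, grid, floor = .DENSITY_FLOOR) {
  s <- .as_sample(field, grid)
  if (is.null(s$orbital_rho)) {
    stop("field carries no orbital densities; the orbital kinetic energy ",
         "density t(r) requires them", call. = FALSE)
  }
  tw <- numeric(s$n_points)   # von Weizsaecker-type orbital sum
  for (o in s$orbital_rho) {
    g2 <- rowSums(o$grad^2)
    tw <- tw + ifelse(o$rho > floor, g2 / (8 * pmax(o$rho, floor)), 0)
  }
  t <- tw - s$laplacian / 8
  t_tf <- gbp_constants()$c_K * pmax(s$rho, 0)^(5 / 3)
  structure(list(t = t, t_tf = t_tf, T_S = grid_integrate(t, grid)),
            class = "kinetic_densities")
}

#' Constants of the Ghosh-Berkowitz-Parr entropy
#'
#' @return list with `c_K = (3/10)(3 pi^2)^{2/3}` and
#'   `c = 5/3 + ln(4 pi c_K / 3)`.
#' @export
gbp_constants <- function() {
  c_K <- (3 / 10) * (3 * pi^2)^(2 / 3)
  list(c_K = c_K, c = 5 / 3 + log(4 * pi * c_K / 3))
}

#' Ghosh-Berkowitz-Parr entropy
#'
#' `S_GBP = -Int (3/2) k rho [c + ln(t/t_TF)] dr` with `k = 1` in atomic
#' units (configurable).
#'
#' @inheritParams shannon_entropy
#' @param kd optional [kinetic_energy_densities()] result; computed from the
#'   field's orbital densities when `NULL`.
#' @param k Boltzmann constant in the working units (1 in a.u.).
#' @return entropy in atomic units.
#' @export
gbp_entropy <- function(field, kd = NULL, grid, k = 1,
                        floor = .DENSITY_FLOOR) {
  s <- .as_sample(field, grid)
  if (is.null(kd)) kd <- kinetic_energy_densities(s, grid, floor)
  stopifnot(inherits(kd, "kinetic_densities"))
  sig <- s$rho > 1e-8
  bad <- sig & kd$t <= 0
  if (any(bad)) {
    stop("non-positive kinetic energy density t(r) at ", sum(bad),
         " points of significant density", call. = FALSE)
  }
  cc <- gbp_constants()$c
  ok <- s$rho > floor & kd$t > 0 & kd$t_tf > 0
  f <- numeric(s$n_points)
  f[ok] <- -1.5 * k * s$rho[ok] * (cc + log(kd$t[ok] / kd$t_tf[ok]))
  grid_integrate(f, grid)
}

#' Onicescu information energy
#'
#' `E_n = 1/(n-1) Int rho^n dr` for n = 2, 3 (disequilibrium-type measure;
#' the 1/(n-1) prefactor is configurable).
#'
#' @inheritParams shannon_entropy
#' @param order n, 2 or 3.
#' @param prefactor multiplier of `Int rho^n`; default `1/(order - 1)`.
#' @return information energy in atomic units.
#' @export
onicescu_energy <- function(field, grid, order, prefactor = NULL) {
  if (!order %in% c(2, 3)) stop("unsupported order ", order,
                                "; supported orders are 2 and 3")
  s <- .as_sample(field, grid)
  .check_rho(s$rho)
  if (is.null(prefactor)) prefactor <- 1 / (order - 1)
  prefactor * grid_integrate(pmax(s$rho, 0)^order, grid)
}

#' Relative Renyi entropy of order n
#'
#' `R_n = 1/(1-n) log10 Int rho^n / rho0^{n-1} dr`; density and reference
#' must share the same normalization.
#'
#' @inheritParams shannon_entropy
#' @param ref_field reference density ([density_field()] or `field_sample`).
#' @param order n, 2 or 3.
#' @return relative Renyi entropy (log10 convention).
#' @export
relative_renyi <- function(field, ref_field, grid, order,
                           floor = .DENSITY_FLOOR) {
  if (!order %in% c(2, 3)) stop("unsupported order ", order,
                                "; supported orders are 2 and 3")
  s <- .as_sample(field, grid)
  r <- .as_sample(ref_field, grid)
  .check_rho(s$rho)
  if (any(s$rho > floor & r$rho < floor)) {
    warning("reference density below floor where the density is not; ",
            "floor applied (possible divergence)")
  }
  f <- ifelse(s$rho > floor,
              pmax(s$rho, 0)^order / pmax(r$rho, floor)^(order - 1), 0)
  (1 / (1 - order)) * log10(grid_integrate(f, grid))
}

#' Information gain (Kullback-Leibler divergence)
#'
#' `I_G = Int rho ln(rho/rho0) dr`; non-negative when the two densities
#' share normalization (Gibbs inequality).
#'
#' @inheritParams relative_renyi
#' @return information gain in atomic units.
#' @export
information_gain <- function(field, ref_field, grid,
                             floor = .DENSITY_FLOOR) {
  s <- .as_sample(field, grid)
  r <- .as_sample(ref_field, grid)
  .check_rho(s$rho)
  if (any(s$rho > floor & r$rho < floor)) {
    warning("reference density below floor where the density is not; ",
            "floor applied (possible divergence)")
  }
  f <- ifelse(s$rho > floor,
              s$rho * log(pmax(s$rho, floor) / pmax(r$rho, floor)), 0)
  grid_integrate(f, grid)
}

#' G1, G2, G3 density-deformation functionals
#'
#' Hirshfeld-atom sums
#' `G3 = sum_A Int rho_A [grad ln(rho_A/rho0_A)]^2 dr`,
#' `G1 = sum_A Int (lap rho_A) (rho_A/rho0_A) dr`,
#' `G2 = sum_A Int rho_A [lap rho_A / rho_A - lap rho0_A / rho0_A] dr`.
#' Because the stockholder ratio `rho_A/rho0_A = rho/P` (P the promolecule)
#' is atom-independent, the sums collapse exactly to molecular-level
#' integrals, which is how they are evaluated.
#'
#' @param partition a [hirshfeld_partition()].
#' @param grid the grid the partition was built on.
#' @param floor density floor for ratios and logarithms.
#' @return list with `G1`, `G2`, `G3` and per-atom `G3_atomic`.
#' @export
g_functions <- function(partition, grid, floor = .DENSITY_FLOOR) {
  stopifnot(inherits(partition, "hirshfeld_partition"))
  s <- partition$sample
  if (is.null(s$laplacian)) stop("field sample lacks Laplacian values")
  P <- partition$promolecule$rho
  ok <- s$rho > floor & P > floor
  ratio <- numeric(s$n_points)
  ratio[ok] <- s$rho[ok] / P[ok]
  # grad ln(rho/P) = grad rho / rho - grad P / P
  v <- matrix(0, s$n_points, 3)
  v[ok, ] <- s$grad[ok, , drop = FALSE] / s$rho[ok] -
    partition$promolecule$grad[ok, , drop = FALSE] / P[ok]
  v2 <- rowSums(v^2)
  G3_atomic <- as.numeric(crossprod(partition$atomic_rho * v2, grid$weights))
  G3 <- sum(G3_atomic)
  G1 <- grid_integrate(ratio * s$laplacian, grid)
  G2 <- grid_integrate(s$laplacian - ratio * partition$promolecule$laplacian,
                       grid)
  list(G1 = G1, G2 = G2, G3 = G3, G3_atomic = G3_atomic)
}

#' Compute the full 11-component ITA descriptor vector
#'
#' Evaluates, in the fixed canonical order of [ita_names()]: Shannon
#' entropy, Fisher information, GBP entropy, Onicescu energies E2/E3,
#' relative Renyi entropies of orders 2/3, information gain, and G1/G2/G3.
#' The promolecular reference is rescaled to the molecular electron count
#' before the relative entropies; the G functionals use the raw atomic
#' references.
#'
#' @param field a [density_field()] with orbital densities.
#' @param atoms an [atoms()] table.
#' @param ref a `"promolecular_reference"`.
#' @param grid a [build_molecular_grid()] object.
#' @param floor density floor.
#' @return named numeric vector of class `"ita_vector"`, length 11.
#' @export
compute_ita_vector <- function(field, atoms, ref, grid,
                               floor = .DENSITY_FLOOR) {
  s <- .as_sample(field, grid)
  step <- function(what, expr) {
    tryCatch(expr, error = function(e) {
      stop(what, ": ", conditionMessage(e), call. = FALSE)
    })
  }
  N <- grid_integrate(s$rho, grid)
  promol <- step("promolecule", build_promolecule(atoms, ref))
  promol_n <- step("reference normalization",
                   normalize_reference(promol, N, grid))
  ref_s <- evaluate_field(promol_n, grid)
  part <- step("G1/G2/G3 (Hirshfeld partition)",
               hirshfeld_partition(s, atoms, ref, grid))
  g <- step("G1/G2/G3", g_functions(part, grid, floor))
  kd <- step("S_GBP (kinetic energy densities)",
             kinetic_energy_densities(s, grid, floor))
  out <- c(
    S_S = step("S_S", shannon_entropy(s, grid, floor)),
    I_F = step("I_F", fisher_information(s, grid, floor)),
    S_GBP = step("S_GBP", gbp_entropy(s, kd, grid, floor = floor)),
    E2 = step("E2", onicescu_energy(s, grid, 2)),
    E3 = step("E3", onicescu_energy(s, grid, 3)),
    rR2 = step("rR2", relative_renyi(s, ref_s, grid, 2, floor)),
    rR3 = step("rR3", relative_renyi(s, ref_s, grid, 3, floor)),
    I_G = step("I_G", information_gain(s, ref_s, grid, floor)),
    G1 = g$G1, G2 = g$G2, G3 = g$G3)
  class(out) <- "ita_vector"
  out
}

#' @export
print.ita_vector <- function(x, digits = 6, ...) {
  cat("ITA descriptor vector (atomic units):\n")
  print(signif(unclass(x), digits))
  invisible(x)
}
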