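## Multicenter quadrature over all space.
##
## Per atom: Gauss-Chebyshev (2nd kind) radial nodes mapped onto [0, Inf) by
## the rational transformation r = r_m (1 + x) / (1 - x) with an
## element-dependent scale r_m from Bragg-Slater radii, crossed with a
## Gauss-Legendre (cos theta) x uniform-phi angular product rule.  Atomic
## grids are glued by Becke's smooth multicenter partition (3 polynomial
## smoothing iterations), which is folded into the quadrature weights.

# Gauss-Legendre nodes/weights on [-1, 1] by Golub-Welsch.
.gauss_legendre <- function(n) {
  if (n == 1L) return(list(x = 0, w = 2))
  i <- seq_len(n - 1)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- b
  J[cbind(i + 1, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  x <- e$values
  w <- 2 * e$vectors[1, ]^2
  ord <- order(x)
  list(x = x[ord], w = w[ord])
}

.valid_angular_sizes <- function(kmax = 20L) 2L * seq_len(kmax)^2

# Angular product rule with N = 2 k^2 points: k Gauss-Legendre nodes in
# cos(theta), 2k uniform nodes in phi.  Weights sum to 4*pi.
.angular_grid <- function(n_angular) {
  k <- sqrt(n_angular / 2)
  if (k != round(k) || k < 1) {
    stop("unsupported angular size ", n_angular,
         "; valid sizes are 2*k^2: ",
         paste(.valid_angular_sizes(12L), collapse = ", "), ", ...",
         call. = FALSE)
  }
  k <- as.integer(round(k))
  gl <- .gauss_legendre(k)
  nphi <- 2L * k
  phi <- 2 * pi * (seq_len(nphi) - 0.5) / nphi
  ct <- rep(gl$x, each = nphi)
  st <- sqrt(pmax(0, 1 - ct^2))
  dirs <- cbind(st * cos(phi), st * sin(phi), ct)
  w <- rep(gl$w, each = nphi) * (2 * pi / nphi)
  list(dirs = dirs, w = w)
}

# Radial rule for integrals \int_0^Inf f(r) r^2 dr.
.radial_grid <- function(n, r_m) {
  i <- seq_len(n)
  theta <- i * pi / (n + 1)
  x <- cos(theta)
  # Gauss-Chebyshev 2: \int_{-1}^{1} h(x) dx ~ sum (pi/(n+1)) sin(theta) h(x)
  w_x <- (pi / (n + 1)) * sin(theta)
  r <- r_m * (1 + x) / (1 - x)
  jac <- 2 * r_m / (1 - x)^2
  list(r = r, w = w_x * jac * r^2)
}

.becke_smooth <- function(mu, iterations = 3L) {
  f <- mu
  for (i in seq_len(iterations)) f <- 1.5 * f - 0.5 * f^3
  0.5 * (1 - f)
}

# Becke multicenter partition weights for points owned by atom `a`.
.becke_weights <- function(points, positions, a, iterations = 3L) {
  n_at <- nrow(positions)
  if (n_at == 1L) return(rep(1, nrow(points)))
  npt <- nrow(points)
  d <- matrix(0, npt, n_at) # distances point -> atom
  for (b in seq_len(n_at)) {
    d[, b] <- sqrt(rowSums((points - matrix(positions[b, ], npt, 3,
                                            byrow = TRUE))^2))
  }
  P <- matrix(1, npt, n_at)
  for (i in seq_len(n_at - 1)) {
    for (j in seq((i + 1), n_at)) {
      Rij <- sqrt(sum((positions[i, ] - positions[j, ])^2))
      mu <- (d[, i] - d[, j]) / Rij
      s <- .becke_smooth(mu, iterations)
      P[, i] <- P[, i] * s
      P[, j] <- P[, j] * (1 - s)
    }
  }
  P[, a] / rowSums(P)
}

#' Build a multicenter molecular quadrature grid
#'
#' Atom-centered radial x angular product grids with Becke's smooth
#' multicenter partition folded into the quadrature weights, so that
#' `sum(values * weights)` approximates an all-space integral.
#'
#' @param atoms an [atoms()] table.
#' @param radial_points radial nodes per atom (default 75).
#' @param angular_points angular nodes per radial shell; must be `2*k^2` for
#'   integer `k` (default 288).  The coarse preset used by fast tests is
#'   `radial_points = 30, angular_points = 98`.
#' @param becke_iterations smoothing iterations of the Becke cell polynomial.
#' @return an object of class `"molecular_grid"`: list with `points`
#'   (n x 3, bohr), `weights` (bohr^3), `atom_of_point`.
#' @examples
#' g <- build_molecular_grid(atoms("H", matrix(0, 1, 3)), 30, 98)
#' f <- gaussian_density(1, 1, c(0, 0, 0))
#' grid_integrate(evaluate_field(f, g)$rho, g)  # ~ 1
#' @export
build_molecular_grid <- function(atoms, radial_points = 75L,
                                 angular_points = 288L,
                                 becke_iterations = 3L) {
  stopifnot(inherits(atoms, "atoms"), nrow(atoms) >= 1)
  ang <- .angular_grid(angular_points)
  positions <- .atom_positions(atoms)
  rm_bohr <- .element_row(atoms$element)$bragg_slater * .BOHR_PER_ANGSTROM
  # customary halving of the Bragg-Slater scale except for hydrogen
  r_m <- ifelse(atoms$element == "H", rm_bohr, rm_bohr / 2)

  pts_list <- vector("list", nrow(atoms))
  w_list <- vector("list", nrow(atoms))
  own_list <- vector("list", nrow(atoms))
  for (a in seq_len(nrow(atoms))) {
    rad <- .radial_grid(radial_points, r_m[a])
    # outer product radial x angular
    npt <- radial_points * nrow(ang$dirs)
    r_rep <- rep(rad$r, each = nrow(ang$dirs))
    dirs_rep <- ang$dirs[rep(seq_len(nrow(ang$dirs)), radial_points), ,
                         drop = FALSE]
    pts <- dirs_rep * r_rep
    pts <- sweep(pts, 2, positions[a, ], "+")
    w <- rep(rad$w, each = nrow(ang$dirs)) * rep(ang$w, radial_points)
    w <- w * .becke_weights(pts, positions, a, becke_iterations)
    pts_list[[a]] <- pts
    w_list[[a]] <- w
    own_list[[a]] <- rep(a, npt)
  }
  out <- list(points = do.call(rbind, pts_list),
              weights = do.call(c, w_list),
              atom_of_point = do.call(c, own_list),
              radial_points = as.integer(radial_points),
              angular_points = as.integer(angular_points))
  class(out) <- "molecular_grid"
  out
}

#' @export
print.molecular_grid <- function(x, ...) {
  cat("<molecular_grid> ", length(x$weights), " points (",
      x$radial_points, " radial x ", x$angular_points, " angular x ",
      max(x$atom_of_point), " centers)\n", sep = "")
  invisible(x)
}

#' Quadrature of a sampled scalar field
#'
#' @param values numeric vector of integrand samples at the grid points.
#' @param grid a [build_molecular_grid()] object.
#' @return the quadrature sum `sum(values * weights)`.
#' @export
grid_integrate <- function(values, grid) {
  stopifnot(inherits(grid, "molecular_grid"))
  if (length(values) != length(grid$weights)) {
    stop("length(values) [", length(values),
         "] does not match the number of grid points [",
         length(grid$weights), "]", call. = FALSE)
  }
  sum(values * grid$weights)
}
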