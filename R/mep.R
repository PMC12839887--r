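## Molecular electrostatic potential (MEP) at a nucleus and carbonyl-oxygen
## identification.  V(R_A) = sum_{B != A} Z_B / |R_A - R_B|
##                           - Int rho(r) / |r - R_A| dr,
## with the self-nucleus term excluded.  The 1/|r - R_A| singularity is
## integrable (the radial metric supplies r^2) and is resolved by the
## atom-centered radial shells of the quadrature grid.

#' Electrostatic potential at an arbitrary point
#'
#' @param atoms an [atoms()] table (nuclear charges used as point charges).
#' @param field a [density_field()] or `field_sample`, or `NULL` for a
#'   nuclei-only potential.
#' @param grid quadrature grid (must sample near `point` for accuracy).
#' @param point 3-vector, bohr.
#' @param exclude_atom optional atom index whose nuclear term is skipped.
#' @return potential in atomic units (hartree per unit charge).
#' @export
mep_at_point <- function(atoms, field, grid, point, exclude_atom = NA) {
  stopifnot(inherits(atoms, "atoms"))
  point <- as.numeric(point)
  centers <- .atom_positions(atoms)
  dn <- sqrt(rowSums(sweep(centers, 2, point, "-")^2))
  keep <- seq_len(nrow(atoms))
  if (!is.na(exclude_atom)) keep <- setdiff(keep, exclude_atom)
  if (any(dn[keep] < 1e-10)) stop("a non-excluded nucleus coincides with ",
                                  "the probe point")
  v_nuc <- sum(atoms$Z[keep] / dn[keep])
  v_el <- 0
  if (!is.null(field)) {
    s <- .as_sample(field, grid)
    r <- sqrt(rowSums(sweep(grid$points, 2, point, "-")^2))
    if (min(r) > 0.1) {
      warning("no grid point within 0.1 bohr of the probe; the electronic ",
              "integral may be inaccurate")
    }
    v_el <- grid_integrate(s$rho / pmax(r, 1e-14), grid)
  }
  v_nuc - v_el
}

#' MEP at a nucleus
#'
#' Evaluates the molecular electrostatic potential at the position of atom
#' `target_atom_index`, excluding that nucleus' own (singular) term.
#'
#' @inheritParams mep_at_point
#' @param target_atom_index index of the probe atom.
#' @return potential in atomic units.
#' @export
mep_at_nucleus <- function(atoms, field, grid, target_atom_index) {
  i <- as.integer(target_atom_index)
  if (i < 1 || i > nrow(atoms)) stop("target atom index out of range")
  mep_at_point(atoms, field, grid,
               as.numeric(.atom_positions(atoms)[i, ]), exclude_atom = i)
}

.bond_matrix <- function(atoms, scale = 1.15) {
  pos <- .atom_positions(atoms)
  n <- nrow(pos)
  d <- as.matrix(stats::dist(pos))
  rcov <- .element_row(atoms$element)$covalent * .BOHR_PER_ANGSTROM
  cutoff <- outer(rcov, rcov, "+") * scale
  bonded <- d < cutoff & d > 1e-8
  diag(bonded) <- FALSE
  list(bonded = bonded, dist = d)
}

#' Identify the two carbonyl oxygens of a quinone scaffold
#'
#' Bond perception by a covalent-radius distance criterion (sum of covalent
#' radii times `scale`); carbonyl oxygens are those bonded to exactly one
#' atom, that atom being a carbon.  Ether/hydroxyl oxygens are excluded by
#' the bond-count rule.
#'
#' @param atoms an [atoms()] table (positions in bohr).
#' @param dist_matrix optional precomputed distance matrix (bohr);
#'   recomputed from positions when `NULL`.
#' @param scale covalent-radius scale factor for bonding (default 1.15).
#' @return integer vector `c(O1, O2)`, O1 the lower atom index.
#' @export
identify_carbonyl_oxygens <- function(atoms, dist_matrix = NULL,
                                      scale = 1.15) {
  stopifnot(inherits(atoms, "atoms"))
  bm <- .bond_matrix(atoms, scale)
  if (!is.null(dist_matrix)) {
    rcov <- .element_row(atoms$element)$covalent * .BOHR_PER_ANGSTROM
    cutoff <- outer(rcov, rcov, "+") * scale
    bm$bonded <- dist_matrix < cutoff & dist_matrix > 1e-8
    diag(bm$bonded) <- FALSE
    bm$dist <- dist_matrix
  }
  ox <- which(atoms$element == "O")
  cand <- ox[vapply(ox, function(i) {
    nb <- which(bm$bonded[i, ])
    length(nb) == 1L && atoms$element[nb] == "C"
  }, TRUE)]
  if (length(cand) < 2L) {
    stop("fewer than two carbonyl-type oxygens found; oxygens present at ",
         "indices: ", paste(ox, collapse = ", "), call. = FALSE)
  }
  if (length(cand) > 2L) {
    # prefer the two shortest C=O contacts
    dCO <- vapply(cand, function(i) min(bm$dist[i, bm$bonded[i, ]]), 0)
    cand <- cand[order(dCO)[1:2]]
    warning("more than two carbonyl-type oxygens; selected the two with ",
            "the shortest C=O distances")
  }
  sort(as.integer(cand))
}

#' Assemble one descriptor row
#'
#' Joins the 11 ITA quantities with HOMO/LUMO energies and the MEP at the
#' two carbonyl oxygens; `mep_o_avg` is defined as their arithmetic mean.
#' The valence-NAO energy sum `sum_nao_o` is ingested, never computed.
#'
#' @param molecule_id identifier string.
#' @param family one of `"BQ"`, `"NQ"`, `"AQ"`, `"misc"`, `"non-quinone"`.
#' @param ita an `"ita_vector"` (length 11).
#' @param homo,lumo orbital energies, hartree.
#' @param mep_o1,mep_o2 MEP at the two carbonyl oxygen nuclei, a.u.
#' @param sum_nao_o ingested NAO energy sum (hartree) or `NA`.
#' @param q1_mv,q2_mv experimental redox potentials (mV vs SCE) or `NA`.
#' @param sigma_p Hammett constant or `NA`.
#' @return one-row data frame following the descriptor-table schema, plus
#'   `mep_o_avg`.
#' @export
descriptor_row <- function(molecule_id, family, ita, homo, lumo,
                           mep_o1, mep_o2, sum_nao_o = NA_real_,
                           q1_mv = NA_real_, q2_mv = NA_real_,
                           sigma_p = NA_real_) {
  stopifnot(length(ita) == 11L, identical(names(ita), ita_names()))
  out <- data.frame(molecule_id = as.character(molecule_id),
                    family = family, t(unclass(ita)),
                    homo = homo, lumo = lumo,
                    mep_o1 = mep_o1, mep_o2 = mep_o2,
                    mep_o_avg = (mep_o1 + mep_o2) / 2,
                    sum_nao_o = sum_nao_o,
                    q1_mv = q1_mv, q2_mv = q2_mv, sigma_p = sigma_p,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
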