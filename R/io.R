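## File formats: Gaussian cube (bohr, standard counts+origin header), XYZ
## (angstrom, converted to bohr on read), and the descriptor/label CSV
## schema.  Missing labels are explicit NA (empty CSV cells), never 0.

#' Read a Gaussian cube file
#'
#' @param path file path.
#' @return list with `comments` (2 lines), `atoms` ([atoms()] table),
#'   `origin` (bohr), `axes` (3 x 3 step-vector matrix, rows = axes),
#'   `dims` (3 integers), `values` (array dims `dims`, fastest index = 3rd
#'   axis as in the format).
#' @export
read_cube <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 7) stop("malformed cube file (line 3): truncated header")
  comments <- lines[1:2]
  hdr <- scan(text = lines[3], quiet = TRUE)
  if (length(hdr) < 4) stop("malformed cube header (line 3)")
  natoms <- as.integer(hdr[1])
  if (natoms < 0) natoms <- -natoms  # orbital-id variant; ids unused here
  origin <- hdr[2:4]
  axes <- matrix(0, 3, 3)
  dims <- integer(3)
  for (i in 1:3) {
    v <- scan(text = lines[3 + i], quiet = TRUE)
    if (length(v) < 4) stop("malformed cube header (line ", 3 + i, ")")
    dims[i] <- as.integer(v[1])
    axes[i, ] <- v[2:4]
  }
  if (any(dims < 1)) stop("malformed cube header: non-positive grid counts")
  at <- matrix(scan(text = lines[7:(6 + natoms)], quiet = TRUE),
               ncol = 5, byrow = TRUE)
  a <- atoms(.element_symbol(as.integer(at[, 1])), at[, 3:5],
             Z = as.integer(at[, 1]))
  vals <- scan(text = lines[(7 + natoms):length(lines)], quiet = TRUE)
  if (length(vals) != prod(dims)) {
    stop("cube value count ", length(vals), " does not match grid ",
         paste(dims, collapse = "x"))
  }
  # file order: axis-1 slowest, axis-3 fastest
  values <- aperm(array(vals, dim = rev(dims)), 3:1)
  list(comments = comments, atoms = a, origin = origin, axes = axes,
       dims = dims, values = values)
}

#' Write a Gaussian cube file
#'
#' Values are written with 16 significant digits so a write/read round trip
#' is lossless to better than 1e-12 relative.
#'
#' @param cube a list as returned by [read_cube()].
#' @param path output path.
#' @export
write_cube <- function(cube, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(cube$comments[1:2], con)
  writeLines(sprintf("%5d %23.15E %23.15E %23.15E", nrow(cube$atoms),
                     cube$origin[1], cube$origin[2], cube$origin[3]), con)
  for (i in 1:3) {
    writeLines(sprintf("%5d %23.15E %23.15E %23.15E", cube$dims[i],
                       cube$axes[i, 1], cube$axes[i, 2], cube$axes[i, 3]),
               con)
  }
  pos <- .atom_positions(cube$atoms)
  for (a in seq_len(nrow(cube$atoms))) {
    writeLines(sprintf("%5d %23.15E %23.15E %23.15E %23.15E",
                       cube$atoms$Z[a], as.numeric(cube$atoms$Z[a]),
                       pos[a, 1], pos[a, 2], pos[a, 3]), con)
  }
  v <- as.vector(aperm(cube$values, 3:1))
  full <- length(v) %/% 6L
  if (full > 0) {
    m <- matrix(v[seq_len(full * 6L)], ncol = 6, byrow = TRUE)
    writeLines(apply(m, 1, function(r) paste(sprintf("%23.15E", r),
                                             collapse = " ")), con)
  }
  if (length(v) > full * 6L) {
    writeLines(paste(sprintf("%23.15E", v[(full * 6L + 1):length(v)]),
                     collapse = " "), con)
  }
  invisible(path)
}

#' Integrate a cube's scalar field
#'
#' Lattice sum with the voxel volume as uniform quadrature weight.
#'
#' @param cube a [read_cube()] list.
#' @return the integral estimate.
#' @export
cube_integrate <- function(cube) {
  vol <- abs(det(cube$axes))
  sum(cube$values) * vol
}

#' Cube lattice points
#' @param cube a [read_cube()] list.
#' @return matrix (prod(dims) x 3) of lattice points, bohr, in the cube's
#'   storage order.
#' @export
cube_points <- function(cube) {
  idx <- as.matrix(expand.grid(i3 = seq_len(cube$dims[3]) - 1,
                               i2 = seq_len(cube$dims[2]) - 1,
                               i1 = seq_len(cube$dims[1]) - 1))
  pts <- idx[, c("i1", "i2", "i3")] %*% cube$axes
  sweep(pts, 2, cube$origin, "+")
}

#' Sample a cube as a scalar field with finite-difference derivatives
#'
#' Central differences on the lattice supply gradient and Laplacian (one-
#' sided at the boundary is avoided by zero-padding assumptions; the outer
#' layer is simply copied, adequate when the density has decayed there).
#'
#' @param cube a [read_cube()] list with orthogonal axes.
#' @return a `field_sample` whose point order matches [cube_points()].
#' @export
cube_to_sample <- function(cube) {
  h <- sqrt(rowSums(cube$axes^2))
  if (max(abs(cube$axes[upper.tri(cube$axes)]),
          abs(cube$axes[lower.tri(cube$axes)])) > 1e-10) {
    stop("finite-difference sampling requires axis-aligned cube vectors")
  }
  v <- cube$values
  d <- dim(v)
  shift <- function(arr, axis, by) {
    idx <- lapply(d, seq_len)
    i <- pmin(pmax(idx[[axis]] + by, 1L), d[axis])
    idx[[axis]] <- i
    do.call(`[`, c(list(arr), idx))
  }
  g <- lapply(1:3, function(ax) (shift(v, ax, 1L) - shift(v, ax, -1L)) /
                (2 * h[ax]))
  lap <- Reduce(`+`, lapply(1:3, function(ax) {
    (shift(v, ax, 1L) - 2 * v + shift(v, ax, -1L)) / h[ax]^2
  }))
  flat <- function(a) as.vector(aperm(a, 3:1))
  structure(list(rho = flat(v),
                 grad = cbind(flat(g[[1]]), flat(g[[2]]), flat(g[[3]])),
                 laplacian = flat(lap), orbital_rho = NULL,
                 n_electrons = cube_integrate(cube),
                 n_points = prod(d)),
            class = "field_sample")
}

#' Read an XYZ geometry (angstrom; converted to bohr)
#'
#' @param path file path.
#' @return an [atoms()] table, positions in bohr.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n)) stop("malformed XYZ header (line 1): atom count expected")
  if (length(lines) < n + 2) stop("XYZ file truncated")
  parts <- strsplit(trimws(lines[3:(2 + n)]), "\\s+")
  sym <- vapply(parts, `[[`, "", 1)
  xyz <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
  atoms(sym, xyz * .BOHR_PER_ANGSTROM)
}

.DESCRIPTOR_COLUMNS <- c("molecule_id", "family", "S_S", "I_F", "S_GBP",
                         "E2", "E3", "rR2", "rR3", "I_G", "G1", "G2", "G3",
                         "homo", "lumo", "mep_o1", "mep_o2", "sum_nao_o",
                         "q1_mv", "q2_mv", "sigma_p")

#' Feature columns of the 13-dimensional model input
#' @return character vector: the 11 ITA names plus `homo`, `lumo`.
#' @export
feature_names <- function() c(ita_names(), "homo", "lumo")

#' Write a descriptor/label table as CSV
#'
#' Missing labels become empty cells.  Column order follows the documented
#' schema; extra columns (e.g. `mep_o_avg`) are dropped.
#'
#' @param table data frame with the schema columns.
#' @param path output path.
#' @export
write_descriptor_table <- function(table, path) {
  missing_cols <- setdiff(.DESCRIPTOR_COLUMNS, names(table))
  if (length(missing_cols)) {
    stop("table lacks schema columns: ", paste(missing_cols, collapse = ", "))
  }
  utils::write.csv(table[, .DESCRIPTOR_COLUMNS], path, row.names = FALSE,
                   na = "")
  invisible(path)
}

#' Read a descriptor/label table from CSV
#'
#' @param path CSV path following the documented schema.
#' @return data frame; empty label cells become `NA` (the missingness mask
#'   is `is.na()` on the label columns).
#' @export
read_descriptor_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(molecule_id = "character"))
  missing_cols <- setdiff(.DESCRIPTOR_COLUMNS, names(tab))
  if (length(missing_cols)) {
    stop("CSV lacks schema columns: ", paste(missing_cols, collapse = ", "))
  }
  tab
}
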