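#' Molecular geometry
#'
#' A geometry holds element symbols, Cartesian coordinates (bohr, length 3N)
#' and per-atom masses (electron-mass units).  Masses default to standard
#' atomic weights.
#'
#' @param symbols character vector of element symbols
#' @param coords numeric vector of length 3N, Cartesian positions in bohr
#' @param masses optional per-atom masses in electron-mass units
#' @return an object of class `pq_geometry`
#' @export
geometry <- function(symbols, coords, masses = NULL) {
  n <- length(symbols)
  if (n < 1) stop("geometry needs at least one atom")
  coords <- as.numeric(coords)
  if (length(coords) != 3 * n)
    stop("coords must have length 3 * n_atoms = ", 3 * n)
  if (is.null(masses)) masses <- atomic_mass_me(symbols)
  if (length(masses) != n || any(masses <= 0))
    stop("masses must be ", n, " positive values")
  structure(list(symbols = symbols, coords = coords, masses = masses),
            class = "pq_geometry")
}

#' @export
print.pq_geometry <- function(x, ...) {
  cat("<pq_geometry> ", n_atoms(x), " atoms (",
      paste(x$symbols, collapse = " "), ")\n", sep = "")
  m <- coord_matrix(x)
  dimnames(m) <- list(x$symbols, c("x", "y", "z"))
  print(round(m, 6))
  invisible(x)
}

#' Number of atoms in a geometry
#' @param geom a `pq_geometry`
#' @export
n_atoms <- function(geom) length(geom$symbols)

#' Coordinates as an N x 3 matrix (bohr)
#' @param geom a `pq_geometry`
#' @export
coord_matrix <- function(geom) matrix(geom$coords, ncol = 3, byrow = TRUE)

set_coords <- function(geom, coords) {
  geom$coords <- as.numeric(coords)
  geom
}

#' Centre of mass of a geometry (bohr)
#' @param geom a `pq_geometry`
#' @export
centre_of_mass <- function(geom) {
  m <- coord_matrix(geom)
  colSums(m * geom$masses) / sum(geom$masses)
}

#' Apply a rigid rotation (and optional translation) to a geometry
#' @param geom a `pq_geometry`
#' @param rot 3 x 3 rotation matrix
#' @param shift optional length-3 translation (bohr)
#' @export
rotate_geometry <- function(geom, rot, shift = c(0, 0, 0)) {
  m <- coord_matrix(geom) %*% t(rot)
  m <- sweep(m, 2, -shift)
  set_coords(geom, as.numeric(t(m)))
}

#' Distance between two atoms (bohr)
#' @param geom a `pq_geometry`
#' @param i,j atom indices
#' @export
atom_distance <- function(geom, i, j) {
  m <- coord_matrix(geom)
  sqrt(sum((m[i, ] - m[j, ])^2))
}

#' O-O distance of a two-water geometry (bohr)
#' @param geom a `pq_geometry` containing exactly two oxygen atoms
#' @export
r_oo <- function(geom) {
  io <- which(geom$symbols == "O")
  if (length(io) != 2) stop("geometry does not contain exactly 2 O atoms")
  atom_distance(geom, io[1], io[2])
}

#' Partition a two-water geometry into monomer fragments
#'
#' Each hydrogen is assigned to its nearest oxygen.  The assignment must
#' yield exactly two H per O; geometries where a hydrogen is (numerically)
#' equidistant from both oxygens, or where an oxygen would not receive two
#' hydrogens, raise an error naming the offending atoms.
#'
#' @param geom a `pq_geometry` with 2 O and 4 H atoms
#' @param tol relative tolerance for declaring an H equidistant
#' @return list of two `pq_geometry` fragments (each O H H), plus an
#'   `index` attribute giving original atom indices per fragment
#' @export
fragment_partition <- function(geom, tol = 1e-6) {
  io <- which(geom$symbols == "O")
  ih <- which(geom$symbols == "H")
  if (length(io) != 2 || length(ih) != 4)
    stop("fragment_partition expects 2 O and 4 H atoms")
  m <- coord_matrix(geom)
  assign <- integer(4)
  for (k in seq_along(ih)) {
    d <- c(sqrt(sum((m[ih[k], ] - m[io[1], ])^2)),
           sqrt(sum((m[ih[k], ] - m[io[2], ])^2)))
    if (abs(d[1] - d[2]) <= tol * mean(d))
      stop("ambiguous fragment assignment: H atom ", ih[k],
           " is equidistant from O atoms ", io[1], " and ", io[2])
    assign[k] <- which.min(d)
  }
  if (any(tabulate(assign, 2) != 2)) {
    bad <- which(tabulate(assign, 2) != 2)
    stop("ambiguous fragment assignment: O atom ", io[bad[1]],
         " has ", sum(assign == bad[1]), " nearest hydrogens (need 2)")
  }
  frags <- lapply(1:2, function(f) {
    idx <- c(io[f], ih[assign == f])
    sel <- as.numeric(t(m[idx, , drop = FALSE]))
    g <- geometry(geom$symbols[idx], sel, geom$masses[idx])
    attr(g, "index") <- idx
    g
  })
  frags
}

#' Read geometries from an XYZ file (angstrom)
#'
#' @param path file path
#' @return a list of `pq_geometry` frames (length 1 for a single-frame file)
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  frames <- list()
  i <- 1
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1; next }
    n <- as.integer(trimws(lines[i]))
    block <- lines[(i + 2):(i + 1 + n)]
    toks <- strsplit(trimws(block), "[[:space:]]+")
    sym <- vapply(toks, `[`, "", 1)
    xyz <- t(vapply(toks, function(t) as.numeric(t[2:4]), numeric(3)))
    frames[[length(frames) + 1]] <-
      geometry(sym, angstrom_to_bohr(as.numeric(t(xyz))))
    i <- i + 2 + n
  }
  frames
}

#' Write geometries to an XYZ file (angstrom)
#'
#' @param geoms a `pq_geometry` or list of them
#' @param path file path
#' @param comments per-frame comment lines
#' @export
write_xyz <- function(geoms, path, comments = NULL) {
  if (inherits(geoms, "pq_geometry")) geoms <- list(geoms)
  if (is.null(comments)) comments <- rep("", length(geoms))
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_along(geoms)) {
    g <- geoms[[f]]
    writeLines(c(as.character(n_atoms(g)), comments[[f]]), con)
    m <- bohr_to_angstrom(coord_matrix(g))
    writeLines(sprintf("%-2s %18.10f %18.10f %18.10f",
                       g$symbols, m[, 1], m[, 2], m[, 3]), con)
  }
  invisible(path)
}
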