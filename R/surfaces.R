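#' Potential-energy surface contract
#'
#' A potential surface is a callable pair: `energy(geom)` returning hartree
#' and optionally `gradient(geom)` returning a 3N vector in hartree/bohr.
#' When no analytic gradient is supplied, [evaluate_gradient()] falls back
#' to central finite differences.
#'
#' @param energy function of a `pq_geometry` returning a scalar (hartree)
#' @param gradient optional function returning the 3N gradient
#' @param label short description
#' @return an object of class `pq_potential`
#' @export
potential_surface <- function(energy, gradient = NULL, label = "custom") {
  stopifnot(is.function(energy), is.null(gradient) || is.function(gradient))
  structure(list(energy = energy, gradient = gradient, label = label),
            class = "pq_potential")
}

#' @export
print.pq_potential <- function(x, ...) {
  cat("<pq_potential> ", x$label,
      if (is.null(x$gradient)) " (finite-difference gradient)" else
        " (analytic gradient)", "\n", sep = "")
  invisible(x)
}

#' Dipole-moment surface contract
#'
#' @param dipole function of a `pq_geometry` returning a 3-vector (e bohr)
#' @param jacobian optional function returning the 3 x 3N jacobian
#' @param label short description
#' @return an object of class `pq_dipole`
#' @export
dipole_surface <- function(dipole, jacobian = NULL, label = "custom") {
  stopifnot(is.function(dipole), is.null(jacobian) || is.function(jacobian))
  structure(list(dipole = dipole, jacobian = jacobian, label = label),
            class = "pq_dipole")
}

#' Evaluate a potential surface
#'
#' @param surface a `pq_potential`
#' @param geom a `pq_geometry`
#' @return potential energy in hartree
#' @export
evaluate_potential <- function(surface, geom) {
  e <- surface$energy(geom)
  if (!is.finite(e)) {
    cond <- simpleError(paste0("surface evaluation returned a non-finite ",
                               "energy (", surface$label, ")"))
    cond$geometry <- geom
    stop(cond)
  }
  e
}

#' Evaluate (or finite-difference) the gradient of a potential surface
#'
#' @param surface a `pq_potential`
#' @param geom a `pq_geometry`
#' @param fd_step central-difference step in bohr, used when the surface
#'   carries no analytic gradient
#' @return 3N gradient in hartree/bohr
#' @export
evaluate_gradient <- function(surface, geom, fd_step = 1e-4) {
  if (!is.null(surface$gradient)) return(surface$gradient(geom))
  stopifnot(fd_step > 0)
  x <- geom$coords
  g <- numeric(length(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- x[i] + fd_step
    xm <- x; xm[i] <- x[i] - fd_step
    g[i] <- (evaluate_potential(surface, set_coords(geom, xp)) -
             evaluate_potential(surface, set_coords(geom, xm))) /
      (2 * fd_step)
  }
  g
}

#' Evaluate a dipole surface
#'
#' @param dms a `pq_dipole`
#' @param geom a `pq_geometry`
#' @return dipole 3-vector in e bohr
#' @export
evaluate_dipole <- function(dms, geom) {
  mu <- dms$dipole(geom)
  if (length(mu) != 3 || !all(is.finite(mu)))
    stop("dipole surface must return a finite 3-vector")
  as.numeric(mu)
}

#' Evaluate (or finite-difference) the dipole jacobian
#'
#' @param dms a `pq_dipole`
#' @param geom a `pq_geometry`
#' @param fd_step central-difference step in bohr
#' @return 3 x 3N jacobian matrix
#' @export
evaluate_dipole_jacobian <- function(dms, geom, fd_step = 1e-4) {
  if (!is.null(dms$jacobian)) return(dms$jacobian(geom))
  x <- geom$coords
  J <- matrix(0, 3, length(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- x[i] + fd_step
    xm <- x; xm[i] <- x[i] - fd_step
    J[, i] <- (evaluate_dipole(dms, set_coords(geom, xp)) -
               evaluate_dipole(dms, set_coords(geom, xm))) / (2 * fd_step)
  }
  J
}

#' Assemble a many-body surface from monomer and pair terms
#'
#' Builds the 2-fragment many-body expansion: total energy is the sum of the
#' 1-body terms evaluated on each fragment plus the 2-body term evaluated on
#' the full geometry; the dipole likewise.  The pair terms must vanish as
#' the fragments separate.
#'
#' @param monomers list (one per fragment) of lists with elements
#'   `potential` (`pq_potential`) and optionally `dipole` (`pq_dipole`)
#' @param pair_potential `pq_potential` for the 2-body energy over the full
#'   geometry (may be `NULL` for non-interacting fragments)
#' @param pair_dipole optional `pq_dipole` 2-body dipole term
#' @param fragment_index integer vector mapping each atom to its fragment
#' @return list with composite `potential` and `dipole` surfaces
#' @export
assemble_many_body <- function(monomers, pair_potential = NULL,
                               pair_dipole = NULL, fragment_index) {
  nfrag <- length(monomers)
  stopifnot(nfrag >= 1, all(sort(unique(fragment_index)) == seq_len(nfrag)))
  split_geom <- function(geom) {
    if (length(fragment_index) != n_atoms(geom))
      stop("fragment_index covers ", length(fragment_index),
           " atoms but geometry has ", n_atoms(geom))
    m <- coord_matrix(geom)
    lapply(seq_len(nfrag), function(f) {
      idx <- which(fragment_index == f)
      geometry(geom$symbols[idx], as.numeric(t(m[idx, , drop = FALSE])),
               geom$masses[idx])
    })
  }
  energy <- function(geom) {
    frags <- split_geom(geom)
    e <- sum(vapply(seq_len(nfrag), function(f)
      evaluate_potential(monomers[[f]]$potential, frags[[f]]), 0))
    if (!is.null(pair_potential))
      e <- e + evaluate_potential(pair_potential, geom)
    e
  }
  gradient <- NULL
  if (all(vapply(monomers, function(m) !is.null(m$potential$gradient),
                 TRUE)) &&
      (is.null(pair_potential) || !is.null(pair_potential$gradient))) {
    gradient <- function(geom) {
      frags <- split_geom(geom)
      g <- numeric(3 * n_atoms(geom))
      for (f in seq_len(nfrag)) {
        idx <- which(fragment_index == f)
        cols <- as.numeric(t(outer(idx - 1, 1:3, function(a, b) 3 * a + b)))
        g[cols] <- g[cols] +
          evaluate_gradient(monomers[[f]]$potential, frags[[f]])
      }
      if (!is.null(pair_potential))
        g <- g + evaluate_gradient(pair_potential, geom)
      g
    }
  }
  dipole <- NULL
  if (all(vapply(monomers, function(m) !is.null(m$dipole), TRUE))) {
    dipfun <- function(geom) {
      frags <- split_geom(geom)
      mu <- Reduce(`+`, lapply(seq_len(nfrag), function(f)
        evaluate_dipole(monomers[[f]]$dipole, frags[[f]])))
      if (!is.null(pair_dipole))
        mu <- mu + evaluate_dipole(pair_dipole, geom)
      mu
    }
    dipole <- dipole_surface(dipfun, label = "many-body dipole")
  }
  list(potential = potential_surface(energy, gradient,
                                     label = "many-body potential"),
       dipole = dipole)
}
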