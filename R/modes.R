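#' Finite-difference Hessian of a potential surface
#'
#' Central differences of the (analytic or finite-difference) gradient,
#' symmetrized as (H + t(H))/2.  The raw asymmetry before symmetrization is
#' attached as attribute `"asymmetry"`.
#'
#' @param surface a `pq_potential`
#' @param geom a `pq_geometry` near a stationary point
#' @param step central-difference step in bohr (default 5e-3, balancing
#'   truncation and round-off for hartree-scale surfaces)
#' @return symmetric 3N x 3N Hessian (hartree/bohr^2)
#' @export
hessian_fd <- function(surface, geom, step = 5e-3) {
  stopifnot(step > 0)
  x <- geom$coords
  n <- length(x)
  H <- matrix(0, n, n)
  for (i in seq_len(n)) {
    xp <- x; xp[i] <- x[i] + step
    xm <- x; xm[i] <- x[i] - step
    H[, i] <- (evaluate_gradient(surface, set_coords(geom, xp)) -
               evaluate_gradient(surface, set_coords(geom, xm))) /
      (2 * step)
  }
  if (!all(is.finite(H))) stop("non-finite entries in Hessian")
  asym <- max(abs(H - t(H)))
  H <- (H + t(H)) / 2
  attr(H, "asymmetry") <- asym
  H
}

trans_rot_basis <- function(geom) {
  n <- n_atoms(geom)
  m <- geom$masses
  sm <- sqrt(rep(m, each = 3))
  com <- centre_of_mass(geom)
  r <- sweep(coord_matrix(geom), 2, com)
  B <- matrix(0, 3 * n, 6)
  for (a in 1:3) B[seq(a, 3 * n, by = 3), a] <- sqrt(m)
  ax <- diag(3)
  for (a in 1:3) {
    v <- t(apply(r, 1, function(ri) crossprod_vec(ax[a, ], ri)))
    B[, 3 + a] <- sm * as.numeric(t(v))
  }
  qr.Q(qr(B))[, seq_len(qr(B)$rank), drop = FALSE]
}

crossprod_vec <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Normal-mode analysis with translation/rotation projection
#'
#' Mass-weights the Hessian, projects out the 3 translations and up to 3
#' infinitesimal rotations (built from the instantaneous geometry), and
#' diagonalizes.  Imaginary frequencies are reported as negative numbers.
#'
#' @param hessian symmetric Cartesian Hessian (hartree/bohr^2)
#' @param geom the reference `pq_geometry`
#' @param zero_tol frequencies below this (cm^-1, absolute value) count as
#'   projected-out zeros when checking for spurious soft modes
#' @return a `pq_modes` basis: reference geometry, `freq` (hartree, signed,
#'   ascending), `freq_cm`, orthonormal mass-weighted eigenvector matrix
#'   `L` (3N x N_vib), and masses
#' @export
normal_mode_analysis <- function(hessian, geom, zero_tol = 1.0) {
  n <- n_atoms(geom)
  sm <- sqrt(rep(geom$masses, each = 3))
  Hm <- hessian / outer(sm, sm)
  B <- trans_rot_basis(geom)
  P <- diag(3 * n) - B %*% t(B)
  Hp <- P %*% Hm %*% P
  Hp <- (Hp + t(Hp)) / 2
  ev <- eigen(Hp, symmetric = TRUE)
  nproj <- ncol(B)
  nvib <- 3 * n - nproj
  ord <- order(abs(ev$values))
  zero_idx <- ord[seq_len(nproj)]
  keep <- setdiff(seq_len(3 * n), zero_idx)
  lam <- ev$values[keep]
  vec <- ev$vectors[, keep, drop = FALSE]
  freq <- sign(lam) * sqrt(abs(lam))
  o <- order(freq)
  freq <- freq[o]
  vec <- vec[, o, drop = FALSE]
  if (sum(abs(hartree_to_cm(freq)) < zero_tol) > 0)
    warning("more than ", nproj, " near-zero frequencies at a purported ",
            "minimum; geometry may not be a stationary point")
  structure(list(reference = geom, freq = freq,
                 freq_cm = hartree_to_cm(freq), L = vec,
                 masses = geom$masses, projected = B),
            class = "pq_modes")
}

#' @export
print.pq_modes <- function(x, ...) {
  cat("<pq_modes> ", length(x$freq), " vibrational modes\n", sep = "")
  cat("  frequencies (cm^-1): ",
      paste(sprintf("%.1f", x$freq_cm), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Transform Cartesian displacements/velocities to normal-mode coordinates
#'
#' Q = L' sqrt(m) (x - x_ref), P = L' sqrt(m) v.
#'
#' @param basis a `pq_modes`
#' @param geom displaced `pq_geometry` (same atom ordering as reference)
#' @param velocities optional 3N Cartesian velocity vector (a.u.)
#' @return list with `Q` and (if velocities given) `P`
#' @export
cartesian_to_modes <- function(basis, geom, velocities = NULL) {
  if (n_atoms(geom) != n_atoms(basis$reference))
    stop("geometry does not match the reference")
  sm <- sqrt(rep(basis$masses, each = 3))
  Q <- as.numeric(t(basis$L) %*% (sm * (geom$coords -
                                          basis$reference$coords)))
  out <- list(Q = Q)
  if (!is.null(velocities))
    out$P <- as.numeric(t(basis$L) %*% (sm * velocities))
  out
}

#' Reconstruct Cartesian coordinates/velocities from normal-mode coordinates
#'
#' @param basis a `pq_modes`
#' @param Q normal-mode coordinates
#' @param P optional normal-mode momenta
#' @return list with `geometry` and (if `P` given) `velocities`
#' @export
modes_to_cartesian <- function(basis, Q, P = NULL) {
  sm <- sqrt(rep(basis$masses, each = 3))
  x <- basis$reference$coords + as.numeric(basis$L %*% Q) / sm
  out <- list(geometry = set_coords(basis$reference, x))
  if (!is.null(P)) out$velocities <- as.numeric(basis$L %*% P) / sm
  out
}

#' Moment-of-inertia tensor about the centre of mass
#' @param geom a `pq_geometry`
#' @export
inertia_tensor <- function(geom) {
  r <- sweep(coord_matrix(geom), 2, centre_of_mass(geom))
  m <- geom$masses
  I <- matrix(0, 3, 3)
  for (i in seq_len(nrow(r))) {
    ri <- r[i, ]
    I <- I + m[i] * (sum(ri^2) * diag(3) - outer(ri, ri))
  }
  I
}

#' Total angular momentum about the centre of mass (a.u.)
#' @param geom a `pq_geometry`
#' @param velocities 3N Cartesian velocities
#' @export
angular_momentum <- function(geom, velocities) {
  r <- sweep(coord_matrix(geom), 2, centre_of_mass(geom))
  v <- matrix(velocities, ncol = 3, byrow = TRUE)
  m <- geom$masses
  colSums(t(vapply(seq_len(nrow(r)), function(i)
    m[i] * crossprod_vec(r[i, ], v[i, ]), numeric(3))))
}

#' Remove overall rotation (and centre-of-mass drift) from velocities
#'
#' Subtracts the centre-of-mass velocity and the rigid-rotation field
#' omega x r with omega = I^-1 L about the centre of mass.  A singular
#' inertia tensor (linear geometry) is handled by the pseudo-inverse.  The
#' kinetic energy removed is exactly the rigid-rotation energy
#' (1/2) L' I^-1 L.
#'
#' @param geom a `pq_geometry`
#' @param velocities 3N Cartesian velocities (a.u.)
#' @return velocity vector with total L and COM momentum below 1e-10
#' @export
remove_angular_momentum <- function(geom, velocities) {
  m <- geom$masses
  v <- matrix(velocities, ncol = 3, byrow = TRUE)
  vcom <- colSums(v * m) / sum(m)
  v <- sweep(v, 2, vcom)
  L <- angular_momentum(geom, as.numeric(t(v)))
  I <- inertia_tensor(geom)
  om <- pinv_solve(I, L)
  r <- sweep(coord_matrix(geom), 2, centre_of_mass(geom))
  for (i in seq_len(nrow(v)))
    v[i, ] <- v[i, ] - crossprod_vec(om, r[i, ])
  as.numeric(t(v))
}

pinv_solve <- function(A, b, tol = 1e-10) {
  e <- eigen(A, symmetric = TRUE)
  keep <- abs(e$values) > tol * max(abs(e$values))
  as.numeric(e$vectors[, keep, drop = FALSE] %*%
               ((t(e$vectors[, keep, drop = FALSE]) %*% b) /
                  e$values[keep]))
}

#' Frequency table for a normal-mode basis
#'
#' @param basis a `pq_modes`
#' @param labels optional mode labels
#' @return data.frame with mode index, frequency (cm^-1) and label
#' @export
mode_report <- function(basis, labels = NULL) {
  if (is.null(labels)) labels <- rep("", length(basis$freq))
  data.frame(mode = seq_along(basis$freq),
             freq_cm = basis$freq_cm, label = labels)
}
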