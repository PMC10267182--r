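#' A single cavity photon mode
#'
#' A cavity mode carries a frequency, a unit polarization vector and the
#' photonic phase-space coordinates (q, p); the photon coordinate is
#' mass-weighted by construction, so its mass is 1.
#'
#' @param omega_cm1 mode frequency in cm^-1 (alternative to `omega`)
#' @param omega mode frequency in hartree
#' @param polarization 3-vector, normalized internally
#' @param q,p photon displacement and momentum (a.u.)
#' @return object of class `pq_cavity_mode`
#' @export
cavity_mode <- function(omega_cm1 = NULL, omega = NULL,
                        polarization = c(0, 0, 1), q = 0, p = 0) {
  if (is.null(omega)) {
    if (is.null(omega_cm1)) stop("give omega_cm1 or omega")
    omega <- cm_to_hartree(omega_cm1)
  }
  if (omega <= 0) stop("cavity frequency must be positive")
  nrm <- sqrt(sum(polarization^2))
  if (nrm == 0) stop("polarization vector must be non-zero")
  structure(list(omega = omega, e = polarization / nrm, q = q, p = p),
            class = "pq_cavity_mode")
}

#' @export
print.pq_cavity_mode <- function(x, ...) {
  cat(sprintf("<pq_cavity_mode> omega = %.1f cm^-1, e = (%.3f, %.3f, %.3f), q = %.4g, p = %.4g\n",
              hartree_to_cm(x$omega), x$e[1], x$e[2], x$e[3], x$q, x$p))
  invisible(x)
}

#' Convert between coupling factor g and effective cavity volume
#'
#' The light-matter coupling factor is g = sqrt(omega / (2 epsilon0 Vtilde))
#' with epsilon0 = 1/(4 pi) in atomic units.  Given the frequency and either
#' g or the volume, the missing member is computed; the relation is exactly
#' involutive.
#'
#' @param omega_cm1 cavity frequency (cm^-1); alternative `omega` in hartree
#' @param omega frequency in hartree
#' @param g coupling factor in a.u.
#' @param volume_nm3 effective cavity volume in nm^3
#' @return object of class `pq_coupling` with `omega`, `g`, `volume`
#'   (bohr^3), `volume_nm3` and `epsilon0`
#' @examples
#' coupling_volume_convert(omega_cm1 = 3547, g = 0.005)$volume_nm3  # ~0.6
#' @export
coupling_volume_convert <- function(omega_cm1 = NULL, omega = NULL,
                                    g = NULL, volume_nm3 = NULL) {
  if (is.null(omega)) {
    if (is.null(omega_cm1)) stop("give omega_cm1 or omega")
    omega <- cm_to_hartree(omega_cm1)
  }
  if (omega <= 0) stop("frequency must be positive")
  if (is.null(g) == is.null(volume_nm3))
    stop("give exactly one of g or volume_nm3")
  if (!is.null(g)) {
    if (g < 0) stop("g must be non-negative")
    volume <- if (g == 0) Inf else omega / (2 * EPSILON0_AU * g^2)
  } else {
    volume <- nm3_to_bohr3(volume_nm3)
    if (volume <= 0) stop("volume must be positive")
    g <- sqrt(omega / (2 * EPSILON0_AU * volume))
  }
  structure(list(omega = omega, g = g, volume = volume,
                 volume_nm3 = bohr3_to_nm3(volume),
                 epsilon0 = EPSILON0_AU),
            class = "pq_coupling")
}

#' @export
print.pq_coupling <- function(x, ...) {
  cat(sprintf("<pq_coupling> omega = %.1f cm^-1, g = %.4g a.u., V = %.4g nm^3\n",
              hartree_to_cm(x$omega), x$g, x$volume_nm3))
  invisible(x)
}

# displacement coefficient of the completed square, sqrt(2/omega^3) g
cavity_disp_coef <- function(mode, coupling) {
  sqrt(2 / mode$omega^3) * coupling$g
}

as_mode_list <- function(modes) {
  if (inherits(modes, "pq_cavity_mode")) list(modes) else modes
}

as_coupling_list <- function(couplings, nmodes) {
  if (inherits(couplings, "pq_coupling")) couplings <- list(couplings)
  if (length(couplings) == 1 && nmodes > 1)
    couplings <- rep(couplings, nmodes)
  couplings
}

#' Effective potential of the completed-square cavity Hamiltonian
#'
#' V_eff(R, q) = V(R) + sum_k (1/2) omega_k^2 (q_k + sqrt(2/omega_k^3) g_k
#' (mu . e_k))^2.  The dipole self-energy is always included: it is part of
#' the completed square.  For any R the minimum over the photon coordinates
#' equals V(R), attained at q_k* = -sqrt(2/omega_k^3) g_k (mu . e_k).
#'
#' @param potential a `pq_potential`
#' @param dipole a `pq_dipole`
#' @param modes a `pq_cavity_mode` or list of them
#' @param couplings a `pq_coupling` (or list, one per mode)
#' @param geom molecular `pq_geometry`
#' @param q optional photon coordinates (default: taken from the modes)
#' @return V_eff in hartree
#' @export
effective_potential <- function(potential, dipole, modes, couplings, geom,
                                q = NULL) {
  modes <- as_mode_list(modes)
  couplings <- as_coupling_list(couplings, length(modes))
  if (is.null(q)) q <- vapply(modes, `[[`, 0, "q")
  V <- evaluate_potential(potential, geom)
  mu <- evaluate_dipole(dipole, geom)
  for (k in seq_along(modes)) {
    ck <- cavity_disp_coef(modes[[k]], couplings[[k]])
    s <- q[k] + ck * sum(mu * modes[[k]]$e)
    V <- V + 0.5 * modes[[k]]$omega^2 * s^2
  }
  V
}

#' Forces of the effective potential
#'
#' Nuclear forces are -dV/dR minus the chain-rule coupling term through the
#' dipole jacobian; photon forces are -omega_k^2 (q_k + c_k mu.e_k).
#'
#' @inheritParams effective_potential
#' @param fd_step finite-difference step used when the dipole carries no
#'   analytic jacobian; set `fd = FALSE` to make a missing jacobian an error
#' @param fd allow finite-difference jacobian fallback
#' @return list with `nuclear` (3N) and `cavity` (one per mode) forces
#' @export
effective_forces <- function(potential, dipole, modes, couplings, geom,
                             q = NULL, fd = TRUE, fd_step = 1e-4) {
  modes <- as_mode_list(modes)
  couplings <- as_coupling_list(couplings, length(modes))
  if (is.null(q)) q <- vapply(modes, `[[`, 0, "q")
  fn <- -evaluate_gradient(potential, geom)
  mu <- evaluate_dipole(dipole, geom)
  if (is.null(dipole$jacobian) && !fd)
    stop("dipole jacobian unavailable and finite differences disabled")
  J <- evaluate_dipole_jacobian(dipole, geom, fd_step)
  fc <- numeric(length(modes))
  for (k in seq_along(modes)) {
    ck <- cavity_disp_coef(modes[[k]], couplings[[k]])
    s <- q[k] + ck * sum(mu * modes[[k]]$e)
    w2s <- modes[[k]]$omega^2 * s
    fc[k] <- -w2s
    fn <- fn - w2s * ck * as.numeric(t(J) %*% modes[[k]]$e)
  }
  list(nuclear = fn, cavity = fc)
}

#' Energy decomposition of a polaritonic phase-space state
#'
#' E_mol = T_N + V(R); E_cav = sum_k (p_k^2 + omega_k^2 q_k^2)/2;
#' E_field = sum_k (p_k^2 + omega_k^2 (q_k + c_k mu.e_k)^2)/2.  The
#' conserved total is E_mol + E_field.
#'
#' @param geom molecular `pq_geometry`
#' @param velocities 3N Cartesian velocities (a.u.)
#' @param modes a `pq_cavity_mode` or list of them (carrying q, p)
#' @param couplings a `pq_coupling` (or list)
#' @param potential a `pq_potential`
#' @param dipole a `pq_dipole`
#' @return object of class `pq_energy_breakdown` with `E_mol`, `E_cav`,
#'   `E_field`, `E_total` (hartree)
#' @export
energy_decomposition <- function(geom, velocities, modes, couplings,
                                 potential, dipole) {
  modes <- as_mode_list(modes)
  couplings <- as_coupling_list(couplings, length(modes))
  ke <- 0.5 * sum(rep(geom$masses, each = 3) * velocities^2)
  E_mol <- ke + evaluate_potential(potential, geom)
  mu <- evaluate_dipole(dipole, geom)
  E_cav <- 0
  E_field <- 0
  for (k in seq_along(modes)) {
    m <- modes[[k]]
    ck <- cavity_disp_coef(m, couplings[[k]])
    s <- m$q + ck * sum(mu * m$e)
    E_cav <- E_cav + 0.5 * m$p^2 + 0.5 * m$omega^2 * m$q^2
    E_field <- E_field + 0.5 * m$p^2 + 0.5 * m$omega^2 * s^2
  }
  structure(list(E_mol = E_mol, E_cav = E_cav, E_field = E_field,
                 E_total = E_mol + E_field),
            class = "pq_energy_breakdown")
}

#' @export
print.pq_energy_breakdown <- function(x, ...) {
  cat(sprintf("<pq_energy_breakdown> E_mol = %.8f  E_cav = %.8f  E_field = %.8f  E_total = %.8f hartree\n",
              x$E_mol, x$E_cav, x$E_field, x$E_total))
  invisible(x)
}
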