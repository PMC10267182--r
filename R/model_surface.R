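#' Parameters of the analytic model water-dimer surface
#'
#' The model surface is a permutationally invariant stand-in for fitted
#' ab initio water surfaces: each monomer carries two Morse OH bonds and a
#' harmonic bend; the 2-body term is an O-O Morse well, four equivalent
#' H...O cross Morse wells and four equivalent H-H exponential repulsions,
#' all functions of interatomic distances only (hence exactly invariant
#' under rigid motions, intra-monomer H exchange and monomer exchange, and
#' vanishing at infinite separation).  The dipole is a sum of four bond
#' dipoles mu_bond(r) = (mu0 + mu1 (r - r_oh)) along each OH unit vector.
#'
#' Defaults were calibrated once so that the harmonic H-bonded OH stretch
#' falls in the 3400-3700 cm^-1 window and the dimer well depth lands near
#' 1000-1500 cm^-1, with bends near 1650 cm^-1; see the package vignette.
#'
#' @param d_oh,a_oh,r_oh OH Morse depth (hartree), range (bohr^-1), length
#'   (bohr)
#' @param k_bend,theta0 harmonic bend constant (hartree/rad^2) and angle
#'   (rad)
#' @param d_oo,a_oo,r_oo intermolecular O-O Morse well
#' @param d_ho,a_ho,r_ho intermolecular H...O cross Morse well
#' @param d_hh,a_hh,r_hh intermolecular H-H Morse (shallow dispersion-like
#'   well with a steep short-range wall)
#' @param q_h,r_damp intermolecular damped-Coulomb charge on H (e; O carries
#'   -2 q_h) and quartic damping length (bohr); the Coulomb sum supplies the
#'   orientational (dipole-dipole) stiffness a distance-only Morse set lacks
#' @param mu0,mu1 bond-dipole value at r_oh (e bohr) and slope (e)
#' @return list of class `pq_model_params`
#' @export
model_dimer_parameters <- function(d_oh = 0.18, a_oh = 1.165,
                                   r_oh = 1.8141,
                                   k_bend = 0.150,
                                   theta0 = 104.52 * pi / 180,
                                   d_oo = 0.002, a_oo = 1.8, r_oo = 5.5,
                                   d_ho = 0.003, a_ho = 2.3, r_ho = 3.2,
                                   d_hh = 2e-4, a_hh = 1.2, r_hh = 4.3,
                                   q_h = 0.15, r_damp = 9.0,
                                   mu0 = 0.60, mu1 = 0.16) {
  p <- list(d_oh = d_oh, a_oh = a_oh, r_oh = r_oh, k_bend = k_bend,
            theta0 = theta0, d_oo = d_oo, a_oo = a_oo, r_oo = r_oo,
            d_ho = d_ho, a_ho = a_ho, r_ho = r_ho, d_hh = d_hh,
            a_hh = a_hh, r_hh = r_hh, q_h = q_h, r_damp = r_damp,
            mu0 = mu0, mu1 = mu1)
  pos <- c("d_oh", "a_oh", "r_oh", "k_bend", "theta0", "d_oo", "a_oo",
           "r_oo", "d_ho", "a_ho", "r_ho", "d_hh", "a_hh", "r_hh")
  bad <- pos[vapply(p[pos], function(v) !is.finite(v) || v <= 0, TRUE)]
  if (length(bad))
    stop("model parameters must be positive: ", paste(bad, collapse = ", "))
  structure(p, class = "pq_model_params")
}

#' Equilibrium geometry of the model water monomer (analytic)
#' @param params `pq_model_params`
#' @return `pq_geometry` (O H H) at the exact monomer minimum
#' @export
monomer_reference <- function(params = model_dimer_parameters()) {
  r <- params$r_oh; th <- params$theta0
  geometry(c("O", "H", "H"),
           c(0, 0, 0,
             r * sin(th / 2), 0, r * cos(th / 2),
             -r * sin(th / 2), 0, r * cos(th / 2)))
}

# H-bonded starting structure: rigid monomers, donor OH on the O-O axis
dimer_start_geometry <- function(params) {
  r <- params$r_oh; th <- params$theta0; R <- params$r_oo
  # donor: O at origin, bonded H on +z toward the acceptor
  don <- rbind(c(0, 0, 0),
               c(r * sin(th), 0, r * cos(th)),
               c(0, 0, r))
  # acceptor: O on +z, bisector tilted off-axis, H atoms out of the xz plane
  beta <- 120 * pi / 180
  b <- c(sin(beta), 0, cos(beta))
  yy <- c(0, 1, 0)
  h1 <- cos(th / 2) * b + sin(th / 2) * yy
  h2 <- cos(th / 2) * b - sin(th / 2) * yy
  acc <- rbind(c(0, 0, R), c(0, 0, R) + r * h1, c(0, 0, R) + r * h2)
  geometry(c("O", "H", "H", "O", "H", "H"),
           as.numeric(t(rbind(don, acc))))
}

#' Relax a geometry to a stationary point of a surface
#'
#' BFGS followed by projected Newton steps (translations/rotations removed
#' via the pseudo-inverse) until the gradient norm falls below `tol`.
#'
#' @param surface a `pq_potential`
#' @param geom starting `pq_geometry`
#' @param tol gradient-norm convergence threshold (hartree/bohr)
#' @param maxit Newton iteration cap
#' @return relaxed `pq_geometry`
#' @export
relax_geometry <- function(surface, geom, tol = 1e-9, maxit = 50) {
  fn <- function(x) evaluate_potential(surface, set_coords(geom, x))
  gr <- function(x) evaluate_gradient(surface, set_coords(geom, x))
  opt <- stats::optim(geom$coords, fn, gr, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-15))
  x <- opt$par
  for (it in seq_len(maxit)) {
    g <- gr(x)
    if (sqrt(sum(g^2)) < tol) break
    H <- hessian_fd(surface, set_coords(geom, x), step = 1e-3)
    dx <- pinv_solve(H, g, tol = 1e-8)
    if (max(abs(dx)) > 0.2) dx <- dx * 0.2 / max(abs(dx))
    x <- x - dx
  }
  set_coords(geom, x)
}

model_cpp_potential <- function(params) {
  pot <- potential_surface(
    energy = function(geom) pq_model_energy(geom$coords, params),
    gradient = function(geom) pq_model_gradient(geom$coords, params),
    label = "model water dimer")
  pot$native <- "dimer"
  pot$params <- params
  pot
}

model_cpp_dipole <- function(params) {
  dip <- dipole_surface(
    dipole = function(geom) pq_model_dipole(geom$coords, params),
    jacobian = function(geom) pq_model_dipole_jacobian(geom$coords, params),
    label = "model bond-dipole")
  dip$native <- "dimer"
  dip$params <- params
  dip
}

#' Build the model water-dimer potential and dipole surfaces
#'
#' Constructs the analytic model surface, relaxes the dimer and monomer
#' references, runs normal-mode analysis at both minima, identifies the
#' H-bonded OH stretch mode, and verifies that the hydrogen-bond
#' dissociation channel is open: the well depth D_HB (a derived quantity,
#' the energy of the relaxed dimer below two relaxed monomers) must be
#' smaller than one quantum of the H-bonded OH stretch.
#'
#' @param params a `pq_model_params`
#' @return object of class `pq_model_surface` with elements `potential`,
#'   `dipole` (full dimer), `monomer_potential`, `monomer_dipole`,
#'   `pair_potential` (2-body term), `params`, `dimer_min`, `monomer_min`,
#'   `D_HB` (hartree), `basis` (dimer `pq_modes`), `monomer_basis`, and
#'   `hb_mode` (index of the H-bonded stretch in `basis`)
#' @export
model_dimer_surface <- function(params = model_dimer_parameters()) {
  pot <- model_cpp_potential(params)
  dip <- model_cpp_dipole(params)
  mono_pot <- potential_surface(
    energy = function(geom) pq_model_monomer_energy(geom$coords, params),
    gradient = function(geom) pq_model_monomer_gradient(geom$coords,
                                                        params),
    label = "model water monomer")
  mono_pot$native <- "monomer"
  mono_pot$params <- params
  mono_dip <- dipole_surface(
    dipole = function(geom) pq_model_monomer_dipole(geom$coords, params),
    label = "model monomer bond-dipole")
  pair_pot <- potential_surface(
    energy = function(geom) pq_model_pair_energy(geom$coords, params),
    gradient = function(geom) pq_model_pair_gradient(geom$coords, params),
    label = "model 2-body term")

  mono_min <- monomer_reference(params)
  dimer_min <- relax_geometry(pot, dimer_start_geometry(params))
  D_HB <- -evaluate_potential(pot, dimer_min)
  if (D_HB <= 0)
    stop("model parameters give an unbound dimer (D_HB = ",
         signif(-D_HB, 4), " hartree)")

  basis <- normal_mode_analysis(hessian_fd(pot, dimer_min), dimer_min)
  mono_basis <- normal_mode_analysis(hessian_fd(mono_pot, mono_min),
                                     mono_min)
  hb <- hb_stretch_mode(basis, dimer_min)
  w_hb <- basis$freq[hb]
  if (D_HB >= w_hb)
    stop("dissociation channel closed: D_HB = ",
         round(hartree_to_cm(D_HB)), " cm^-1 is not below one quantum of ",
         "the H-bonded OH stretch (", round(hartree_to_cm(w_hb)),
         " cm^-1); choose shallower intermolecular wells")

  structure(list(potential = pot, dipole = dip,
                 monomer_potential = mono_pot, monomer_dipole = mono_dip,
                 pair_potential = pair_pot, params = params,
                 dimer_min = dimer_min, monomer_min = mono_min,
                 D_HB = D_HB, basis = basis, monomer_basis = mono_basis,
                 hb_mode = hb),
            class = "pq_model_surface")
}

#' @export
print.pq_model_surface <- function(x, ...) {
  cat("<pq_model_surface> analytic model water dimer\n")
  cat(sprintf("  D_HB: %.1f cm^-1   H-bonded OH stretch: %.1f cm^-1 (mode %d)\n",
              hartree_to_cm(x$D_HB), x$basis$freq_cm[x$hb_mode], x$hb_mode))
  cat("  dimer modes (cm^-1): ",
      paste(sprintf("%.0f", x$basis$freq_cm), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' Identify the H-bonded OH stretch mode of a dimer basis
#'
#' Among stretch-frequency modes (above `stretch_min` cm^-1) picks the mode
#' with the largest mass-weighted amplitude on the hydrogen closest to the
#' other monomer's oxygen.
#'
#' @param basis dimer `pq_modes`
#' @param geom dimer geometry (defaults to the basis reference)
#' @param stretch_min lower frequency bound for stretch modes (cm^-1)
#' @return mode index into `basis$freq`
#' @export
hb_stretch_mode <- function(basis, geom = basis$reference,
                            stretch_min = 2500) {
  m <- coord_matrix(geom)
  io <- which(geom$symbols == "O")
  ih <- which(geom$symbols == "H")
  # bridging H: smallest H...O distance to the O it is not bonded to
  dmin <- vapply(ih, function(h) {
    d <- vapply(io, function(o) sqrt(sum((m[h, ] - m[o, ])^2)), 0)
    sort(d)[2]
  }, 0)
  hbH <- ih[which.min(dmin)]
  cand <- which(basis$freq_cm > stretch_min)
  if (!length(cand)) stop("no stretch-frequency modes found")
  amp <- vapply(cand, function(k)
    sum(basis$L[3 * (hbH - 1) + 1:3, k]^2), 0)
  cand[which.max(amp)]
}
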