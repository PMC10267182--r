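#' Kabsch alignment of a fragment onto a reference
#'
#' Mass-weighted least-squares rotation (after removing the centres of
#' mass); for small displacements this realizes the Eckart frame of the
#' reference.  Velocities are rotated with the coordinates.
#'
#' @param geom fragment `pq_geometry`
#' @param reference reference `pq_geometry` (same atoms, same order)
#' @param velocities optional 3N velocities to co-rotate
#' @return list with aligned `geometry`, `velocities` and the rotation
#' @export
align_to_reference <- function(geom, reference, velocities = NULL) {
  m <- geom$masses
  X <- sweep(coord_matrix(geom), 2, centre_of_mass(geom))
  Y <- sweep(coord_matrix(reference), 2, centre_of_mass(reference))
  C <- t(X * m) %*% Y
  sv <- svd(C)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  Xr <- X %*% t(R)
  out <- list(geometry = set_coords(reference,
                                    as.numeric(t(sweep(Xr, 2,
                                      -centre_of_mass(reference))))),
              rotation = R)
  out$geometry$symbols <- geom$symbols
  out$geometry$masses <- m
  if (!is.null(velocities)) {
    V <- matrix(velocities, ncol = 3, byrow = TRUE) %*% t(R)
    out$velocities <- as.numeric(t(V))
  }
  out
}

#' Rovibrational energy decomposition of a product fragment
#'
#' E_rovib is the centre-of-mass-frame kinetic energy plus the potential
#' relative to the monomer minimum; E_vib is the same after removing the
#' rotational angular momentum; E_rot is the difference.
#'
#' @param frag fragment `pq_geometry` (1 O + 2 H)
#' @param velocities fragment Cartesian velocities (a.u.)
#' @param monomer_potential 1-body `pq_potential` (zero at the monomer
#'   minimum)
#' @return list with `E_rovib`, `E_vib`, `E_rot` (hartree) and the
#'   rotation-removed velocities
#' @export
fragment_rovib_decomposition <- function(frag, velocities,
                                         monomer_potential) {
  if (sum(frag$symbols == "O") != 1 || sum(frag$symbols == "H") != 2)
    stop("fragment must contain 1 O and 2 H atoms")
  m3 <- rep(frag$masses, each = 3)
  # remove COM drift only
  v <- matrix(velocities, ncol = 3, byrow = TRUE)
  v <- sweep(v, 2, colSums(v * frag$masses) / sum(frag$masses))
  v <- as.numeric(t(v))
  V <- evaluate_potential(monomer_potential, frag)
  E_rovib <- 0.5 * sum(m3 * v^2) + V
  v_vib <- remove_angular_momentum(frag, v)
  E_vib <- 0.5 * sum(m3 * v_vib^2) + V
  list(E_rovib = E_rovib, E_vib = E_vib, E_rot = E_rovib - E_vib,
       v_vib = v_vib)
}

#' Project a fragment onto monomer normal modes
#'
#' Aligns the fragment to the monomer reference (Kabsch), transforms to
#' normal-mode coordinates and momenta, and returns per-mode harmonic
#' energies E_i = (P_i^2 + omega_i^2 Q_i^2)/2.
#'
#' @param frag fragment `pq_geometry`
#' @param velocities rotation-removed fragment velocities
#' @param monomer_basis monomer `pq_modes` built at the monomer minimum
#' @return list with `Q`, `P`, `E_modes`
#' @export
project_fragment_modes <- function(frag, velocities, monomer_basis) {
  al <- align_to_reference(frag, monomer_basis$reference, velocities)
  qp <- cartesian_to_modes(monomer_basis, al$geometry, al$velocities)
  E <- 0.5 * qp$P^2 + 0.5 * monomer_basis$freq^2 * qp$Q^2
  list(Q = qp$Q, P = qp$P, E_modes = E)
}

#' Harmonic action numbers from per-mode energies
#'
#' n'_i = E_i/(hbar omega_i) - 1/2; the integer action is the nearest
#' integer (ties to even), floored at zero.
#'
#' @param E per-mode harmonic energies (hartree)
#' @param omega mode frequencies (hartree)
#' @return list with `n_prime` and integer `n`
#' @export
harmonic_actions <- function(E, omega) {
  stopifnot(all(E >= 0), all(omega > 0))
  n_prime <- E / omega - 0.5
  n <- pmax(0L, as.integer(round(n_prime)))
  list(n_prime = n_prime, n = n)
}

#' Rotational quantum number from the angular momentum vector
#'
#' Solves J(J+1) = |L|^2 (hbar = 1) and rounds to the nearest integer,
#' floored at zero.
#'
#' @param L angular momentum 3-vector, or its magnitude
#' @return integer J
#' @export
rotational_quantum_number <- function(L) {
  L2 <- if (length(L) == 3) sum(L^2) else L^2
  max(0L, as.integer(round((-1 + sqrt(1 + 4 * L2)) / 2)))
}

#' One-Gaussian-binning weight of a product fragment
#'
#' G = beta/sqrt(pi) exp(-beta^2 ((E(n') - E(n)) / (2 E(0)))^2) with
#' beta = 2 sqrt(ln 2)/delta; delta is the full width at half maximum of
#' the weight as a function of the dimensionless energy mismatch.
#'
#' @param E_nprime anharmonic vibrational energy of the product (kinetic +
#'   potential after removing rotation), hartree
#' @param E_n harmonic energy of the assigned state n
#' @param E0 harmonic zero-point energy
#' @param delta FWHM of the Gaussian (dimensionless), default 0.1
#' @return Gaussian weight
#' @export
gaussian_weight <- function(E_nprime, E_n, E0, delta = 0.1) {
  stopifnot(E0 > 0, delta > 0)
  beta <- 2 * sqrt(log(2)) / delta
  beta / sqrt(pi) * exp(-beta^2 * ((E_nprime - E_n) / (2 * E0))^2)
}

#' Correlated weight of a fragment pair
#'
#' @param G_frag1,G_frag2 per-fragment Gaussian weights
#' @return their product
#' @export
correlated_weight <- function(G_frag1, G_frag2) G_frag1 * G_frag2

# monomer mode roles by eigenvector character: bend = lowest of the three;
# the stretch whose two OH-bond elongations share a sign is symmetric
monomer_mode_roles <- function(monomer_basis) {
  ref <- monomer_basis$reference
  m <- coord_matrix(ref)
  b1 <- (m[2, ] - m[1, ]); b1 <- b1 / sqrt(sum(b1^2))
  b2 <- (m[3, ] - m[1, ]); b2 <- b2 / sqrt(sum(b2^2))
  sm <- sqrt(rep(ref$masses, each = 3))
  roles <- character(3)
  roles[1] <- "bend"                       # frequencies sorted ascending
  for (k in 2:3) {
    L <- monomer_basis$L[, k] / sm         # Cartesian displacement
    s1 <- sum(L[4:6] * b1) - sum(L[1:3] * b1)
    s2 <- sum(L[7:9] * b2) - sum(L[1:3] * b2)
    roles[k] <- if (s1 * s2 > 0) "sym" else "asym"
  }
  if (!setequal(roles[2:3], c("sym", "asym")))
    roles[2:3] <- c("sym", "asym")         # degenerate-character fallback
  roles
}

#' Full product-state analysis of one fragment
#'
#' @param frag fragment `pq_geometry`
#' @param velocities fragment velocities
#' @param model a `pq_model_surface` (supplies the monomer surface/basis)
#' @return a `pq_fragment_analysis`: energies, Q/P, per-mode energies,
#'   actions ordered (n1, n2, n3) = (symmetric stretch, bend, asymmetric
#'   stretch), J, and the ingredients of the Gaussian weight
#' @export
fragment_analysis <- function(frag, velocities, model) {
  dec <- fragment_rovib_decomposition(frag, velocities,
                                      model$monomer_potential)
  pr <- project_fragment_modes(frag, dec$v_vib, model$monomer_basis)
  act <- harmonic_actions(pr$E_modes, model$monomer_basis$freq)
  roles <- monomer_mode_roles(model$monomer_basis)
  ord <- c(which(roles == "sym"), which(roles == "bend"),
           which(roles == "asym"))
  # COM-frame angular momentum before removal
  v <- matrix(velocities, ncol = 3, byrow = TRUE)
  v <- sweep(v, 2, colSums(v * frag$masses) / sum(frag$masses))
  L <- angular_momentum(frag, as.numeric(t(v)))
  w <- model$monomer_basis$freq
  structure(list(E_rovib = dec$E_rovib, E_vib = dec$E_vib,
                 E_rot = dec$E_rot, Q = pr$Q, P = pr$P,
                 E_modes = pr$E_modes,
                 n_prime = act$n_prime[ord], n = act$n[ord],
                 mode_order = ord, J = rotational_quantum_number(L),
                 E_nprime = dec$E_vib,
                 E_n = sum((act$n + 0.5) * w), E0 = sum(w) / 2),
            class = "pq_fragment_analysis")
}

#' Canonical channel label for a fragment pair
#'
#' @param n1,n2 integer action triplets of the two fragments
#' @return string like `"(000)+(010)"`, lexicographically smaller first
#' @export
channel_label <- function(n1, n2) {
  s <- c(paste0(n1, collapse = ""), paste0(n2, collapse = ""))
  s <- s[order(s)]
  paste0("(", s[1], ")+(", s[2], ")")
}

#' Analyze the dissociated final frames of an ensemble
#'
#' @param ensemble a `pq_ensemble`
#' @param model the `pq_model_surface` used for the run
#' @return list of fragment-analysis pairs (one per dissociated trajectory)
#' @export
analyze_products <- function(ensemble, model) {
  out <- list()
  for (f in ensemble$finals) {
    if (is.null(f)) next
    frags <- fragment_partition(f$geometry)
    pair <- lapply(frags, function(fr) {
      idx <- attr(fr, "index")
      vsel <- as.numeric(t(matrix(f$velocities, ncol = 3,
                                  byrow = TRUE)[idx, ]))
      fragment_analysis(fr, vsel, model)
    })
    out[[length(out) + 1]] <- pair
  }
  out
}

#' Gaussian-binned channel populations and J distributions
#'
#' P_GB(n) = sum_i G_i(n) / sum_n sum_i G_i(n) with the correlated pair
#' weight G = G(fragment 1) x G(fragment 2).  Also tabulates
#' weight-resolved rotational distributions per channel.
#'
#' @param pairs list of fragment-analysis pairs (from [analyze_products()])
#' @param delta Gaussian FWHM (dimensionless), default 0.1; `Inf` reduces
#'   the populations to raw channel counts / N
#' @return a `pq_channels`: `table` (channel, P_GB, count, raw fraction),
#'   `jdist` (channel x J weighted histogram), `delta`, `beta`
#' @export
channel_populations <- function(pairs, delta = 0.1) {
  if (!length(pairs)) stop("no dissociated fragment pairs to bin")
  lab <- character(length(pairs))
  wt <- numeric(length(pairs))
  Js <- vector("list", length(pairs))
  for (i in seq_along(pairs)) {
    a <- pairs[[i]][[1]]
    b <- pairs[[i]][[2]]
    lab[i] <- channel_label(a$n, b$n)
    g <- if (is.infinite(delta)) c(1, 1) else
      c(gaussian_weight(a$E_nprime, a$E_n, a$E0, delta),
        gaussian_weight(b$E_nprime, b$E_n, b$E0, delta))
    wt[i] <- correlated_weight(g[1], g[2])
    Js[[i]] <- c(a$J, b$J)
  }
  tot <- sum(wt)
  if (tot <= 0) stop("all Gaussian weights vanished; increase delta")
  channels <- sort(unique(lab))
  P <- vapply(channels, function(ch) sum(wt[lab == ch]) / tot, 0)
  cnt <- vapply(channels, function(ch) sum(lab == ch), 0L)
  jmax <- max(unlist(Js))
  jd <- matrix(0, length(channels), jmax + 1,
               dimnames = list(channels, 0:jmax))
  for (i in seq_along(pairs))
    for (J in Js[[i]])
      jd[lab[i], J + 1] <- jd[lab[i], J + 1] + wt[i] / 2
  structure(list(table = data.frame(channel = channels, P_GB = unname(P),
                                    count = unname(cnt),
                                    raw_frac = unname(cnt) /
                                      length(pairs)),
                 jdist = jd, delta = delta,
                 beta = if (is.infinite(delta)) 0 else
                   2 * sqrt(log(2)) / delta,
                 n_pairs = length(pairs)),
            class = "pq_channels")
}

#' @export
print.pq_channels <- function(x, ...) {
  cat("<pq_channels> ", x$n_pairs, " fragment pairs, delta = ", x$delta,
      "\n", sep = "")
  tab <- x$table[order(-x$table$P_GB), ]
  print(tab, row.names = FALSE, digits = 3)
  invisible(x)
}
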