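#' Gauss-Hermite quadrature nodes and weights (weight exp(-y^2))
#'
#' Golub-Welsch: eigen-decomposition of the Jacobi matrix.
#'
#' @param n number of points
#' @return list with nodes `x` (ascending) and weights `w`
#' @export
gauss_hermite <- function(n) {
  if (n == 1) return(list(x = 0, w = sqrt(pi)))
  off <- sqrt(seq_len(n - 1) / 2)
  J <- matrix(0, n, n)
  J[cbind(seq_len(n - 1), 2:n)] <- off
  J[cbind(2:n, seq_len(n - 1))] <- off
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(x = e$values[ord], w = sqrt(pi) * e$vectors[1, ord]^2)
}

# orthonormal Hermite functions with the Gaussian stripped:
# c_a(y) = psi_a(y) exp(y^2/2); integrals become sums over GH nodes
hermite_ortho <- function(nbasis, y) {
  C <- matrix(0, length(y), nbasis)
  C[, 1] <- pi^(-0.25)
  if (nbasis > 1) C[, 2] <- sqrt(2) * y * C[, 1]
  if (nbasis > 2) for (a in 2:(nbasis - 1))
    C[, a + 1] <- y * sqrt(2 / a) * C[, a] -
      sqrt((a - 1) / a) * C[, a - 1]
  C
}

# quadrature-basis matrix: B[p, a] with
# integral(phi_a phi_b f) = sum_p B[p,a] B[p,b] f(Q_p); independent of the
# mode frequency (which only scales the node positions Q = y/sqrt(w))
quad_basis <- function(nq, nbasis) {
  gh <- gauss_hermite(nq)
  list(y = gh$x, B = sqrt(gh$w) * hermite_ortho(nbasis, gh$x))
}

# kinetic energy p^2/2 of a unit-mass mode in its HO primitive basis
kinetic_primitive <- function(nbasis, w) {
  K <- diag((w / 4) * (2 * seq_len(nbasis) - 1))
  if (nbasis > 2) {
    a <- 0:(nbasis - 3)
    off <- -(w / 4) * sqrt((a + 1) * (a + 2))
    K[cbind(seq_len(nbasis - 2), 3:nbasis)] <- off
    K[cbind(3:nbasis, seq_len(nbasis - 2))] <- off
  }
  K
}

grid_index <- function(nq, k) {
  as.matrix(expand.grid(rep(list(seq_len(nq)), k)))
}

lin_index <- function(GI, pos, nq) {
  li <- rep(1, nrow(GI))
  mult <- 1
  for (m in seq_along(pos)) {
    li <- li + (GI[, pos[m]] - 1) * mult
    mult <- mult * nq
  }
  li
}

all_subsets <- function(k) {
  out <- list()
  for (j in seq_len(k)) {
    cmb <- utils::combn(k, j)
    for (c in seq_len(ncol(cmb))) out[[length(out) + 1]] <- cmb[, c]
  }
  out
}

#' Hierarchical n-mode representation of a potential or dipole component
#'
#' Expands f(Q) = f(0) + sum over mode subsets S (|S| <= order) of
#' hierarchical increments v_S, each evaluated on a tensor-product
#' Gauss-Hermite grid whose size may shrink with the coupling order.  The
#' increments are computed by inclusion-exclusion over sub-grids, so each
#' k-mode term has all lower-order contributions subtracted exactly; when
#' order equals the number of modes the representation reconstructs f at
#' every grid point.
#'
#' @param f batched function: given an n x M matrix of mode displacements
#'   (mass-weighted bohr for molecular modes, a.u. for photon modes)
#'   returns a length-n vector, or an n x ncomp matrix for vector-valued
#'   surfaces (dipole components)
#' @param freqs harmonic frequency per mode (hartree): sets the quadrature
#'   scaling Q = y/sqrt(freq)
#' @param order maximum coupling order (e.g. 4 for a potential, 3 for a
#'   dipole)
#' @param nquad quadrature points per order (recycled); e.g.
#'   `c(20, 16, 10, 8)`
#' @param mode_ids global mode identities (positions in the VSCF mode list)
#'   so that operators over mode subsets can be combined
#' @param ncomp number of components f returns
#' @return object of class `pq_nmr`
#' @export
build_nmode_rep <- function(f, freqs, order, nquad = c(20, 16, 10, 8),
                            mode_ids = seq_along(freqs), ncomp = 1) {
  M <- length(freqs)
  if (order > M) stop("coupling order (", order,
                      ") exceeds the number of modes (", M, ")")
  if (order < 1) stop("order must be at least 1")
  nquad <- rep(nquad, length.out = order)
  V0 <- matrix(f(matrix(0, 1, M)), 1, ncomp)
  terms <- list()
  for (k in seq_len(order)) {
    nq <- nquad[k]
    gh <- gauss_hermite(nq)
    subsets <- utils::combn(M, k)
    GI <- grid_index(nq, k)
    for (ci in seq_len(ncol(subsets))) {
      S <- subsets[, ci]
      nodes <- lapply(S, function(j) gh$x / sqrt(freqs[j]))
      # inclusion-exclusion: v_S = sum_{T subset S} (-1)^(|S|-|T|) f_T;
      # the empty subset contributes (-1)^k f(0)
      vals <- matrix((-1)^k * rep(as.numeric(V0), each = nrow(GI)),
                     nrow(GI), ncomp)
      for (T in all_subsets(k)) {
        sgn <- (-1)^(k - length(T))
        GT <- grid_index(nq, length(T))
        Qm <- matrix(0, nrow(GT), M)
        for (m in seq_along(T))
          Qm[, S[T[m]]] <- nodes[[T[m]]][GT[, m]]
        fT <- matrix(f(Qm), nrow(GT), ncomp)
        li <- lin_index(GI, T, nq)
        vals <- vals + sgn * fT[li, , drop = FALSE]
      }
      key <- paste(mode_ids[S], collapse = "-")
      terms[[key]] <- list(modes = mode_ids[S], nq = nq,
                           nodes = nodes, values = vals)
    }
  }
  structure(list(mode_ids = mode_ids, freqs = freqs, order = order,
                 nquad = nquad, V0 = as.numeric(V0), terms = terms,
                 ncomp = ncomp),
            class = "pq_nmr")
}

#' @export
print.pq_nmr <- function(x, ...) {
  cat("<pq_nmr> ", length(x$mode_ids), " modes, order ", x$order,
      ", ", length(x$terms), " terms, ", x$ncomp, " component(s)\n",
      sep = "")
  invisible(x)
}

#' Reconstruct an n-mode representation on its top-order grid
#'
#' Only meaningful when all orders share the same quadrature size (then
#' every lower-order term is known at projections of the top grid).  Used
#' to verify the telescoping identity: at order = n_modes the
#' reconstruction equals the original function at every grid point.
#'
#' @param nmr a `pq_nmr` built with a scalar `nquad`
#' @param key term key (default: the first top-order term)
#' @return list with the grid displacement matrix `Q` and reconstructed
#'   `values`
#' @export
nmr_reconstruct_top <- function(nmr, key = NULL) {
  if (length(unique(nmr$nquad)) != 1)
    stop("reconstruction needs a single quadrature size for all orders")
  nq <- nmr$nquad[1]
  ks <- vapply(nmr$terms, function(t) length(t$modes), 0L)
  if (is.null(key)) key <- names(nmr$terms)[which.max(ks)]
  top <- nmr$terms[[key]]
  k <- length(top$modes)
  GI <- grid_index(nq, k)
  vals <- matrix(rep(nmr$V0, each = nrow(GI)), nrow(GI), nmr$ncomp)
  for (T in all_subsets(k)) {
    tk <- paste(top$modes[T], collapse = "-")
    if (is.null(nmr$terms[[tk]])) next
    li <- lin_index(GI, T, nq)
    vals <- vals + nmr$terms[[tk]]$values[li, , drop = FALSE]
  }
  Q <- matrix(0, nrow(GI), length(nmr$mode_ids))
  for (m in seq_len(k)) {
    pos <- match(top$modes[m], nmr$mode_ids)
    Q[, pos] <- top$nodes[[m]][GI[, m]]
  }
  list(Q = Q, values = vals)
}

# contract a term-value vector over all modes except (optionally) one,
# using per-position density vectors at the term's nodes
contract_term <- function(v, k, nq, keep = NULL, dens) {
  arr <- array(v, dim = rep(nq, k))
  rem <- seq_len(k)
  while (length(rem) > (if (is.null(keep)) 0 else 1)) {
    nd <- length(rem)
    if (!is.null(keep) && rem[nd] == keep) {
      perm <- c(nd, seq_len(nd - 1))
      arr <- aperm(array(arr, dim = rep(nq, nd)), perm)
      rem <- rem[perm]
      nd <- length(rem)
    }
    mat <- matrix(arr, ncol = nq)
    arr <- as.numeric(mat %*% dens[[rem[nd]]])
    rem <- rem[-nd]
  }
  as.numeric(arr)
}

#' Vibrational self-consistent field over an n-mode representation
#'
#' Solves the mean-field equations for a target (default ground) state in a
#' harmonic-oscillator primitive basis per mode, with the kinetic energy
#' diagonal in rectilinear normal modes.  Iterates until the state energy
#' changes by less than `tol`.
#'
#' @param nmr a `pq_nmr` of the (effective) potential over all modes
#' @param nbasis primitive HO functions per mode (default 14)
#' @param target integer occupation per mode (default all 0)
#' @param tol energy convergence threshold (hartree)
#' @param maxit SCF sweep cap
#' @return object of class `pq_vscf`: per-mode `modals` (coefficient
#'   matrices, columns = modal states), modal energies, total `E`,
#'   convergence `history`, and the basis bookkeeping used by the VCI step
#' @export
vscf_solve <- function(nmr, nbasis = 14, target = NULL, tol = 1e-8,
                       maxit = 80) {
  M <- length(nmr$mode_ids)
  if (is.null(target)) target <- integer(M)
  stopifnot(length(target) == M, all(target >= 0), all(target < nbasis))
  qb_cache <- list()
  get_qb <- function(nq) {
    key <- as.character(nq)
    if (is.null(qb_cache[[key]]))
      qb_cache[[key]] <<- quad_basis(nq, nbasis)
    qb_cache[[key]]
  }
  for (t in nmr$terms) get_qb(t$nq)
  K <- lapply(nmr$freqs, function(w) kinetic_primitive(nbasis, w))
  modals <- lapply(seq_len(M), function(i) diag(nbasis))
  pos_of <- function(ids) match(ids, nmr$mode_ids)

  dens_at <- function(i, nq) {
    B <- get_qb(nq)$B
    as.numeric((B %*% modals[[i]][, target[i] + 1])^2)
  }
  state_energy <- function() {
    E <- nmr$V0[1]
    for (i in seq_len(M)) {
      c0 <- modals[[i]][, target[i] + 1]
      E <- E + as.numeric(t(c0) %*% K[[i]] %*% c0)
    }
    for (t in nmr$terms) {
      pos <- pos_of(t$modes)
      dens <- lapply(pos, function(i) dens_at(i, t$nq))
      names(dens) <- NULL
      dl <- vector("list", length(pos))
      for (m in seq_along(pos)) dl[[m]] <- dens[[m]]
      E <- E + contract_term(t$values[, 1], length(pos), t$nq,
                             keep = NULL, dens = dl)
    }
    E
  }

  history <- numeric(0)
  E_old <- Inf
  converged <- FALSE
  for (it in seq_len(maxit)) {
    for (i in seq_len(M)) {
      h <- K[[i]]
      for (t in nmr$terms) {
        pos <- pos_of(t$modes)
        if (!(i %in% pos)) next
        keep <- which(pos == i)
        dl <- vector("list", length(pos))
        for (m in seq_along(pos))
          if (m != keep) dl[[m]] <- dens_at(pos[m], t$nq)
        vbar <- contract_term(t$values[, 1], length(pos), t$nq,
                              keep = keep, dens = dl)
        B <- get_qb(t$nq)$B
        h <- h + crossprod(B, B * vbar)
      }
      es <- eigen((h + t(h)) / 2, symmetric = TRUE)
      ord <- order(es$values)            # eigen() returns descending
      modals[[i]] <- es$vectors[, ord, drop = FALSE]
      # fix sign convention for reproducibility
      for (cc in seq_len(nbasis)) {
        jmax <- which.max(abs(modals[[i]][, cc]))
        if (modals[[i]][jmax, cc] < 0)
          modals[[i]][, cc] <- -modals[[i]][, cc]
      }
      attr(modals[[i]], "energies") <- es$values[ord]
    }
    E <- state_energy()
    history <- c(history, E)
    if (abs(E - E_old) < tol) { converged <- TRUE; break }
    E_old <- E
  }
  if (!converged)
    warning("VSCF did not converge in ", maxit, " sweeps; energy history: ",
            paste(signif(tail(history, 5), 10), collapse = ", "))
  structure(list(modals = modals, E = E, history = history,
                 converged = converged, target = target, nbasis = nbasis,
                 nmr = nmr, K = K, qb_cache = qb_cache,
                 freqs = nmr$freqs, mode_ids = nmr$mode_ids),
            class = "pq_vscf")
}

#' @export
print.pq_vscf <- function(x, ...) {
  cat(sprintf("<pq_vscf> %d modes, E = %.8f hartree, %s after %d sweeps\n",
              length(x$mode_ids), x$E,
              if (x$converged) "converged" else "NOT converged",
              length(x$history)))
  invisible(x)
}

compositions_upto <- function(cap, parts) {
  if (cap < parts) return(matrix(0L, 0, parts))
  if (parts == 1) return(matrix(seq_len(cap), ncol = 1))
  out <- list()
  for (first in seq_len(cap - parts + 1)) {
    rest <- compositions_upto(cap - first, parts - 1)
    out[[first]] <- cbind(first, rest)
  }
  do.call(rbind, out)
}

#' Enumerate a VCI configuration space
#'
#' `space[k]` is the maximum total number of quanta in a configuration that
#' excites exactly k modes (the usual (singles, doubles, triples, ...)
#' excitation-space convention).
#'
#' @param M number of modes
#' @param space integer caps per excitation class
#' @param max_per_mode optional cap on the quanta of any single mode (use
#'   nbasis - 1 to enumerate a complete direct-product space)
#' @return integer matrix (configurations x modes); row 1 is the ground
#'   configuration
#' @export
enumerate_configs <- function(M, space, max_per_mode = NULL) {
  rows <- list(integer(M))
  for (cls in seq_along(space)) {
    if (cls > M) break
    comps <- compositions_upto(space[cls], cls)
    if (!is.null(max_per_mode))
      comps <- comps[apply(comps, 1, max) <= max_per_mode, ,
                     drop = FALSE]
    if (!nrow(comps)) next
    sub <- utils::combn(M, cls)
    for (ci in seq_len(ncol(sub))) {
      block <- matrix(0L, nrow(comps), M)
      block[, sub[, ci]] <- comps
      rows[[length(rows) + 1]] <- block
    }
  }
  cfg <- do.call(rbind, lapply(rows, function(r)
    matrix(as.integer(r), ncol = M)))
  cfg
}

# grouped assembly of a many-mode operator in the VSCF-product basis:
# either accumulates the dense matrix (out = NULL) or applies the operator
# to a vector x
assemble_operator <- function(configs, vscf, nmr, comp = 1,
                              x = NULL, H = NULL, chunk = 50000L) {
  nconf <- nrow(configs)
  apply_mode <- is.null(H)
  if (apply_mode) y <- numeric(nconf)
  cols_of <- function(ids) match(ids, vscf$mode_ids)
  for (t in nmr$terms) {
    cols <- cols_of(t$modes)
    if (anyNA(cols)) stop("operator references modes outside the VSCF set")
    k <- length(cols)
    nq <- t$nq
    qb <- vscf$qb_cache[[as.character(nq)]]
    tup <- configs[, cols, drop = FALSE]
    tkey <- apply(tup, 1, paste, collapse = ",")
    uu <- !duplicated(tkey)
    U <- tup[uu, , drop = FALSE]
    uid <- match(tkey, tkey[uu])
    smax <- apply(U, 2, max)
    GI <- grid_index(nq, k)
    npts <- nrow(GI)
    G <- matrix(1, npts, nrow(U))
    for (m in seq_len(k)) {
      Bm <- qb$B %*% vscf$modals[[cols[m]]][, seq_len(smax[m] + 1),
                                            drop = FALSE]
      G <- G * Bm[GI[, m], U[, m] + 1, drop = FALSE]
    }
    v <- t$values[, comp]
    I <- crossprod(G, v * G)
    cfg0 <- configs
    cfg0[, cols] <- 0L
    gkey <- apply(cfg0, 1, paste, collapse = ",")
    for (grp in split(seq_len(nconf), gkey)) {
      tid <- uid[grp]
      if (apply_mode) {
        y[grp] <- y[grp] + I[tid, tid, drop = FALSE] %*% x[grp]
      } else {
        H[grp, grp] <- H[grp, grp] + I[tid, tid, drop = FALSE]
      }
    }
  }
  if (apply_mode) y else H
}

add_one_mode_operator <- function(configs, vscf, mats, H = NULL,
                                  x = NULL) {
  # mats: list per mode of a matrix in the modal basis
  nconf <- nrow(configs)
  apply_mode <- is.null(H)
  if (apply_mode) y <- numeric(nconf)
  for (i in seq_len(ncol(configs))) {
    cfg0 <- configs
    cfg0[, i] <- 0L
    gkey <- apply(cfg0, 1, paste, collapse = ",")
    A <- mats[[i]]
    for (grp in split(seq_len(nconf), gkey)) {
      sid <- configs[grp, i] + 1L
      if (apply_mode) {
        y[grp] <- y[grp] + A[sid, sid, drop = FALSE] %*% x[grp]
      } else {
        H[grp, grp] <- H[grp, grp] + A[sid, sid, drop = FALSE]
      }
    }
  }
  if (apply_mode) y else H
}

#' Vibrational configuration interaction in the VSCF-state basis
#'
#' Builds the VCI matrix over the product configurations of VSCF modals
#' (kinetic + n-mode potential terms), checks hermiticity, diagonalizes,
#' and assigns each eigenstate its leading configurations.
#'
#' @param vscf a converged `pq_vscf`
#' @param space excitation-space caps, e.g. `c(10, 9, 8, 7)` for maximum
#'   total quanta in single/double/triple/quadruple excitations
#' @param nstates number of eigenstates to retain (default: all)
#' @param max_per_mode optional per-mode quanta cap (see
#'   [enumerate_configs()])
#' @return object of class `pq_vci`: `E` (hartree, ascending), `E_cm`
#'   (cm^-1 above the ZPE), coefficient matrix `C` (configurations x
#'   states), `configs`, and leading-configuration `assignments`
#' @export
vci_solve <- function(vscf, space = c(10, 9, 8, 7), nstates = NULL,
                      max_per_mode = NULL) {
  M <- length(vscf$mode_ids)
  configs <- enumerate_configs(M, space, max_per_mode)
  if (max(configs) + 1 > vscf$nbasis)
    stop("excitation space needs quanta up to ", max(configs),
         " but only ", vscf$nbasis, " primitive functions per mode ",
         "are available; increase nbasis")
  nconf <- nrow(configs)
  H <- matrix(0, nconf, nconf)
  kin <- lapply(seq_len(M), function(i)
    crossprod(vscf$modals[[i]], vscf$K[[i]] %*% vscf$modals[[i]]))
  H <- add_one_mode_operator(configs, vscf, kin, H = H)
  H <- assemble_operator(configs, vscf, vscf$nmr, comp = 1, H = H)
  diag(H) <- diag(H) + vscf$nmr$V0[1]
  asym <- max(abs(H - t(H)))
  if (asym > 1e-10)
    warning("VCI matrix asymmetry ", signif(asym, 3),
            " exceeds 1e-10 before symmetrization")
  H <- (H + t(H)) / 2
  es <- eigen(H, symmetric = TRUE)
  ord <- seq_len(nconf)            # eigen returns descending; reverse
  E <- rev(es$values)
  C <- es$vectors[, rev(ord), drop = FALSE]
  if (!is.null(nstates) && nstates < nconf) {
    E <- E[seq_len(nstates)]
    C <- C[, seq_len(nstates), drop = FALSE]
  }
  for (s in seq_len(ncol(C))) {
    jmax <- which.max(abs(C[, s]))
    if (C[jmax, s] < 0) C[, s] <- -C[, s]
  }
  lead <- apply(abs(C), 2, which.max)
  assignments <- data.frame(
    state = seq_along(E), E_cm = hartree_to_cm(E - E[1]),
    leading = vapply(lead, function(j)
      paste(configs[j, ], collapse = ""), ""),
    coeff = vapply(seq_along(E), function(s) abs(C[lead[s], s]), 0))
  structure(list(E = E, E_cm = hartree_to_cm(E - E[1]), C = C,
                 configs = configs, space = space,
                 assignments = assignments, vscf = vscf),
            class = "pq_vci")
}

#' @export
print.pq_vci <- function(x, ...) {
  cat("<pq_vci> ", nrow(x$configs), " configurations, ZPE = ",
      sprintf("%.2f", hartree_to_cm(x$E[1])), " cm^-1\n", sep = "")
  print(head(x$assignments, 12), row.names = FALSE, digits = 4)
  invisible(x)
}

config_index <- function(vci, config) {
  hit <- which(apply(vci$configs, 1, function(r)
    all(r == config)))
  if (!length(hit)) NA_integer_ else hit[1]
}

#' Transition dipoles from the VCI ground state
#'
#' @param vci a `pq_vci`
#' @param dipole_nmr a 3-component `pq_nmr` of the dipole surface (its
#'   modes may be a subset of the VCI modes; the dipole is the identity on
#'   the rest)
#' @return matrix (states x 3) of <0|mu|f> in e bohr
#' @export
transition_dipoles <- function(vci, dipole_nmr) {
  C0 <- vci$C[, 1]
  out <- matrix(0, ncol(vci$C), 3)
  for (comp in seq_len(dipole_nmr$ncomp)) {
    y <- assemble_operator(vci$configs, vci$vscf, dipole_nmr,
                           comp = comp, x = C0)
    y <- y + dipole_nmr$V0[comp] * C0
    out[, comp] <- as.numeric(crossprod(vci$C, y))
  }
  out
}

# km/mol per (cm^-1 x (e bohr)^2); equals the familiar
# 2.50654 km/mol per (cm^-1 D^2) with 1 e bohr = 2.541746 D
KM_MOL_FACTOR <- 2.506540 * 2.541746^2

#' Infrared stick spectrum from a VCI solution
#'
#' Lines at E_f - E_0 with intensity proportional to the transition
#' frequency times the squared transition dipole; optionally a
#' Lorentzian-broadened trace.
#'
#' @param vci a `pq_vci`
#' @param dipole_nmr 3-component dipole `pq_nmr`
#' @param fwhm_cm optional Lorentzian FWHM for a broadened trace (cm^-1)
#' @param grid_cm frequency grid for the trace
#' @return object of class `pq_spectrum`: data.frame `lines` (freq_cm,
#'   intensity_km_mol, assignment) and optional `trace`
#' @export
ir_spectrum <- function(vci, dipole_nmr, fwhm_cm = NULL, grid_cm = NULL) {
  td <- transition_dipoles(vci, dipole_nmr)
  freq <- hartree_to_cm(vci$E - vci$E[1])
  mu2 <- rowSums(td^2)
  inten <- KM_MOL_FACTOR * freq * mu2
  lines <- data.frame(state = seq_along(freq), freq_cm = freq,
                      mu2 = mu2, intensity_km_mol = inten,
                      assignment = vci$assignments$leading)[-1, ]
  trace <- NULL
  if (!is.null(fwhm_cm)) {
    if (is.null(grid_cm))
      grid_cm <- seq(0, max(freq) * 1.05, length.out = 2000)
    hw <- fwhm_cm / 2
    y <- numeric(length(grid_cm))
    for (i in seq_len(nrow(lines)))
      y <- y + lines$intensity_km_mol[i] * hw^2 /
        ((grid_cm - lines$freq_cm[i])^2 + hw^2)
    trace <- data.frame(freq_cm = grid_cm, intensity = y)
  }
  structure(list(lines = lines, trace = trace), class = "pq_spectrum")
}

#' @export
print.pq_spectrum <- function(x, ...) {
  strong <- x$lines[x$lines$intensity_km_mol >
                      0.01 * max(x$lines$intensity_km_mol), ]
  cat("<pq_spectrum> ", nrow(x$lines), " lines; strongest:\n", sep = "")
  print(head(strong[order(-strong$intensity_km_mol), ], 10),
        row.names = FALSE, digits = 4)
  invisible(x)
}

#' Tabulate VCI coefficients of designated configurations
#'
#' For each requested eigenstate, reports the absolute VCI coefficient of
#' each labelled configuration (coefficients below `cutoff` print as "/",
#' the conventional marker for negligible contributions).
#'
#' @param vci a `pq_vci`
#' @param labels named list of integer configuration vectors
#' @param states eigenstate indices (default: the first 8 excited states)
#' @param cutoff reporting threshold
#' @return data.frame, one row per label, one column per state
#' @export
assign_states <- function(vci, labels, states = 2:9, cutoff = 0.005) {
  states <- states[states <= ncol(vci$C)]
  idx <- vapply(labels, function(cf) config_index(vci, cf), 0L)
  tab <- data.frame(configuration = names(labels))
  for (s in states) {
    col <- vapply(idx, function(j)
      if (is.na(j)) NA_real_ else abs(vci$C[j, s]), 0)
    tab[[paste0("state", s, "_", sprintf("%.0fcm", vci$E_cm[s]))]] <-
      ifelse(is.na(col) | col < cutoff, "/", sprintf("%.2f", col))
  }
  tab
}

#' Identify the lower and upper polariton states
#'
#' The two eigenstates with the largest absolute coefficient on the
#' cavity-fundamental configuration; the lower is the LP, the upper the UP.
#'
#' @param vci a `pq_vci`
#' @param cavity_mode_col column of the cavity mode in the configuration
#'   matrix
#' @return list with `lp`, `up` state indices, their energies (cm^-1 above
#'   ZPE), cavity coefficients and the Rabi splitting
#' @export
polariton_states <- function(vci, cavity_mode_col) {
  cf <- integer(ncol(vci$configs))
  cf[cavity_mode_col] <- 1L
  j <- config_index(vci, cf)
  if (is.na(j)) stop("cavity fundamental not in the configuration space")
  w <- abs(vci$C[j, ])
  w[1] <- 0                        # never the ground state
  top <- order(-w)[1:2]
  lp <- min(top); up <- max(top)
  list(lp = lp, up = up,
       E_lp_cm = vci$E_cm[lp], E_up_cm = vci$E_cm[up],
       coeff_lp = w[lp], coeff_up = w[up],
       rabi_cm = vci$E_cm[up] - vci$E_cm[lp])
}

#' Polaritonic IR spectrum of the model dimer by cavity VSCF/VCI
#'
#' Reduced-dimensional cav-VSCF/VCI over the high-frequency molecular
#' modes of the model dimer plus one cavity mode: builds the n-mode
#' representation of the effective potential (molecular + photon
#' coordinates on equal footing) and of the dipole, solves VSCF, then VCI,
#' and returns the stick spectrum with polariton assignments.
#'
#' @param model a `pq_model_surface`
#' @param g light-matter coupling factor (a.u.); 0 gives the bare-molecule
#'   spectrum plus an uncoupled photon ladder
#' @param omega_cm1 cavity frequency; defaults to the harmonic H-bonded
#'   OH-stretch frequency of the model
#' @param n_modes number of (highest-frequency) molecular modes to include
#' @param orders coupling orders for potential and dipole, default c(4, 3)
#' @param space VCI excitation-space caps
#' @param nbasis,nquad primitive basis size and per-order quadrature sizes
#' @param polarization `"oo-axis"` or a 3-vector
#' @param nstates eigenstates to retain
#' @return list with `vci`, `spectrum`, `polaritons`, `coupling`,
#'   `mode_sel` (selected molecular mode indices), `cavity_col`
#' @export
cavvci_spectrum <- function(model, g = 0.005, omega_cm1 = NULL,
                            n_modes = 6, orders = c(4, 3),
                            space = c(6, 5, 4, 4), nbasis = 14,
                            nquad = c(20, 16, 10, 8),
                            polarization = "oo-axis", nstates = 60) {
  basis <- model$basis
  nvib <- length(basis$freq)
  sel <- seq(nvib - n_modes + 1, nvib)
  wm <- basis$freq[sel]
  omega <- if (is.null(omega_cm1)) basis$freq[model$hb_mode] else
    cm_to_hartree(omega_cm1)
  e <- resolve_polarization(polarization, model$dimer_min)
  coupling <- coupling_volume_convert(omega = omega, g = g)
  ck <- sqrt(2 / omega^3) * g
  sm <- sqrt(rep(basis$masses, each = 3))
  Lsel <- basis$L[, sel, drop = FALSE]
  ref <- basis$reference$coords
  params <- model$params
  nm <- length(sel)

  to_cart <- function(Qm) {
    disp <- Qm %*% t(sweep(Lsel, 1, sm, "/"))
    sweep(disp, 2, ref, "+")
  }
  f_veff <- function(Q) {
    X <- to_cart(Q[, seq_len(nm), drop = FALSE])
    V <- pq_model_energy_batch(X, params)
    mue <- as.numeric(pq_model_dipole_batch(X, params) %*% e)
    V + 0.5 * omega^2 * (Q[, nm + 1] + ck * mue)^2
  }
  f_mu <- function(Q) {
    pq_model_dipole_batch(to_cart(Q), params)
  }

  nmr_v <- build_nmode_rep(f_veff, c(wm, omega),
                           order = min(orders[1], nm + 1), nquad = nquad)
  nmr_mu <- build_nmode_rep(f_mu, wm, order = min(orders[2], nm),
                            nquad = nquad, mode_ids = seq_len(nm),
                            ncomp = 3)
  vscf <- vscf_solve(nmr_v, nbasis = nbasis)
  vci <- vci_solve(vscf, space = space, nstates = nstates)
  spec <- ir_spectrum(vci, nmr_mu)
  pol <- if (g > 0) polariton_states(vci, nm + 1) else NULL
  list(vci = vci, spectrum = spec, polaritons = pol,
       coupling = coupling, mode_sel = sel, cavity_col = nm + 1,
       mode_freq_cm = hartree_to_cm(c(wm, omega)))
}

#' Anharmonic H-bonded OH-stretch fundamental of the model dimer
#'
#' Runs a bare-molecule (g = 0) cavity VSCF/VCI calculation and returns the
#' energy of the eigenstate led by the HB-stretch fundamental
#' configuration.  This is the natural resonant cavity frequency: the
#' experiment-facing fundamental lies well below the harmonic frequency
#' because of the Morse anharmonicity of the bonded OH.
#'
#' @param model a `pq_model_surface`
#' @param ... passed to [cavvci_spectrum()]
#' @return frequency in cm^-1
#' @export
hb_fundamental_cm <- function(model, ...) {
  sp <- cavvci_spectrum(model, g = 0, ...)
  hb_pos <- match(model$hb_mode, sp$mode_sel)
  cf <- replace(integer(ncol(sp$vci$configs)), hb_pos, 1L)
  idx <- config_index(sp$vci, cf)
  st <- which.max(abs(sp$vci$C[idx, ]))
  sp$vci$E_cm[st]
}
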