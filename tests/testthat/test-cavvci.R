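test_that("separable potentials have identically vanishing coupling terms", {
  w <- cm_to_hartree(c(1600, 3600, 3700))
  f <- function(Q) 0.5 * colSums(w^2 * t(Q)^2) + 2e-6 * Q[, 1]^3
  nmr <- build_nmode_rep(f, w, order = 3, nquad = 10)
  scale <- max(abs(nmr$terms[["1"]]$values))
  for (key in names(nmr$terms)) {
    t <- nmr$terms[[key]]
    if (length(t$modes) > 1)
      expect_lt(max(abs(t$values)), 1e-12 * scale)
  }
})

test_that("full-order representation reconstructs the potential at every grid point", {
  w <- cm_to_hartree(c(1600, 3600, 3700))
  f <- function(Q) 0.5 * colSums(w^2 * t(Q)^2) +
    1e-6 * Q[, 1] * Q[, 2] * Q[, 3]^2 + 1e-4 * exp(-rowSums(Q^2) / 50)
  nmr <- build_nmode_rep(f, w, order = 3, nquad = 6)
  rec <- nmr_reconstruct_top(nmr)
  expect_equal(rec$values[, 1], f(rec$Q), tolerance = 1e-12)
  expect_error(build_nmode_rep(f, w, order = 4, nquad = 6), "exceeds")
})

test_that("VCI fundamentals converge with coupling order on a 3-mode model", {
  w <- cm_to_hartree(c(1600, 3600, 3700))
  f <- function(Q) 0.5 * colSums(w^2 * t(Q)^2) +
    3e-6 * Q[, 1] * Q[, 2] * Q[, 3] + 2e-6 * Q[, 1]^2 * Q[, 2]
  fund <- vapply(2:3, function(ord) {
    nmr <- build_nmode_rep(f, w, order = ord, nquad = 10)
    vci <- vci_solve(vscf_solve(nmr, nbasis = 10), space = c(4, 4, 4))
    vci$E_cm[2]
  }, 0)
  nmr1 <- build_nmode_rep(f, w, order = 1, nquad = 10)
  f1 <- vci_solve(vscf_solve(nmr1, nbasis = 10), space = c(4, 4))$E_cm[2]
  # order-2 correction is bounded and order 3 changes less than order 2 did
  expect_lt(abs(fund[2] - fund[1]), abs(fund[1] - f1) + 1e-9)
  expect_lt(abs(fund[2] - fund[1]), 20)
})

test_that("uncoupled harmonic modes give exact VSCF energies", {
  w <- cm_to_hartree(c(1600, 3600))
  f <- function(Q) 0.5 * colSums(w^2 * t(Q)^2)
  nmr <- build_nmode_rep(f, w, order = 2, nquad = 16)
  vs0 <- vscf_solve(nmr, nbasis = 12)
  expect_true(vs0$converged)
  expect_equal(vs0$E, sum(w) / 2, tolerance = 1e-12)
  vs1 <- vscf_solve(nmr, nbasis = 12, target = c(1, 2))
  expect_equal(vs1$E, 1.5 * w[1] + 2.5 * w[2], tolerance = 1e-11)
})

test_that("VSCF is a variational upper bound to the exact 2-mode ground state", {
  w <- cm_to_hartree(c(1500, 3400))
  f <- function(Q) 0.5 * colSums(w^2 * t(Q)^2) +
    4e-6 * Q[, 1]^2 * Q[, 2] + 2e-5 * Q[, 1] * Q[, 2] +
    3e-7 * Q[, 1]^4
  nmr <- build_nmode_rep(f, w, order = 2, nquad = 20)
  vs <- vscf_solve(nmr, nbasis = 12)
  # independent oracle: dense direct-product diagonalization on the same
  # primitive basis with exact 2-D quadrature of f itself
  nb <- 12; nq <- 20
  qb <- polariqct:::quad_basis(nq, nb)
  Q1 <- qb$y / sqrt(w[1]); Q2 <- qb$y / sqrt(w[2])
  G2 <- expand.grid(p = seq_len(nq), q = seq_len(nq))
  fv <- f(cbind(Q1[G2$p], Q2[G2$q]))
  Gb <- qb$B[G2$p, rep(seq_len(nb), nb)] *
    qb$B[G2$q, rep(seq_len(nb), each = nb)]
  V <- crossprod(Gb, fv * Gb)
  K1 <- polariqct:::kinetic_primitive(nb, w[1])
  K2 <- polariqct:::kinetic_primitive(nb, w[2])
  H <- V + kronecker(K2, diag(nb)) + kronecker(diag(nb), K1)
  exact <- min(eigen((H + t(H)) / 2, symmetric = TRUE)$values)
  expect_gte(vs$E, exact - 1e-12)
  expect_lt(vs$E - exact, cm_to_hartree(50))
  # and full VCI over the complete product space recovers the oracle
  vci <- vci_solve(vs, space = c(11, 22), max_per_mode = 11)
  expect_lt(abs(hartree_to_cm(vci$E[1] - exact)), 1e-6)
  expect_lt(max(abs(hartree_to_cm(
    vci$E[2:6] - eigen((H + t(H)) / 2,
                       symmetric = TRUE)$values[nb^2 - (1:5)]))), 1e-6)
})

test_that("g = 0 VCI is block diagonal: photon ladder rides on molecular levels", {
  w <- cm_to_hartree(3550); wc <- cm_to_hartree(3500)
  # anharmonic molecular mode, uncoupled photon mode
  f <- function(Q) 0.5 * w^2 * Q[, 1]^2 + 3e-6 * Q[, 1]^3 +
    0.5 * wc^2 * Q[, 2]^2
  nmr <- build_nmode_rep(f, c(w, wc), order = 2, nquad = 16)
  vci <- vci_solve(vscf_solve(nmr, nbasis = 12), space = c(6, 6))
  # cavity fundamental sits exactly omega_c above the ZPE, unmixed
  cf <- polariqct:::config_index(vci, c(0L, 1L))
  state <- which.max(abs(vci$C[cf, ]))
  expect_equal(vci$E_cm[state], hartree_to_cm(wc), tolerance = 1e-6)
  expect_gt(abs(vci$C[cf, state]), 0.9999)
  mol_configs <- which(vci$configs[, 1] > 0 & vci$configs[, 2] == 0)
  expect_lt(max(abs(vci$C[mol_configs, state])), 0.005)
  # every cavity-excited level = molecular level + n_c omega_c
  mol_fund <- vci$E_cm[which.max(abs(vci$C[polariqct:::config_index(
    vci, c(1L, 0L)), ]))]
  comb <- polariqct:::config_index(vci, c(1L, 1L))
  comb_state <- which.max(abs(vci$C[comb, ]))
  expect_equal(vci$E_cm[comb_state], mol_fund + hartree_to_cm(wc),
               tolerance = 1e-6)
})

test_that("resonant cavity + harmonic mode reproduce the quadratic polariton oracle", {
  w <- cm_to_hartree(3600); wc <- w
  lam <- 0.05; mu0 <- 0.3
  rabi <- c()
  for (g in c(0.001, 0.002, 0.005, 0.008, 0.01)) {
    ck <- sqrt(2 / wc^3) * g
    f <- function(Q) 0.5 * w^2 * Q[, 1]^2 +
      0.5 * wc^2 * (Q[, 2] + ck * (mu0 + lam * Q[, 1]))^2
    nmr <- build_nmode_rep(f, c(w, wc), order = 2, nquad = 20)
    vci <- vci_solve(vscf_solve(nmr, nbasis = 14), space = c(8, 8))
    K <- matrix(c(w^2 + 2 * g^2 * lam^2 / wc, sqrt(2 * wc) * g * lam,
                  sqrt(2 * wc) * g * lam, wc^2), 2)
    ana <- hartree_to_cm(sort(sqrt(eigen(K)$values)))
    expect_lt(max(abs(vci$E_cm[2:3] - ana)), 0.1)
    # Rabi-doublet limit: both polaritons carry ~1/sqrt(2) cavity weight
    pol <- polariton_states(vci, 2)
    if (g <= 0.002) {
      expect_gt(pol$coeff_lp, 0.6)
      expect_gt(pol$coeff_up, 0.6)
    }
    rabi <- c(rabi, pol$rabi_cm)
  }
  expect_true(all(diff(rabi) > 0))    # splitting grows with g
})

test_that("VCI zero-point energy decreases weakly as the excitation space grows", {
  w <- cm_to_hartree(c(1550, 3650))
  f <- function(Q) 0.5 * colSums(w^2 * t(Q)^2) +
    4e-6 * Q[, 1]^2 * Q[, 2] + 2e-7 * Q[, 2]^4
  vs <- vscf_solve(build_nmode_rep(f, w, order = 2, nquad = 18),
                   nbasis = 12)
  z <- vapply(list(c(2, 2), c(4, 4), c(8, 8), c(11, 11)), function(sp)
    vci_solve(vs, space = sp)$E[1], 0)
  expect_true(all(diff(z) <= 1e-13))
})

test_that("IR intensities obey selection rules and track the dipole", {
  w <- cm_to_hartree(3600)
  f <- function(Q) 0.5 * w^2 * Q[, 1]^2
  nmr <- build_nmode_rep(f, w, order = 1, nquad = 16)
  vci <- vci_solve(vscf_solve(nmr, nbasis = 12), space = 8)
  # zero dipole: no intensity anywhere
  mu0fun <- function(Q) matrix(0, nrow(Q), 3)
  sp0 <- ir_spectrum(vci, build_nmode_rep(mu0fun, w, order = 1,
                                          nquad = 16, ncomp = 3))
  expect_lt(max(sp0$lines$intensity_km_mol), 1e-20)
  # linear dipole on a harmonic mode: only the fundamental is bright
  mulin <- function(Q) cbind(0.1 + 0.2 * Q[, 1], 0, 0)
  sp <- ir_spectrum(vci, build_nmode_rep(mulin, w, order = 1,
                                         nquad = 16, ncomp = 3))
  bright <- sp$lines$intensity_km_mol / max(sp$lines$intensity_km_mol)
  expect_equal(which.max(bright), 1L)        # the fundamental
  expect_lt(max(bright[-1]), 1e-8)
  # analytic check: |<0|mu|1>|^2 = lam^2 / (2 w)
  expect_equal(sp$lines$mu2[1], 0.2^2 / (2 * w), tolerance = 1e-10)
})

test_that("VCI coefficient vectors are normalized and the matrix is symmetric", {
  w <- cm_to_hartree(c(1600, 3300))
  f <- function(Q) 0.5 * colSums(w^2 * t(Q)^2) + 3e-5 * Q[, 1] * Q[, 2]
  vci <- vci_solve(vscf_solve(build_nmode_rep(f, w, order = 2,
                                              nquad = 14),
                              nbasis = 10), space = c(5, 5))
  norms <- colSums(vci$C^2)
  expect_equal(norms, rep(1, length(norms)), tolerance = 1e-10)
  expect_true(all(diff(vci$E) >= -1e-12))
})

test_that("assign_states reports the conventional coefficient table", {
  w <- cm_to_hartree(3600); wc <- w
  g <- 0.003; lam <- 0.05; ck <- sqrt(2 / wc^3) * g
  f <- function(Q) 0.5 * w^2 * Q[, 1]^2 +
    0.5 * wc^2 * (Q[, 2] + ck * lam * Q[, 1])^2
  vci <- vci_solve(vscf_solve(build_nmode_rep(f, c(w, wc), order = 2,
                                              nquad = 18),
                              nbasis = 12), space = c(6, 6))
  tab <- assign_states(vci, list(`mol fund` = c(1L, 0L),
                                 cavity = c(0L, 1L),
                                 `mol overtone` = c(2L, 0L)),
                       states = 2:3)
  expect_equal(nrow(tab), 3)
  # both polaritons mix molecule and cavity strongly
  expect_true(all(tab[1, -1] != "/"))
  expect_true(all(tab[2, -1] != "/"))
  # the overtone plays no role in a bilinear problem
  expect_true(all(tab[3, -1] == "/"))
})
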