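test_that("model energies are invariant under rigid motions and H permutation", {
  m <- the_model()
  set.seed(1)
  g0 <- m$dimer_min
  e0 <- evaluate_potential(m$potential, g0)
  mu0 <- evaluate_dipole(m$dipole, g0)
  for (i in 1:10) {
    R <- random_rotation()
    shift <- runif(3, -5, 5)
    g1 <- rotate_geometry(g0, R, shift)
    expect_lt(abs(evaluate_potential(m$potential, g1) - e0), 1e-12)
    # dipole rotates covariantly
    expect_lt(max(abs(evaluate_dipole(m$dipole, g1) -
                        as.numeric(R %*% mu0))), 1e-12)
  }
  # swap the two H atoms of the donor monomer
  cm <- coord_matrix(g0)
  gsw <- geometry(g0$symbols, as.numeric(t(cm[c(1, 3, 2, 4, 5, 6), ])))
  expect_equal(evaluate_potential(m$potential, gsw), e0, tolerance = 1e-13)
  # and exchange the two monomers
  gex <- geometry(g0$symbols, as.numeric(t(cm[c(4, 5, 6, 1, 2, 3), ])))
  expect_equal(evaluate_potential(m$potential, gex), e0, tolerance = 1e-13)
})

test_that("zero of energy: relaxed minimum sits at -D_HB, separated monomers at 0", {
  m <- the_model()
  expect_equal(evaluate_potential(m$potential, m$dimer_min), -m$D_HB,
               tolerance = 1e-12)
  expect_equal(evaluate_potential(m$monomer_potential, m$monomer_min), 0,
               tolerance = 1e-13)
  # pull the relaxed monomers 60 bohr apart: many-body limit
  far <- m$dimer_min
  x <- coord_matrix(m$monomer_min)
  far <- geometry(c("O", "H", "H", "O", "H", "H"),
                  c(as.numeric(t(x)), as.numeric(t(sweep(x, 2,
                                                         -c(60, 0, 0))))))
  expect_lt(abs(evaluate_potential(m$potential, far)), 1e-10)
})

test_that("analytic gradients match central finite differences", {
  m <- the_model()
  set.seed(2)
  for (i in 1:10) {
    g <- set_coords(m$dimer_min,
                    m$dimer_min$coords + runif(18, -0.05, 0.05))
    ga <- evaluate_gradient(m$potential, g)
    noan <- potential_surface(m$potential$energy, label = "fd route")
    gf <- evaluate_gradient(noan, g, fd_step = 1e-4)
    expect_lt(max(abs(ga - gf)), 1e-8)
  }
  # dipole jacobian against finite differences
  g <- set_coords(m$dimer_min, m$dimer_min$coords + 0.03)
  Ja <- evaluate_dipole_jacobian(m$dipole, g)
  nojac <- dipole_surface(m$dipole$dipole, label = "fd route")
  Jf <- evaluate_dipole_jacobian(nojac, g, fd_step = 1e-4)
  expect_lt(max(abs(Ja - Jf)), 1e-8)
})

test_that("gradient vanishes at stationary points; FD is exact on quadratics", {
  m <- the_model()
  expect_lt(sqrt(sum(evaluate_gradient(m$potential, m$dimer_min)^2)),
            1e-6)
  hd <- harmonic_diatomic(k = 0.7)
  g <- set_coords(hd$geom, hd$geom$coords + c(0, 0, 0, 0, 0, 0.3))
  for (h in c(1e-2, 1e-3, 1e-5))
    expect_equal(evaluate_gradient(hd$potential, g, fd_step = h),
                 c(0, 0, -0.7 * 0.3, 0, 0, 0.7 * 0.3),
                 tolerance = 1e-9)
})

test_that("energy near the minimum matches the Hessian quadratic form", {
  m <- the_model()
  H <- hessian_fd(m$potential, m$dimer_min)
  set.seed(3)
  for (i in 1:5) {
    d <- runif(18, -1, 1)
    d <- d / sqrt(sum(d^2)) * 0.02
    e <- evaluate_potential(m$potential,
                            set_coords(m$dimer_min,
                                       m$dimer_min$coords + d)) + m$D_HB
    quad <- 0.5 * as.numeric(t(d) %*% H %*% d)
    expect_lt(abs(e - quad) / quad, 0.05)
  }
})

test_that("many-body assembly reproduces the direct model surface", {
  m <- the_model()
  mono <- list(potential = m$monomer_potential, dipole = m$monomer_dipole)
  comp <- assemble_many_body(list(mono, mono), m$pair_potential,
                             fragment_index = c(1, 1, 1, 2, 2, 2))
  set.seed(4)
  for (i in 1:5) {
    g <- set_coords(m$dimer_min,
                    m$dimer_min$coords + runif(18, -0.1, 0.1))
    expect_equal(evaluate_potential(comp$potential, g),
                 evaluate_potential(m$potential, g), tolerance = 1e-13)
    expect_equal(evaluate_gradient(comp$potential, g),
                 as.numeric(evaluate_gradient(m$potential, g)),
                 tolerance = 1e-12)
  }
  # dipole of the composite at large separation = sum of monomer dipoles
  x <- coord_matrix(m$monomer_min)
  far <- geometry(c("O", "H", "H", "O", "H", "H"),
                  c(as.numeric(t(x)),
                    as.numeric(t(sweep(x, 2, -c(50, 0, 0))))))
  expect_equal(evaluate_dipole(comp$dipole, far),
               2 * evaluate_dipole(m$monomer_dipole, m$monomer_min),
               tolerance = 1e-10)
  # zero pair term: composite = sum of monomers
  comp0 <- assemble_many_body(list(mono, mono), NULL,
                              fragment_index = c(1, 1, 1, 2, 2, 2))
  expect_equal(evaluate_potential(comp0$potential, far), 0,
               tolerance = 1e-13)
  expect_lt(abs(evaluate_potential(comp0$potential, m$dimer_min) -
                  (evaluate_potential(m$potential, m$dimer_min) -
                     evaluate_potential(m$pair_potential, m$dimer_min))),
            1e-12)
})

test_that("mismatched fragment indices are rejected", {
  m <- the_model()
  mono <- list(potential = m$monomer_potential)
  comp <- assemble_many_body(list(mono, mono), NULL,
                             fragment_index = c(1, 1, 1, 2, 2))
  expect_error(evaluate_potential(comp$potential, m$dimer_min),
               "fragment_index")
})

test_that("the model builder enforces an open dissociation channel", {
  # a very deep intermolecular well exceeds one OH-stretch quantum
  expect_error(
    model_dimer_surface(model_dimer_parameters(d_ho = 0.08)),
    "channel closed|not below")
  expect_error(model_dimer_parameters(d_oh = -1), "positive")
})

test_that("the model dimer has 12 modes: 4 stretch-like and 2 bend-like high-frequency", {
  m <- the_model()
  f <- m$basis$freq_cm
  expect_length(f, 12)
  expect_true(all(f > 0))
  expect_equal(sum(f > 3000), 4)             # stretch-like
  expect_equal(sum(f > 1200 & f < 2000), 2)  # bend-like
  expect_equal(sum(f < 1200), 6)             # intermolecular
  # H-bonded stretch within the calibration window
  expect_gt(f[m$hb_mode], 3400)
  expect_lt(f[m$hb_mode], 3700)
  # binding energy window and quasi-classically open channel:
  # one HB-stretch quantum exceeds the quantum dissociation threshold
  # D0 = D_HB + ZPE(2 monomers) - ZPE(dimer)
  D0 <- m$D_HB + sum(m$monomer_basis$freq) - sum(m$basis$freq) / 2
  expect_gt(m$basis$freq[m$hb_mode], D0)
  expect_gt(hartree_to_cm(m$D_HB), 1000)
  expect_lt(hartree_to_cm(m$D_HB), 1500)
})

test_that("fragment partition recovers monomers and flags ambiguity", {
  m <- the_model()
  fr <- fragment_partition(m$dimer_min)
  expect_length(fr, 2)
  for (f in fr) expect_setequal(f$symbols, c("O", "H", "H"))
  expect_setequal(unlist(lapply(fr, attr, "index")), 1:6)
  # dissociated frame: both fragments intact monomers
  x <- coord_matrix(m$monomer_min)
  far <- geometry(c("O", "H", "H", "O", "H", "H"),
                  c(as.numeric(t(x)),
                    as.numeric(t(sweep(x, 2, -c(22.7, 0, 0))))))
  fr2 <- fragment_partition(far)
  expect_equal(attr(fr2[[1]], "index"), 1:3)
  # proton-transfer-like frame: H equidistant between the oxygens
  amb <- geometry(c("O", "H", "H", "O", "H", "H"),
                  c(0, 0, 0,   1.8, 0, 0,   0, 1.8, 0,
                    6, 0, 0,   3, 0, 0,     6, 1.8, 0))
  expect_error(fragment_partition(amb), "equidistant")
})

test_that("non-finite surface evaluations carry the offending geometry", {
  bad <- potential_surface(function(g) NaN, label = "broken")
  g <- the_model()$monomer_min
  err <- tryCatch(evaluate_potential(bad, g), error = identity)
  expect_s3_class(err$geometry, "pq_geometry")
})
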