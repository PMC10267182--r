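test_that("forced zero phases put every mode at its turning point", {
  m <- the_model()
  spec <- sampling_spec(quanta = rep(0, 12), rescale = "none")
  s <- normal_mode_sample(m$basis, spec, phases = rep(0, 12))
  qp <- cartesian_to_modes(m$basis, s$geometry, s$velocities)
  expect_lt(max(abs(qp$P)), 1e-8)                 # kinetic energy ~ 0
  # harmonic potential energy equals the ZPE sum
  expect_equal(sum(0.5 * m$basis$freq^2 * s$Q^2),
               sum(m$basis$freq) / 2, tolerance = 1e-12)
  expect_equal(s$Q, sqrt(2 * s$energies) / m$basis$freq,
               tolerance = 1e-12)
})

test_that("sampled states carry no angular momentum or COM drift", {
  m <- the_model()
  set.seed(10)
  for (i in 1:10) {
    s <- normal_mode_sample(m$basis, sampling_spec(), m$potential,
                            hb_mode = m$hb_mode)
    expect_lt(sqrt(sum(angular_momentum(s$geometry,
                                        s$velocities)^2)), 1e-10)
    v <- matrix(s$velocities, ncol = 3, byrow = TRUE)
    expect_lt(max(abs(colSums(v * s$geometry$masses))), 1e-10)
  }
})

test_that("Monte-Carlo: per-mode energies are exact as drawn, near-exact after J removal", {
  m <- the_model()
  spec <- sampling_spec(rescale = "none")
  set.seed(11)
  ndraw <- 500
  Edraw <- Epost <- matrix(0, ndraw, 12)
  for (i in seq_len(ndraw)) {
    s <- normal_mode_sample(m$basis, spec, hb_mode = m$hb_mode)
    Edraw[i, ] <- 0.5 * s$P^2 + 0.5 * m$basis$freq^2 * s$Q^2
    qp <- cartesian_to_modes(m$basis, s$geometry, s$velocities)
    Epost[i, ] <- 0.5 * qp$P^2 + 0.5 * m$basis$freq^2 * qp$Q^2
  }
  target <- (resolve_hb_quanta(m) + 0.5) * m$basis$freq
  # the quasi-classical draw carries the quantized energy exactly
  expect_lt(max(abs(sweep(Edraw, 2, target)) / rep(target,
                                                   each = ndraw)),
            1e-10)
  # enforcing J = 0 perturbs the mode energies only slightly (the dimer
  # is floppy; displaced geometries carry some vibrational angular
  # momentum that the projection removes)
  for (k in 1:12) {
    se <- sd(Epost[, k]) / sqrt(ndraw)
    expect_lt(abs(mean(Epost[, k]) - target[k]),
              3 * se + 0.05 * target[k])
  }
})

test_that("cavity initialization gives exactly half a quantum of field energy", {
  m <- the_model()
  mode <- cavity_mode(omega_cm1 = 3600, polarization = c(0, 0, 1))
  cp <- coupling_volume_convert(omega = mode$omega, g = 0.005)
  mu <- evaluate_dipole(m$dipole, m$dimer_min)
  qstar <- -sqrt(2 / mode$omega^3) * cp$g * sum(mu * mode$e)
  set.seed(12)
  disp <- replicate(2000, {
    mm <- initialize_cavity(mode, cp, mu)
    ef <- 0.5 * mm$p^2 +
      0.5 * mode$omega^2 * (mm$q + sqrt(2 / mode$omega^3) * cp$g *
                              sum(mu * mode$e))^2
    expect_equal(ef, mode$omega / 2, tolerance = 1e-12)
    mm$q - qstar
  })
  # phase-averaged displacement about q* vanishes within MC error
  expect_lt(abs(mean(disp)), 3 * sd(disp) / sqrt(length(disp)))
  # g = 0: centred at q = 0 with E_cav = hbar omega / 2
  c0 <- coupling_volume_convert(omega = mode$omega, g = 0)
  mm <- initialize_cavity(mode, c0, mu, phase = 0.3)
  expect_equal(0.5 * mm$p^2 + 0.5 * mode$omega^2 * mm$q^2,
               mode$omega / 2, tolerance = 1e-14)
})

test_that("symplectic propagation: no secular drift over 10^6 steps", {
  k <- 0.5
  hd <- harmonic_diatomic(k = k, m_amu = 1)
  mu <- amu_to_me(1) / 2
  w <- sqrt(k / mu)
  dt_fs <- au_to_fs(0.2 / w)            # omega dt = 0.2
  dt <- 0.2 / w
  g <- set_coords(hd$geom, hd$geom$coords + c(0, 0, 0, 0, 0, 0.2))
  tr <- propagate(g, numeric(6), hd$potential,
                  integrator = integrator_spec(
                    dt_fs = dt_fs, t_max_ps = 1e6 * dt_fs / 1000,
                    output_stride = 10000, r_crit_ang = Inf),
                  track_roo = FALSE)
  E <- tr$E_mol
  expect_gte(tr$steps, 1e6)
  # instantaneous error oscillates, bounded at O((omega dt)^2)
  expect_lt(max(abs(E - E[1])) / E[1], 0.2^2)
  # velocity Verlet conserves the harmonic shadow invariant
  # mu vrel^2 + k (1 - (w dt)^2/4) x^2 exactly: no secular growth
  shadow <- function(geom, vel) {
    x <- atom_distance(geom, 1, 2) - 2
    vrel <- vel[6] - vel[3]
    mu * vrel^2 / 2 + 0.5 * k * (1 - (w * dt)^2 / 4) * x^2
  }
  I0 <- shadow(g, numeric(6))
  I1 <- shadow(tr$final$geometry, tr$final$velocities)
  expect_lt(abs(I1 - I0) / I0, 1e-10)
})

test_that("propagation is time-reversible", {
  m <- the_model()
  set.seed(13)
  s <- normal_mode_sample(m$basis, sampling_spec(), m$potential,
                          hb_mode = m$hb_mode)
  it <- integrator_spec(t_max_ps = 1e4 * 0.12 / 1000, output_stride = 1e4,
                        stop_at_dissociation = FALSE)
  fwd <- propagate(s$geometry, s$velocities, m$potential, m$dipole,
                   integrator = it)
  back <- propagate(fwd$final$geometry, -fwd$final$velocities,
                    m$potential, m$dipole, integrator = it)
  expect_lt(max(abs(back$final$geometry$coords - s$geometry$coords)),
            1e-8)
})

test_that("g = 0 propagation is bit-identical to a cavity-free run", {
  m <- the_model()
  set.seed(14)
  s <- normal_mode_sample(m$basis, sampling_spec(), m$potential,
                          hb_mode = m$hb_mode)
  it <- integrator_spec(t_max_ps = 0.5, stop_at_dissociation = FALSE)
  bare <- propagate(s$geometry, s$velocities, m$potential, m$dipole,
                    integrator = it)
  mode <- cavity_mode(omega_cm1 = 3600, polarization = c(0, 0, 1),
                      q = 0.3, p = 0.01)
  c0 <- coupling_volume_convert(omega = mode$omega, g = 0)
  with_cav <- propagate(s$geometry, s$velocities, m$potential, m$dipole,
                        mode, c0, integrator = it)
  expect_identical(with_cav$final$geometry$coords,
                   bare$final$geometry$coords)
  expect_identical(with_cav$final$velocities, bare$final$velocities)
})

test_that("dissociation detection and threshold semantics", {
  m <- the_model()
  expect_false(detect_dissociation(m$dimer_min))
  x <- coord_matrix(m$monomer_min)
  mk <- function(dx) geometry(c("O", "H", "H", "O", "H", "H"),
                              c(as.numeric(t(x)),
                                as.numeric(t(sweep(x, 2, -c(dx, 0, 0))))))
  expect_false(detect_dissociation(mk(angstrom_to_bohr(9.9))))
  expect_true(detect_dissociation(mk(angstrom_to_bohr(10.1))))
})

test_that("ZPE-only preparation stays bound for 25 ps", {
  m <- the_model()
  set.seed(15)
  s <- normal_mode_sample(m$basis, sampling_spec(quanta = rep(0, 12)),
                          m$potential)
  tr <- propagate(s$geometry, s$velocities, m$potential, m$dipole,
                  integrator = integrator_spec())
  expect_false(tr$dissociated)
})

test_that("ensembles are seed-reproducible with monotone P(t)", {
  m <- the_model()
  it <- integrator_spec(t_max_ps = 4)
  e1 <- run_ensemble(8, m, integrator = it, seed = 99)
  e2 <- run_ensemble(8, m, integrator = it, seed = 99)
  expect_identical(e1$t_diss_ps, e2$t_diss_ps)
  expect_identical(e1$P_t, e2$P_t)
  expect_true(all(diff(e1$P_t) >= 0))
  expect_true(all(e1$P_t >= 0 & e1$P_t <= 1))
})

test_that("half-lifetime: first-crossing interpolation and exponential oracle", {
  # four trajectories dissociating at 1, 2, 3, 4 ps
  tg <- seq(0, 5, by = 0.5)
  td <- c(1, 2, 3, 4)
  P <- vapply(tg, function(t) mean(td <= t), 0)
  expect_equal(half_lifetime(tg, P), 2.0)
  expect_true(is.na(half_lifetime(tg, P * 0.4)))
  # exponential dissociation times: tau_0.5 = ln(2)/k
  set.seed(16)
  k <- 0.3
  td <- rexp(1e4, k)
  tg <- seq(0, 30, by = 0.01)
  P <- vapply(tg, function(t) mean(td <= t), 0)
  expect_lt(abs(half_lifetime(tg, P) - log(2) / k) / (log(2) / k), 0.03)
})

test_that("disjoint seeds agree within binomial error on the dissociated fraction", {
  m <- the_model()
  it <- integrator_spec(t_max_ps = 6)
  eA <- run_ensemble(60, m, integrator = it, seed = 1001)
  eB <- run_ensemble(60, m, integrator = it, seed = 2002)
  pA <- mean(!is.na(eA$t_diss_ps))
  pB <- mean(!is.na(eB$t_diss_ps))
  se <- sqrt(pA * (1 - pA) / 60 + pB * (1 - pB) / 60 + 1e-12)
  expect_lt(abs(pA - pB), 3 * se + 0.05)
})
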