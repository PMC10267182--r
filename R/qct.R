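#' Quasi-classical sampling specification
#'
#' @param quanta integer quanta per vibrational mode, or `"zpe+hb"` (the
#'   default) for zero-point energy in every mode plus one extra quantum in
#'   the H-bonded OH stretch
#' @param rescale `"kinetic"` (default) rescales velocities after
#'   angular-momentum removal so the total internal energy matches the
#'   harmonic target sum((n_i + 1/2) hbar omega_i); `"none"` leaves the raw
#'   normal-mode draw untouched
#' @param target_J total angular momentum (only 0 is supported)
#' @return object of class `pq_sampling_spec`
#' @export
sampling_spec <- function(quanta = "zpe+hb",
                          rescale = c("kinetic", "none"), target_J = 0) {
  rescale <- match.arg(rescale)
  if (!identical(quanta, "zpe+hb")) {
    quanta <- as.integer(quanta)
    if (any(quanta < 0)) stop("quanta must be non-negative")
  }
  if (target_J != 0) stop("only target_J = 0 is implemented")
  structure(list(quanta = quanta, rescale = rescale, target_J = target_J),
            class = "pq_sampling_spec")
}

#' Integration specification for trajectory propagation
#'
#' @param dt_fs time step (fs), default 0.12
#' @param t_max_ps maximum propagation time (ps), default 25
#' @param output_stride record energies/distances every this many steps
#' @param r_crit_ang O-O dissociation threshold (angstrom), default 10
#' @param stop_at_dissociation terminate at the first threshold crossing
#' @return object of class `pq_integrator_spec`
#' @export
integrator_spec <- function(dt_fs = 0.12, t_max_ps = 25,
                            output_stride = 100, r_crit_ang = 10,
                            stop_at_dissociation = TRUE) {
  if (dt_fs <= 0 || t_max_ps * 1000 <= dt_fs)
    stop("need dt_fs > 0 and t_max > dt")
  structure(list(dt_fs = dt_fs, t_max_ps = t_max_ps,
                 output_stride = as.integer(output_stride),
                 r_crit_ang = r_crit_ang,
                 stop_at_dissociation = stop_at_dissociation),
            class = "pq_integrator_spec")
}

resolve_quanta <- function(basis, spec, hb_mode = NULL) {
  nvib <- length(basis$freq)
  if (identical(spec$quanta, "zpe+hb")) {
    if (is.null(hb_mode)) stop("quanta = 'zpe+hb' needs the H-bonded ",
                               "stretch mode index")
    q <- integer(nvib)
    q[hb_mode] <- 1L
    q
  } else {
    if (length(spec$quanta) != nvib)
      stop("quanta must have one entry per vibrational mode (", nvib, ")")
    spec$quanta
  }
}

#' Draw quasi-classical initial conditions by normal-mode sampling
#'
#' Each mode i receives harmonic energy E_i = (n_i + 1/2) hbar omega_i at a
#' uniformly random phase: Q_i = sqrt(2 E_i)/omega_i cos(phi),
#' P_i = -sqrt(2 E_i) sin(phi).  The Cartesian state is reconstructed,
#' centre-of-mass motion and total angular momentum are removed, and (by
#' default) velocities are rescaled so the total internal energy matches the
#' harmonic target.
#'
#' @param basis a `pq_modes` at a minimum (all frequencies positive)
#' @param spec a `pq_sampling_spec`
#' @param surface optional `pq_potential` used for the energy-matching
#'   rescale (required when `rescale = "kinetic"`)
#' @param hb_mode H-bonded stretch mode index (for `quanta = "zpe+hb"`)
#' @param phases optional fixed phases (radians) instead of random ones
#' @param max_attempts resample cap when a draw leaves no kinetic energy to
#'   rescale
#' @return list with `geometry`, `velocities`, `Q`, `P`, `phases`,
#'   `energies` (per-mode harmonic energies of the draw), `target_energy`
#'   and `rescale_factor`
#' @export
normal_mode_sample <- function(basis, spec = sampling_spec(),
                               surface = NULL, hb_mode = NULL,
                               phases = NULL, max_attempts = 50) {
  if (any(basis$freq <= 0))
    stop("sampling requires a basis at a minimum (all frequencies > 0)")
  n <- resolve_quanta(basis, spec, hb_mode)
  w <- basis$freq
  E <- (n + 0.5) * w
  target <- sum(E)
  if (spec$rescale == "kinetic" && is.null(surface))
    stop("rescale = 'kinetic' needs the potential surface")
  for (attempt in seq_len(max_attempts)) {
    phi <- if (is.null(phases)) runif(length(w), 0, 2 * pi) else phases
    Q <- sqrt(2 * E) / w * cos(phi)
    P <- -sqrt(2 * E) * sin(phi)
    st <- modes_to_cartesian(basis, Q, P)
    geom <- st$geometry
    vel <- remove_angular_momentum(geom, st$velocities)
    fac <- 1
    if (spec$rescale == "kinetic") {
      dV <- evaluate_potential(surface, geom) -
        evaluate_potential(surface, basis$reference)
      ke <- 0.5 * sum(rep(geom$masses, each = 3) * vel^2)
      if (target - dV <= 0 || ke <= 0) {
        if (!is.null(phases))
          stop("fixed phases leave no kinetic energy to rescale")
        next
      }
      fac <- sqrt((target - dV) / ke)
      vel <- vel * fac
    }
    return(list(geometry = geom, velocities = vel, Q = Q, P = P,
                phases = phi, energies = E, quanta = n,
                target_energy = target, rescale_factor = fac,
                attempts = attempt))
  }
  stop("normal-mode sampling failed: no draw left positive kinetic ",
       "energy after ", max_attempts, " attempts")
}

#' Initialize a cavity mode with its harmonic zero-point energy
#'
#' The photon coordinate is displaced about the field minimum
#' q* = -sqrt(2/omega^3) g (mu . e) at a random phase such that the field
#' energy is exactly (1/2) hbar omega at t = 0.
#'
#' @param mode a `pq_cavity_mode`
#' @param coupling a `pq_coupling`
#' @param mu_t0 molecular dipole vector at t = 0 (e bohr)
#' @param phase optional fixed phase
#' @return the mode with `q`, `p` set
#' @export
initialize_cavity <- function(mode, coupling, mu_t0, phase = NULL) {
  w <- mode$omega
  ck <- cavity_disp_coef(mode, coupling)
  qstar <- -ck * sum(mu_t0 * mode$e)
  if (is.null(phase)) phase <- runif(1, 0, 2 * pi)
  Ef <- 0.5 * w                     # harmonic ZPE of the photon mode
  mode$q <- qstar + sqrt(2 * Ef) / w * cos(phase)
  mode$p <- -sqrt(2 * Ef) * sin(phase)
  mode
}

#' Has this frame dissociated?
#'
#' @param geom a two-water `pq_geometry`
#' @param r_crit_ang O-O threshold in angstrom
#' @return TRUE iff R_OO >= threshold
#' @export
detect_dissociation <- function(geom, r_crit_ang = 10) {
  r_oo(geom) >= angstrom_to_bohr(r_crit_ang)
}

native_model <- function(potential, dipole) {
  identical(potential$native, "dimer") &&
    (is.null(dipole) || identical(dipole$native, "dimer")) &&
    (is.null(dipole) ||
       identical(potential$params, dipole$params))
}

#' Propagate a (possibly cavity-coupled) trajectory
#'
#' NVE velocity-Verlet propagation of the completed-square Hamiltonian.  On
#' the built-in model surface a compiled propagator is used; any other
#' surface is propagated by an equivalent R loop (slower, intended for toy
#' systems and tests).  The run terminates at `t_max` or, by default, at the
#' first crossing of the O-O dissociation threshold.
#'
#' @param geom starting `pq_geometry`
#' @param velocities 3N Cartesian velocities (a.u.)
#' @param potential a `pq_potential`
#' @param dipole a `pq_dipole` (required when cavity modes are present)
#' @param modes optional `pq_cavity_mode` or list of them
#' @param couplings matching `pq_coupling`(s)
#' @param integrator a `pq_integrator_spec`
#' @param track_roo track the O-O distance (two-water geometries)
#' @return object of class `pq_trajectory`: recorded `time_ps`, `E_mol`,
#'   `E_cav`, `E_field`, `R_OO` series, `dissociated`, `t_diss_ps`, and the
#'   final phase-space state
#' @export
propagate <- function(geom, velocities, potential, dipole = NULL,
                      modes = NULL, couplings = NULL,
                      integrator = integrator_spec(), track_roo = TRUE) {
  dt <- fs_to_au(integrator$dt_fs)
  nsteps <- as.integer(round(ps_to_au(integrator$t_max_ps) / dt))
  rcrit <- angstrom_to_bohr(integrator$r_crit_ang)
  modes <- if (is.null(modes)) list() else as_mode_list(modes)
  couplings <- if (length(modes)) as_coupling_list(couplings,
                                                   length(modes)) else list()
  if (length(modes) && is.null(dipole))
    stop("cavity-coupled propagation needs a dipole surface")

  if (native_model(potential, dipole)) {
    k <- length(modes)
    om <- vapply(modes, `[[`, 0, "omega")
    gg <- vapply(couplings, `[[`, 0, "g")
    ee <- if (k) vapply(modes, `[[`, numeric(3), "e") else
      matrix(0, 3, 0)
    qq <- vapply(modes, `[[`, 0, "q")
    pp <- vapply(modes, `[[`, 0, "p")
    res <- pq_propagate_model(geom$coords, velocities, geom$masses,
                              om, gg, matrix(ee, nrow = 3), qq, pp, dt,
                              nsteps, integrator$output_stride, rcrit,
                              potential$params,
                              integrator$stop_at_dissociation)
  } else {
    res <- propagate_r(geom, velocities, potential, dipole, modes,
                       couplings, dt, nsteps, integrator$output_stride,
                       rcrit, integrator$stop_at_dissociation, track_roo)
  }
  final_modes <- modes
  for (j in seq_along(final_modes)) {
    final_modes[[j]]$q <- res$q[j]
    final_modes[[j]]$p <- res$p[j]
  }
  structure(list(time_ps = au_to_ps(res$time), E_mol = res$E_mol,
                 E_cav = res$E_cav, E_field = res$E_field,
                 R_OO = res$R_OO, dissociated = res$dissociated,
                 t_diss_ps = if (is.na(res$t_diss)) NA_real_ else
                   au_to_ps(res$t_diss),
                 steps = res$steps,
                 final = list(geometry = set_coords(geom, res$coords),
                              velocities = res$velocities,
                              modes = final_modes)),
            class = "pq_trajectory")
}

#' @export
print.pq_trajectory <- function(x, ...) {
  cat("<pq_trajectory> ", x$steps, " steps",
      if (isTRUE(x$dissociated))
        sprintf(", dissociated at %.2f ps", x$t_diss_ps) else
          ", bound", "\n", sep = "")
  invisible(x)
}

# reference R implementation of the same velocity-Verlet scheme, for
# arbitrary surfaces (tests, toy systems)
propagate_r <- function(geom, velocities, potential, dipole, modes,
                        couplings, dt, nsteps, stride, rcrit, stop_diss,
                        track_roo) {
  k <- length(modes)
  m3 <- rep(geom$masses, each = 3)
  x <- geom$coords
  v <- velocities
  q <- vapply(modes, `[[`, 0, "q")
  p <- vapply(modes, `[[`, 0, "p")
  has_oo <- track_roo && sum(geom$symbols == "O") == 2

  eval_forces <- function(x, q) {
    g <- set_coords(geom, x)
    if (k) {
      for (j in seq_len(k)) modes[[j]]$q <- q[j]
      f <- effective_forces(potential, dipole, modes, couplings, g, q = q)
      V <- evaluate_potential(potential, g)
      mu <- evaluate_dipole(dipole, g)
      list(fn = f$nuclear, fc = f$cavity, V = V, mu = mu)
    } else {
      list(fn = -evaluate_gradient(potential, g), fc = numeric(0),
           V = evaluate_potential(potential, g), mu = NULL)
    }
  }
  roo_of <- function(x) {
    io <- which(geom$symbols == "O")
    sqrt(sum((x[3 * io[1] - 2:0] - x[3 * io[2] - 2:0])^2))
  }

  nrec <- nsteps %/% stride + 2
  rec <- list(time = numeric(0), E_mol = numeric(0), E_cav = numeric(0),
              E_field = numeric(0), R_OO = numeric(0))
  add_rec <- function(t, fr) {
    ke <- 0.5 * sum(m3 * v^2)
    ec <- ef <- 0
    if (k) for (j in seq_len(k)) {
      ck <- cavity_disp_coef(modes[[j]], couplings[[j]])
      s <- q[j] + ck * sum(fr$mu * modes[[j]]$e)
      ec <- ec + 0.5 * p[j]^2 + 0.5 * modes[[j]]$omega^2 * q[j]^2
      ef <- ef + 0.5 * p[j]^2 + 0.5 * modes[[j]]$omega^2 * s^2
    }
    rec$time <<- c(rec$time, t)
    rec$E_mol <<- c(rec$E_mol, ke + fr$V)
    rec$E_cav <<- c(rec$E_cav, ec)
    rec$E_field <<- c(rec$E_field, ef)
    rec$R_OO <<- c(rec$R_OO, if (has_oo) roo_of(x) else NA_real_)
  }

  fr <- eval_forces(x, q)
  add_rec(0, fr)
  dissociated <- has_oo && roo_of(x) >= rcrit
  t_diss <- if (dissociated) 0 else NA_real_
  steps <- 0L
  for (step in seq_len(nsteps)) {
    v <- v + 0.5 * dt * fr$fn / m3
    x <- x + dt * v
    if (k) {
      p <- p + 0.5 * dt * fr$fc
      q <- q + dt * p
    }
    fr <- eval_forces(x, q)
    v <- v + 0.5 * dt * fr$fn / m3
    if (k) p <- p + 0.5 * dt * fr$fc
    steps <- step
    t <- step * dt
    if (!dissociated && has_oo && roo_of(x) >= rcrit) {
      dissociated <- TRUE
      t_diss <- t
    }
    if (step %% stride == 0 || step == nsteps ||
        (dissociated && stop_diss))
      add_rec(t, fr)
    if (dissociated && stop_diss) break
  }
  list(time = rec$time, E_mol = rec$E_mol, E_cav = rec$E_cav,
       E_field = rec$E_field, R_OO = rec$R_OO, dissociated = dissociated,
       t_diss = t_diss, steps = steps, coords = x, velocities = v,
       q = q, p = p)
}

resolve_polarization <- function(polarization, geom) {
  if (identical(polarization, "oo-axis")) {
    io <- which(geom$symbols == "O")
    m <- coord_matrix(geom)
    e <- m[io[2], ] - m[io[1], ]
    e / sqrt(sum(e^2))
  } else {
    as.numeric(polarization)
  }
}

#' Run an ensemble of quasi-classical trajectories
#'
#' Draws per-trajectory seeds from a master seed (so any trajectory can be
#' reproduced in isolation), samples initial conditions, initializes the
#' cavity mode with its zero-point energy, propagates, and accumulates the
#' dissociated-fraction curve P(t) and half-lifetime.
#'
#' @param n_traj number of trajectories
#' @param model a `pq_model_surface`
#' @param sampling a `pq_sampling_spec`
#' @param integrator a `pq_integrator_spec`
#' @param cavity `NULL` for a cavity-free run, else a list with
#'   `omega_cm1` (or `omega`), one of `g` / `volume_nm3`, and
#'   `polarization` (`"oo-axis"`, the default, or a 3-vector)
#' @param seed master RNG seed
#' @return object of class `pq_ensemble`: `t_grid_ps`, `P_t`,
#'   `tau_half_ps`, per-trajectory `t_diss_ps`, `seeds`, and the final
#'   frames of dissociated trajectories (geometry + velocities) for product
#'   analysis
#' @export
run_ensemble <- function(n_traj, model, sampling = sampling_spec(),
                         integrator = integrator_spec(), cavity = NULL,
                         seed = 1) {
  stopifnot(n_traj >= 1)
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L, n_traj)
  t_diss <- rep(NA_real_, n_traj)
  finals <- vector("list", n_traj)
  spec <- NULL
  for (i in seq_len(n_traj)) {
    set.seed(seeds[i])
    s <- normal_mode_sample(model$basis, sampling, model$potential,
                            hb_mode = model$hb_mode)
    modes <- NULL
    coup <- NULL
    if (!is.null(cavity)) {
      pol <- resolve_polarization(cavity[["polarization"]] %||% "oo-axis",
                                  s$geometry)
      mode <- cavity_mode(omega_cm1 = cavity[["omega_cm1"]],
                          omega = cavity[["omega"]], polarization = pol)
      coup <- coupling_volume_convert(omega = mode$omega,
                                      g = cavity[["g"]],
                                      volume_nm3 = cavity[["volume_nm3"]])
      mu0 <- evaluate_dipole(model$dipole, s$geometry)
      modes <- initialize_cavity(mode, coup, mu0)
    }
    tr <- propagate(s$geometry, s$velocities, model$potential,
                    model$dipole, modes, coup, integrator)
    t_diss[i] <- tr$t_diss_ps
    if (isTRUE(tr$dissociated))
      finals[[i]] <- tr$final
  }
  dt_grid <- integrator$dt_fs * integrator$output_stride / 1000
  t_grid <- seq(0, integrator$t_max_ps, by = dt_grid)
  P_t <- vapply(t_grid, function(t) mean(!is.na(t_diss) & t_diss <= t), 0)
  structure(list(n_traj = n_traj, t_grid_ps = t_grid, P_t = P_t,
                 tau_half_ps = half_lifetime(t_grid, P_t),
                 t_diss_ps = t_diss, seeds = seeds, master_seed = seed,
                 finals = finals, cavity = cavity),
            class = "pq_ensemble")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.pq_ensemble <- function(x, ...) {
  cat(sprintf("<pq_ensemble> %d trajectories, %.1f%% dissociated",
              x$n_traj, 100 * mean(!is.na(x$t_diss_ps))))
  if (!is.na(x$tau_half_ps))
    cat(sprintf(", tau_0.5 = %.2f ps", x$tau_half_ps))
  cat("\n")
  invisible(x)
}

#' Half-lifetime from a dissociated-fraction curve
#'
#' First time P(t) crosses 0.5, linearly interpolated between the
#' bracketing grid points; `NA` when the curve never reaches 0.5.
#'
#' @param t time grid (ps), or a `pq_ensemble`
#' @param P dissociated fraction on the grid (omit for an ensemble)
#' @return tau_0.5 in ps (or `NA`)
#' @export
half_lifetime <- function(t, P = NULL) {
  if (inherits(t, "pq_ensemble")) {
    P <- t$P_t
    t <- t$t_grid_ps
  }
  if (max(P) < 0.5) return(NA_real_)
  i <- which(P >= 0.5)[1]
  if (i == 1 || P[i] == 0.5) return(t[i])
  t[i - 1] + (0.5 - P[i - 1]) / (P[i] - P[i - 1]) * (t[i] - t[i - 1])
}
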