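# Shared fixtures, built once per test run.  The model surface build
# (relaxation + two Hessians) takes a couple of seconds.

the_model <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- model_dimer_surface()
    cache
  }
})

# a 1-D harmonic "diatomic" along z: two unit-mass atoms, spring k
harmonic_diatomic <- function(k = 1, m_amu = 1, r0 = 2) {
  pot <- potential_surface(
    energy = function(g) {
      r <- atom_distance(g, 1, 2)
      0.5 * k * (r - r0)^2
    },
    gradient = function(g) {
      m <- coord_matrix(g)
      d <- m[1, ] - m[2, ]
      r <- sqrt(sum(d^2))
      f <- k * (r - r0) * d / r
      c(f, -f)
    },
    label = "harmonic diatomic")
  geom <- geometry(c("H", "H"), c(0, 0, 0, 0, 0, r0),
                   masses = rep(amu_to_me(m_amu), 2))
  list(potential = pot, geom = geom, k = k)
}

resolve_hb_quanta <- function(model) {
  q <- integer(length(model$basis$freq))
  q[model$hb_mode] <- 1L
  q
}

random_rotation <- function() {
  th <- runif(3, 0, 2 * pi)
  Rx <- rbind(c(1, 0, 0), c(0, cos(th[1]), -sin(th[1])),
              c(0, sin(th[1]), cos(th[1])))
  Ry <- rbind(c(cos(th[2]), 0, sin(th[2])), c(0, 1, 0),
              c(-sin(th[2]), 0, cos(th[2])))
  Rz <- rbind(c(cos(th[3]), -sin(th[3]), 0),
              c(sin(th[3]), cos(th[3]), 0), c(0, 0, 1))
  Rx %*% Ry %*% Rz
}
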