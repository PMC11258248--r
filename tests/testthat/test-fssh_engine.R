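test_that("uncoupled model never hops and keeps its population", {
  m <- model_coupled_harmonics(k = c(5, 5), a = c(0, 0.3), e = c(0, 1),
                               coupling = 0)
  out <- propagate_trajectory(list(coords = 0.1, velocities = 0.01, state = 2),
                              m, sh_settings(total_time = 200, seed = 5))
  expect_equal(nrow(out$hops), 0L)
  expect_equal(out$record$final_state, 2L)
  expect_true(all(Mod(out$record$coeffs[, 2])^2 >= 1 - 1e-8))
})

test_that("single harmonic surface conserves energy to < 1e-6 over 1 ps", {
  # torsion-scale mode; velocity-Verlet energy error ~ (omega dt)^2 / 8
  m <- model_harmonic(k = 1, x0 = 0, mass = 50)
  out <- propagate_trajectory(list(coords = 0.4, velocities = 0, state = 1),
                              m, sh_settings(total_time = 1000, seed = 1,
                                             decoherence = "none"))
  etot <- 0.5 * 50 * 103.642697 * out$record$velocities[, 1]^2 +
    out$record$energies[, 1]
  expect_lt(max(abs(etot - etot[1])) / etot[1], 1e-6)
  expect_length(out$record$time, 1000 / 0.1 + 1)
})

test_that("electronic step: identity overlap and equal energies leave coeffs", {
  c0 <- c(sqrt(0.7), sqrt(0.3) * 1i)
  st <- electronic_step(c0, diag(2), c(1, 1), dt = 0.1)
  # unchanged up to a global phase
  ratio <- st$coeffs / c0
  expect_equal(Mod(ratio), c(1, 1), tolerance = 1e-12)
  expect_lt(abs(Arg(ratio[1]) - Arg(ratio[2])), 1e-12)
  expect_equal(max(abs(st$flux)), 0, tolerance = 1e-14)
})

test_that("electronic step: gap advances the relative phase by dE dt / hbar", {
  c0 <- complex(real = c(1, 1)) / sqrt(2)
  dE <- 0.8
  dt <- 0.5
  st <- electronic_step(c0, diag(2), c(0, dE), dt = dt)
  rel <- Arg(st$coeffs[2] / st$coeffs[1])
  expect_equal(rel, -dE * dt / 0.6582119569, tolerance = 1e-10)
})

test_that("electronic step matches a fine-substep matrix-exponential oracle", {
  hbar <- 0.6582119569
  set.seed(7)
  for (r in 1:5) {
    th <- runif(1, -0.1, 0.1)
    S <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2)
    E0 <- sort(runif(2, 0, 3))
    E1 <- E0 + runif(2, -0.05, 0.05)
    c0 <- complex(real = rnorm(2), imaginary = rnorm(2))
    c0 <- c0 / sqrt(sum(Mod(c0)^2))
    dt <- 0.1
    st <- electronic_step(c0, S, E0, dt, energies_next = E1,
                          substeps = 1000L)
    # brute-force: dense expm over 10000 midpoint sub-intervals
    H0 <- diag(E0)
    H1 <- S %*% diag(E1) %*% t(S)  # S is orthogonal here
    P <- diag(1 + 0i, 2)
    nsub <- 20000
    for (s in seq_len(nsub)) {
      H <- (1 - (s - 0.5) / nsub) * H0 + (s - 0.5) / nsub * H1
      es <- eigen(H, symmetric = TRUE)
      P <- (es$vectors %*% (exp(-1i * es$values * (dt / nsub) / hbar) *
                              t(es$vectors))) %*% P
    }
    cref <- drop(t(S) %*% P %*% c0)
    expect_equal(st$coeffs, cref, tolerance = 1e-8)
    expect_equal(sum(Mod(st$coeffs)^2), 1, tolerance = 1e-10)
  }
})

test_that("hop probabilities: zero without flux, clipped, loss fraction", {
  c0 <- c(sqrt(0.6), sqrt(0.4)) * (1 + 0i)
  expect_equal(hop_probabilities(1, c0, matrix(0, 2, 2)), c(0, 0))
  # contrived flux exceeding the active population is clipped to sum <= 1
  flux <- matrix(c(0, -2, 2, 0), 2, 2, byrow = TRUE)
  g <- hop_probabilities(1, c0, t(flux))
  expect_true(sum(g) <= 1 && all(g >= 0 & g <= 1))
  # two-state rotation: hop probability equals the population-loss fraction
  th <- 0.05
  S <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2)
  st <- electronic_step(c0, S, c(1, 1), dt = 0.1)
  g2 <- hop_probabilities(1, c0, st$flux)
  loss <- (Mod(c0[1])^2 - Mod(st$coeffs[1])^2) / Mod(c0[1])^2
  expect_equal(g2[2], loss, tolerance = 1e-6)
})

test_that("hop probabilities warn at vanishing active population", {
  c0 <- c(0, 1) * (1 + 0i)
  expect_warning(g <- hop_probabilities(1, c0, matrix(0, 2, 2)),
                 "machine epsilon")
  expect_equal(g, c(0, 0))
})

test_that("apply_hop conserves energy, frustrates, and uses the closed form", {
  kee <- function(fr) 0.5 * 103.642697 * sum(fr$masses * fr$velocities^2)
  fr <- list(velocities = c(0.02, -0.01), masses = c(10, 50),
             energies = c(0, 1, 2.5), active = 2L)
  ke0 <- kee(fr)
  dn <- apply_hop(fr, 1L)  # downhill, gap -1 eV
  expect_true(dn$hopped)
  expect_equal(kee(dn), ke0 + 1, tolerance = 1e-10)
  up <- apply_hop(fr, 3L)  # uphill 1.5 eV > ke0
  expect_false(up$hopped)
  expect_equal(up$velocities, fr$velocities)
  rev <- apply_hop(fr, 3L, policy = "reverse")
  expect_equal(rev$velocities, -fr$velocities)
  # uphill with sufficient kinetic energy: factor = sqrt(1 - gap/KE)
  fr2 <- list(velocities = c(0.2, -0.1), masses = c(10, 50),
              energies = c(0, 1, 2.5), active = 2L)
  ke2 <- kee(fr2)
  up2 <- apply_hop(fr2, 3L)
  expect_true(up2$hopped)
  expect_equal(up2$scale, sqrt(1 - 1.5 / ke2), tolerance = 1e-12)
})

test_that("decoherence corrections follow their closed forms", {
  c0 <- c(sqrt(0.8), sqrt(0.2)) * (1 + 0i)
  expect_identical(decoherence_correct(c0, 1L, "none"), c0)
  # overlap collapse
  cc <- decoherence_correct(c0, 1L, "overlap", list(threshold = 1e-3),
                            list(overlap = 1e-4))
  expect_equal(Mod(cc), c(1, 0))
  # no collapse above threshold
  nc <- decoherence_correct(c0, 1L, "overlap", list(threshold = 1e-3),
                            list(overlap = 0.5))
  expect_identical(nc, c0)
  # energy-based damping factor
  gap <- 0.7; ke <- 0.4; dt <- 0.1; C <- 0.1 * 27.211386245988
  tau <- 0.6582119569 / gap * (1 + C / ke)
  eb <- decoherence_correct(c0, 1L, "energy_based", list(C = C),
                            list(energies = c(0, gap), kinetic_energy = ke,
                                 dt = dt))
  expect_equal(Mod(eb[2]), Mod(c0[2]) * exp(-dt / tau), tolerance = 1e-10)
  expect_equal(sum(Mod(eb)^2), 1, tolerance = 1e-12)
})

test_that("initial-state sampling follows |mu|^2 weights", {
  ens <- list(coords = matrix(0, 5, 1), velocities = matrix(0, 5, 1))
  # single nonzero dipole: always chosen
  s1 <- sample_initial_conditions(ens, c(0, 0, 1), n = 50, seed = 2)
  expect_true(all(vapply(s1, `[[`, integer(1), "state") == 3L))
  # equal dipoles: 0.5 +- 0.02 at n = 10000
  s2 <- sample_initial_conditions(ens, c(0, 1, 1), n = 10000, seed = 3)
  f <- mean(vapply(s2, `[[`, integer(1), "state") == 2L)
  expect_lt(abs(f - 0.5), 0.02)
  # |mu|^2 weights (1, 2): frequencies 1/3, 2/3 within binomial 3 sigma
  s3 <- sample_initial_conditions(ens, c(0, 1, sqrt(2)), n = 10000, seed = 4)
  f3 <- mean(vapply(s3, `[[`, integer(1), "state") == 3L)
  expect_lt(abs(f3 - 2 / 3), 3 * sqrt(2 / 9 / 10000))
  expect_error(sample_initial_conditions(ens, c(0, 0, 0), n = 1),
               "dipoles are zero")
})

test_that("same seed and settings give a bitwise-identical trajectory", {
  m <- model_carotenoid()
  init <- list(coords = c(0.09, 0.05), velocities = c(0.001, 0.0005), state = 3)
  s <- sh_settings(total_time = 100, seed = 42)
  a <- propagate_trajectory(init, m, s)
  b <- propagate_trajectory(init, m, s)
  expect_identical(a$record$coords, b$record$coords)
  expect_identical(a$record$coeffs, b$record$coeffs)
  expect_identical(a$hops, b$hops)
})

test_that("recorded hops change state and conserve total energy", {
  m <- model_carotenoid()
  ens <- sample_ground_ensemble(m, 10, 300, seed = 9, x0 = c(0.1, 0))
  nhops <- 0L
  for (i in 1:10) {
    s <- sh_settings(total_time = 400, seed = 300 + i)
    o <- propagate_trajectory(list(coords = ens$coords[i, ],
                                   velocities = ens$velocities[i, ],
                                   state = 3), m, s)
    if (nrow(o$hops) > 0) {
      nhops <- nhops + nrow(o$hops)
      expect_true(all(o$hops$from != o$hops$to))
    }
    # total energy along the active surface stays within tolerance
    act <- o$record$active
    eact <- o$record$energies[cbind(seq_along(act), act)]
    etot <- 0.5 * 103.642697 *
      (o$record$velocities^2 %*% m$masses)[, 1] + eact
    expect_lt(max(abs(etot - etot[1])), 0.02)
  }
  expect_gt(nhops, 0L)
})

test_that("frustrated-hop reversal keeps the run stable", {
  m <- model_coupled_harmonics(k = c(5, 5), a = c(0, 0.05), e = c(0, 0.4),
                               coupling = 0.05)
  s <- sh_settings(total_time = 300, seed = 8, frustrated = "reverse")
  o <- propagate_trajectory(list(coords = 0, velocities = 0.005, state = 1),
                            m, s)
  expect_equal(length(o$record$time), 3001L)
})
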