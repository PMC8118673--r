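# A free-particle provider: constant energies, zero gradients/couplings.
free_pes <- function(ns = 2, ndof = 2) {
  structure(list(
    fun = function(x) {
      pes_evaluation(state_energies = seq(0.1, by = 0.1, length.out = ns),
                     state_gradients = matrix(0, ns, ndof),
                     nac = array(0, c(ns, ns, ndof)))
    },
    masses = rep(1, ndof), n_states = ns, kind = "free"),
    class = "pes_provider")
}

test_that("zero gradient gives uniform linear motion", {
  pes <- free_pes()
  cfg <- fssh_config(dt = 0.5, t_total = 5, initial_state = 1, seed = 1,
                     n_substeps = 5)
  tr <- run_trajectory(pes, c(0, 1), c(0.02, -0.01), cfg)
  dt_au <- 0.5 / units_au$au_fs
  expect_equal(tr$pos[11, ], c(0, 1) + 10 * dt_au * c(0.02, -0.01),
               tolerance = 1e-12)
  expect_equal(tr$vel[11, ], c(0.02, -0.01))
  expect_equal(tr$active, rep(1L, 11))
})

test_that("harmonic motion conserves energy and has the right period", {
  # single-state LVC: V = omega Q^2 / 2, period 2 pi / omega
  om <- 0.004
  p <- lvc_parameters(om, 0.0, matrix(0, 1, 1), array(0, c(1, 1, 1)))
  pes <- make_lvc_pes(p)
  period_fs <- 2 * pi / om * units_au$au_fs           # ~38 fs
  cfg <- fssh_config(dt = period_fs / 1000, t_total = period_fs,
                     initial_state = 1, allow_hops = FALSE, seed = 1,
                     n_substeps = 1)
  sam <- list(Q = matrix(1.3, 1, 1), P = matrix(0, 1, 1))
  tr <- run_ensemble(sam, cfg, pes)$trajectories[[1]]
  expect_lt(max(abs(tr$etot - tr$etot[1])), 1e-6)
  # after one full period the coordinate returns to its start (0.1% phase)
  expect_equal(tr$pos[nrow(tr$pos), 1], 1.3,
               tolerance = 1.3 * 2 * pi * 1e-3)
})

test_that("compiled and R reference propagators agree without hops", {
  p <- tiny_lvc()
  cfg <- fssh_config(dt = 0.5, t_total = 25, initial_state = 2,
                     allow_hops = FALSE, seed = 6, n_substeps = 20)
  sam <- list(Q = matrix(c(0.4, -0.3), 1, 2), P = matrix(c(0.2, 0.5), 1, 2))
  cpp <- run_ensemble(sam, cfg, make_lvc_pes(p))$trajectories[[1]]
  rtr <- run_trajectory(make_lvc_pes(p), c(0.4, -0.3),
                        p$omega * c(0.2, 0.5), cfg)
  expect_equal(rtr$pos, cpp$pos, tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(rtr$energies, cpp$energies, tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(Mod(rtr$coeff)^2, Mod(cpp$coeff)^2, tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("coefficient propagation: phase-only evolution when uncoupled", {
  ns <- 2
  mk_state <- function(coeff) {
    ev <- pes_evaluation(state_energies = c(0.1, 0.3),
                         state_gradients = matrix(0, ns, 1),
                         nac = array(0, c(ns, ns, 1)))
    trajectory_state(0, 0, 0.0, 1, 1, coeff, ev)
  }
  c0 <- sqrt(c(0.7, 0.3)) * exp(1i * c(0, 0.4))
  st <- mk_state(c0)
  dt <- 1.0
  cc <- propagate_coefficients(st, mk_state(c0), dt, 400)
  expect_equal(Mod(cc)^2, c(0.7, 0.3), tolerance = 1e-8,
               ignore_attr = TRUE)
  dphi <- Arg(cc[2] / cc[1]) - Arg(c0[2] / c0[1])
  expect_equal(dphi %% (2 * pi), (-0.2 * dt / units_au$au_fs) %% (2 * pi),
               tolerance = 1e-7)
})

test_that("constant coupling between degenerate states gives Rabi
           oscillation", {
  V <- 0.002  # effective v.d coupling (a.u.)
  ns <- 2
  ev <- pes_evaluation(state_energies = c(0.2, 0.2 + 1e-15),
                       state_gradients = matrix(0, ns, 1),
                       nac = array(c(0, -V, V, 0), c(ns, ns, 1)))
  st0 <- trajectory_state(0, 0, 1.0, 1, 1, c(1 + 0i, 0i), ev)
  t_fs <- 30
  st1 <- st0; st1$time_fs <- t_fs
  cc <- propagate_coefficients(st0, st1, t_fs, 2000)
  t_au <- t_fs / units_au$au_fs
  expect_equal(Mod(cc[2])^2, sin(V * t_au)^2, tolerance = 1e-4)
})

test_that("coefficient integration converges at 4th order", {
  # random 3-state couplings; halving the substep must shrink the error
  # by ~2^4
  # energies/couplings kept small enough that the coarsest grid stays
  # below the internal norm-drift retry threshold
  set.seed(9)
  ns <- 3
  E0 <- sort(runif(ns, 0.001, 0.005))
  E1 <- sort(E0 + runif(ns, -2e-4, 2e-4))
  A0 <- matrix(rnorm(ns * ns, sd = 3e-4), ns)
  A1 <- matrix(rnorm(ns * ns, sd = 3e-4), ns)
  mk <- function(E, A, v) {
    nac <- array(0, c(ns, ns, 1))
    nac[, , 1] <- (A - t(A))
    pes_evaluation(state_energies = E, state_gradients = matrix(0, ns, 1),
                   nac = nac)
  }
  c0 <- rep(1 / sqrt(ns) + 0i, ns)
  st0 <- trajectory_state(0, 0, 1.0, 1, 1, c0, mk(E0, A0))
  st1 <- trajectory_state(2, 0, 1.0, 1, 1, c0, mk(E1, A1))
  sol <- function(nsub) propagate_coefficients(st0, st1, 2.0, nsub)
  ref <- sol(512)
  e1 <- max(Mod(sol(8) - ref))
  e2 <- max(Mod(sol(16) - ref))
  expect_gt(e1 / e2, 2^4 * 0.6)   # allow slack off the asymptotic rate
})

test_that("hop probabilities follow the fewest-switches formula", {
  ns <- 2
  V <- 0.01
  mk <- function(sgn) {
    nac <- array(c(0, -sgn * V, sgn * V, 0), c(ns, ns, 1))
    ev <- pes_evaluation(state_energies = c(0.2, 0.3),
                         state_gradients = matrix(0, ns, 1), nac = nac)
    trajectory_state(0, 0, 1.0, 1, 1,
                     sqrt(c(0.6, 0.4)) * c(1 + 0i, 1 + 0i), ev)
  }
  dt <- 0.5
  g <- hop_probability(mk(+1), dt)
  manual <- max(0, 2 * (dt / units_au$au_fs) *
                  Re(sqrt(0.6) * sqrt(0.4) * V) / 0.6)
  expect_equal(g[2], manual, tolerance = 1e-12)
  # sign gate: flipping the coupling zeroes the probability
  expect_equal(hop_probability(mk(-1), dt)[2], 0)
  # no coupling, no hops ever
  st <- mk(+1); st$eval$nac[] <- 0
  expect_equal(hop_probability(st, dt), c(0, 0))
})

test_that("hops conserve energy; frustrated hops reject or reverse", {
  p <- tiny_lvc()
  ev <- evaluate_lvc(p, c(0.5, -0.2))
  masses <- 1 / p$omega
  # downhill hop from state 2: always allowed, speed increases
  v <- c(0.001, 0.002)
  st <- trajectory_state(0, c(0.5, -0.2), v, masses, 2,
                         c(0i, 1 + 0i), ev)
  e_before <- total_energy(st)
  res <- attempt_hop(st, 1)
  expect_true(res$event$accepted)
  expect_equal(total_energy(res$state), e_before, tolerance = 1e-9)
  expect_gt(sum(res$state$masses * res$state$v^2),
            sum(st$masses * st$v^2))
  # uphill hop with zero kinetic energy: frustrated
  st0 <- trajectory_state(0, c(0.5, -0.2), c(0, 0), masses, 1,
                          c(1 + 0i, 0i), ev)
  res2 <- attempt_hop(st0, 2)
  expect_false(res2$event$accepted)
  expect_equal(res2$state$active, 1L)
  expect_equal(res2$state$v, c(0, 0))
  # reverse policy flips the velocity component along the coupling vector
  stv <- trajectory_state(0, c(0.5, -0.2), c(1e-4, 1e-4), masses, 1,
                          c(1 + 0i, 0i), ev)
  res3 <- attempt_hop(stv, 2, frustrated = "reverse")
  expect_false(res3$event$accepted)
  h <- ev$nac[1, 2, ]
  expect_equal(sum(res3$state$v * h), -sum(stv$v * h), tolerance = 1e-10)
})

test_that("ensembles have the configured frame count and are seed-exact", {
  p <- tiny_lvc()
  sam <- sample_wigner_modes(p, 4, seed = 3)
  cfg <- fssh_config(dt = 0.5, t_total = 300, initial_state = 2, seed = 7,
                     n_substeps = 20)
  ens <- run_ensemble(sam, cfg, make_lvc_pes(p))
  expect_length(ens$trajectories, 4)
  for (tr in ens$trajectories) expect_length(tr$times, 601)
  ens2 <- run_ensemble(sam, cfg, make_lvc_pes(p))
  expect_identical(lapply(ens$trajectories, `[[`, "pos"),
                   lapply(ens2$trajectories, `[[`, "pos"))
  expect_identical(lapply(ens$trajectories, `[[`, "hops"),
                   lapply(ens2$trajectories, `[[`, "hops"))
})

test_that("ground-state start of an uncoupled model never leaves state 1", {
  p <- lvc_parameters(c(0.002, 0.003), c(0.40, 0.43),
                      rbind(c(0.002, -0.001), c(-0.003, 0.002)),
                      array(0, c(2, 2, 2)))
  sam <- sample_wigner_modes(p, 5, seed = 2)
  cfg <- fssh_config(dt = 0.5, t_total = 100, initial_state = 1, seed = 5)
  ens <- run_ensemble(sam, cfg, make_lvc_pes(p))
  for (tr in ens$trajectories) {
    expect_true(all(tr$active == 1L))
    expect_equal(Mod(tr$coeff[, 1])^2, rep(1, 201), tolerance = 1e-9)
  }
})

test_that("PES failure mid-trajectory truncates and flags, never drops", {
  calls <- 0
  pes <- structure(list(
    fun = function(x) {
      calls <<- calls + 1
      if (calls > 5) stop("SCF blew up")
      pes_evaluation(state_energies = 0.1,
                     state_gradients = matrix(0, 1, 1),
                     nac = array(0, c(1, 1, 1)))
    },
    masses = 1, n_states = 1, kind = "flaky"), class = "pes_provider")
  cfg <- fssh_config(dt = 0.5, t_total = 10, initial_state = 1, seed = 1,
                     n_substeps = 2)
  expect_warning(tr <- run_trajectory(pes, 0, 0.01, cfg), "truncated")
  expect_true(tr$flags$truncated)
  expect_lt(length(tr$times), 21)
  expect_gt(length(tr$times), 1)
})

test_that("trajectory ensembles round-trip through the archive", {
  p <- tiny_lvc()
  sam <- sample_wigner_modes(p, 2, seed = 1)
  cfg <- fssh_config(dt = 0.5, t_total = 10, initial_state = 1, seed = 1,
                     n_substeps = 5)
  ens <- run_ensemble(sam, cfg, make_lvc_pes(p))
  path <- withr::local_tempfile(fileext = ".rds")
  write_ensemble(ens, path)
  expect_identical(read_ensemble(path), ens)
})
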