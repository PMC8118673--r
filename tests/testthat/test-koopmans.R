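test_that("hole states are built from the valence manifold, HOMO first", {
  be <- mock_hf_backend()
  g <- mock_geometry()
  ev <- evaluate_koopmans_states(g, 3, be)
  out <- be(g$symbols, g$coords, 0, 1)
  # ascending cation energies = E_HF - eps, HOMO hole lowest
  expect_equal(ev$state_energies,
               out$e_hf - c(-0.40, -0.55, -0.80), tolerance = 1e-12)
  expect_equal(ev$reference_energy, out$e_hf)
  expect_equal(ev$hole_levels, c(-0.40, -0.55, -0.80))
  # both 1s-dominated orbitals found, assigned to the right atoms
  expect_equal(nrow(ev$core_levels), 2)
  expect_equal(ev$core_levels$element, c("O", "C"))
  expect_equal(ev$core_levels$energy, c(-15, -11))
  # dipole blocks forwarded per (core site, hole state)
  expect_equal(dim(ev$hole_dipoles), c(2, 3, 3))
  expect_equal(ev$hole_dipoles[1, 1, 1], 0.1)   # core 1 -> HOMO (eps -0.40)
})

test_that("single-state request and over-request behave per contract", {
  be <- mock_hf_backend()
  g <- mock_geometry()
  ev <- evaluate_koopmans_states(g, 1, be)
  expect_length(ev$state_energies, 1)
  expect_error(evaluate_koopmans_states(g, 4, be), "3 occupied valence")
})

test_that("backend failures surface with the geometry attached", {
  bad <- function(symbols, coords, ...) stop("SCF did not converge")
  expect_error(evaluate_koopmans_states(mock_geometry(), 2, bad),
               "SCF did not converge")
  expect_error(evaluate_koopmans_states(mock_geometry(), 2, bad),
               "geometry")
})

test_that("finite-difference gradients match the analytic mock surface", {
  be <- mock_hf_backend()
  g <- mock_geometry()
  ev <- koopmans_fd_gradients(g, 3, be, step = 1e-3)
  # analytic at r = r0: d e_hf/dr = 0; gradients are -d eps/dr along z2
  # (hole states: MO5, MO4, MO3 in ascending cation energy)
  z2 <- 6  # atom 2 z displacement; dr/dz2 = +1
  expect_equal(ev$state_gradients[1, z2], -0.06, tolerance = 1e-4)
  expect_equal(ev$state_gradients[2, z2], 0.08, tolerance = 1e-4)
  expect_equal(ev$state_gradients[3, z2], -0.05, tolerance = 1e-4)
  # gradients along x/y of either atom vanish at the r-only mock surface
  expect_lt(max(abs(ev$state_gradients[, c(1, 2, 4, 5)])), 1e-6)
  # NAC antisymmetry holds exactly
  for (d in 1:6) {
    expect_equal(ev$nac[, , d], -t(ev$nac[, , d]), tolerance = 1e-14)
  }
  # the mock's valence MOs 3/4 rotate at dtheta/dr = 0.2: that pair's
  # coupling (hole states 2 and 3) shows it; the fixed HOMO couples to
  # neither
  expect_equal(abs(ev$nac[2, 3, z2]), 0.2, tolerance = 1e-3)
  expect_lt(max(abs(ev$nac[1, 2, ])), 1e-6)
})

test_that("Koopmans energies are invariant under rigid motion of the
           geometry", {
  be <- mock_hf_backend()
  g <- mock_geometry()
  ev0 <- evaluate_koopmans_states(g, 3, be)
  th <- 0.6
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  g2 <- g
  g2$coords <- g$coords %*% t(R) + matrix(rep(c(1, -2, 0.5), each = 2), 2)
  ev2 <- evaluate_koopmans_states(g2, 3, be)
  expect_equal(ev2$state_energies, ev0$state_energies, tolerance = 1e-6)
})

test_that("recorded urea backend reproduces the contract and rejects other
           geometries", {
  be <- urea_hf_backend()
  g <- attr(be, "geometry")
  expect_identical(g$symbols, c("C", "O", "N", "N", "H", "H", "H", "H"))
  out <- be(g$symbols, g$coords, 0, 1)
  expect_lt(out$e_hf, -223)
  expect_length(out$eps_occ, 16)
  g2 <- g; g2$coords[1, 1] <- g2$coords[1, 1] + 0.1
  expect_error(be(g2$symbols, g2$coords, 0, 1), "recorded")
})

test_that("urea valence binding energies and core assignments are
           physically sensible", {
  be <- urea_hf_backend()
  g <- attr(be, "geometry")
  ev <- evaluate_koopmans_states(g, 3, be)
  bes <- binding_energies(ev)
  expect_length(bes, 3)
  expect_true(all(diff(bes) > 0))
  expect_true(all(bes > 9 & bes < 15))
  # four 1s cores: O, 2 N, C, each > 90% on one atom
  expect_equal(nrow(ev$core_levels), 4)
  expect_setequal(ev$core_levels$element, c("C", "N", "N", "O"))
  expect_true(all(ev$core_levels$population > 0.9))
  sh <- koopmans_edge_shifts(ev)
  expect_setequal(sh$element, c("C", "N", "O"))
  expect_true(all(sh$shift > 10 & sh$shift < 35))
})

test_that("a Koopmans PES provider drives the generic propagator", {
  be <- mock_hf_backend()
  g <- mock_geometry()
  pes <- make_koopmans_pes(g, 2, be)
  cfg <- fssh_config(dt = 0.5, t_total = 5, initial_state = 1, seed = 3,
                     n_substeps = 10)
  x0 <- as.numeric(t(g$coords)) / units_au$bohr_ang
  tr <- run_trajectory(pes, x0, rep(0, 6), cfg)
  expect_length(tr$times, 11)
  expect_false(tr$flags$truncated)
  # rough energy conservation on the (heavy-mass) mock surface
  expect_lt(max(abs(tr$etot - tr$etot[1])), 5e-5)
})

test_that("Wigner samples drive a live-backend ensemble end to end", {
  be <- mock_hf_backend()
  g <- mock_geometry()
  modes <- modes_from_hessian(g, diatomic_hessian(0.25))
  samples <- sample_wigner(modes, 2, seed = 4)
  pes <- make_koopmans_pes(g, 2, be)
  cfg <- fssh_config(dt = 0.5, t_total = 5, initial_state = 1, seed = 2,
                     n_substeps = 5)
  ens <- run_ensemble(samples, cfg, pes)
  expect_length(ens$trajectories, 2)
  expect_false(any(vapply(ens$trajectories, function(t) t$flags$truncated,
                          TRUE)))
  pc <- state_populations(ens)
  expect_equal(rowSums(pc$populations), rep(1, 11))
})
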