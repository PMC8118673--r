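test_that("single-line cross section: dark line, peak value, area", {
  grid <- seq(270, 290, by = 0.001)
  wide <- seq(130, 430, by = 0.005)   # tails of a Lorentzian die off slowly
  # dark transition
  expect_equal(line_cross_section(280, c(0, 0, 0), grid), rep(0, length(grid)))
  # on-resonance peak equals prefactor * |d|^2/3 * 2/(pi Gamma)
  d <- c(0.2, -0.1, 0.05)
  gam_ev <- 0.1
  sig <- line_cross_section(280, d, 280, linewidth = gam_ev)
  w0 <- 280 / units_au$hartree_ev
  gam <- gam_ev / units_au$hartree_ev
  pref <- (4 / 3) * pi^2 * w0 * units_au$fine_structure * sum(d^2) / 3
  expect_equal(sig, pref * 2 / (pi * gam), tolerance = 1e-12)
  # integrated area equals the closed-form prefactor within 0.1%,
  # independent of linewidth
  for (lw in c(0.05, 0.1, 0.4)) {
    sig <- line_cross_section(280, d, wide, linewidth = lw)
    area <- pracma::trapz(wide / units_au$hartree_ev, sig)
    expect_equal(area, pref, tolerance = 1e-3)
  }
  # linear in |d|^2
  expect_equal(line_cross_section(280, 2 * d, grid),
               4 * line_cross_section(280, d, grid), tolerance = 1e-12)
  expect_error(line_cross_section(-5, d, grid), "transition energy")
})

test_that("frame spectra sum same-element sites and scale as |d|^2", {
  core <- data.frame(site = c("N1", "N2", "O1"),
                     element = c("N", "N", "O"),
                     energy = c(-14.8, -14.8, -19.2))
  edge_n <- edge_config("N", seq(360, 385, by = 0.01))
  hole <- -0.41
  # two identical N sites: exactly twice one site's line
  one <- line_cross_section((hole + 14.8) * units_au$hartree_ev,
                            0.09, edge_n$energy_grid + 25, 0.1)
  both <- frame_spectrum(core, hole, c(0.09, 0.09, 0.04), edge_n)
  expect_equal(both, 2 * one, tolerance = 1e-12)
  # doubling one site's dipole quadruples its contribution
  d2 <- frame_spectrum(core, hole, c(4 * 0.09, 0.09, 0.04), edge_n)
  expect_equal(d2 - both, 4 * one - one, tolerance = 1e-10)
  expect_error(frame_spectrum(core, hole, c(1, 1, 1),
                              edge_config("C", seq(250, 260, 0.1))),
               "no core site")
})

test_that("spectrograms: static limit, mixtures, and NA for empty bins", {
  core <- data.frame(site = "X1", element = "X", energy = -10)
  times <- seq(0, 10, by = 0.5)
  tr1 <- planted_spectral_trajectory(times, rep(1L, length(times)),
                                     c(-0.40, -0.35), core,
                                     rbind(c(0.09, 0.09)))
  tr2 <- planted_spectral_trajectory(times, rep(2L, length(times)),
                                     c(-0.40, -0.35), core,
                                     rbind(c(0.09, 0.09)))
  edge <- edge_config("X", seq(255, 270, by = 0.01), shift = 0)
  # frozen ensemble: constant in time
  res1 <- ensemble_spectrogram(planted_ensemble(list(tr1)), edge)
  for (i in seq_along(times)[-1]) {
    expect_equal(res1$sigma[i, ], res1$sigma[1, ], tolerance = 1e-13)
  }
  # two-subset mixture: lines at both energies with subset weights
  ens <- planted_ensemble(list(tr1, tr1, tr1, tr2))
  res <- ensemble_spectrogram(ens, edge)
  e1 <- (-0.40 + 10) * units_au$hartree_ev
  e2 <- (-0.35 + 10) * units_au$hartree_ev
  i1 <- which.min(abs(edge$energy_grid - e1))
  i2 <- which.min(abs(edge$energy_grid - e2))
  r1 <- ensemble_spectrogram(planted_ensemble(list(tr1)), edge)
  r2 <- ensemble_spectrogram(planted_ensemble(list(tr2)), edge)
  expect_equal(res$sigma, 0.75 * r1$sigma + 0.25 * r2$sigma,
               tolerance = 1e-12)
  expect_gt(res$sigma[1, i1], res$sigma[1, i2])
  # bins beyond the trajectory end are NA, not zero
  resNA <- ensemble_spectrogram(planted_ensemble(list(tr1)), edge,
                                time_grid = seq(0, 20, by = 0.5))
  expect_true(all(is.na(resNA$sigma[41, ])))
  expect_true(all(is.na(resNA$integrated[41])))
})

test_that("relaxation blueshifts the line by the planted hole-level step", {
  # active state drops 2 -> 1 at t = 5 fs; hole level rises by delta, so
  # the line moves delta (in eV) to higher photon energy
  core <- data.frame(site = "X1", element = "X", energy = -10)
  times <- seq(0, 10, by = 0.5)
  delta <- 0.055  # hartree
  act <- ifelse(times < 5, 2L, 1L)
  tr <- planted_spectral_trajectory(times, act, c(-0.40, -0.40 - delta),
                                    core, rbind(c(0.09, 0.09)))
  edge <- edge_config("X", seq(255, 270, by = 0.005), shift = 0)
  res <- ensemble_spectrogram(planted_ensemble(list(tr)), edge)
  peak_before <- edge$energy_grid[which.max(res$sigma[1, ])]
  peak_after <- edge$energy_grid[which.max(res$sigma[nrow(res$sigma), ])]
  expect_equal(peak_after - peak_before, delta * units_au$hartree_ev,
               tolerance = 0.01)
})

test_that("relaxation in the three-state model blueshifts its spectrum", {
  p <- lvc_preset("urea_cation_3state")
  sam <- sample_wigner_modes(p, 30, seed = 21)
  cfg <- fssh_config(dt = 0.5, t_total = 150, initial_state = 3, seed = 8)
  ens <- run_ensemble(sam, cfg, make_lvc_pes(p))
  edge <- edge_config("O", seq(500, 522, by = 0.02), shift = 0)
  res <- ensemble_spectrogram(ens, edge)
  centroid <- function(row) sum(edge$energy_grid * row) / sum(row)
  first <- centroid(res$sigma[1, ])
  last <- centroid(res$sigma[nrow(res$sigma), ])
  # the 0.055 Ha state-1/state-3 offset plus adiabatic level repulsion in
  # the vibrationally hot relaxed ensemble: a few-eV blueshift
  expect_gt(last - first, 1)
  expect_lt(last - first, 8)
})

test_that("edge shift moves lines rigidly, leaving integrals unchanged", {
  core <- data.frame(site = "X1", element = "X", energy = -10)
  times <- seq(0, 3, by = 0.5)
  tr <- planted_spectral_trajectory(times, rep(1L, length(times)),
                                    c(-0.40, -0.35), core,
                                    rbind(c(0.09, 0.09)))
  g <- seq(240, 280, by = 0.01)
  r0 <- ensemble_spectrogram(planted_ensemble(list(tr)),
                             edge_config("X", g, shift = 0))
  r5 <- ensemble_spectrogram(planted_ensemble(list(tr)),
                             edge_config("X", g, shift = -5))
  i0 <- which.max(r0$sigma[1, ]); i5 <- which.max(r5$sigma[1, ])
  expect_equal(g[i0] - g[i5], 5, tolerance = 0.02)
  # identical up to Lorentzian tail truncation at the window edges
  expect_equal(r0$integrated, r5$integrated, tolerance = 1e-4)
})

test_that("energy-integrated traces: consistency, locality, additivity", {
  core <- data.frame(site = "X1", element = "X", energy = -10)
  times <- seq(0, 3, by = 0.5)
  tr <- planted_spectral_trajectory(times, rep(1L, length(times)),
                                    c(-0.40, -0.35), core,
                                    rbind(c(0.09, 0.09)))
  edge <- edge_config("X", seq(250, 272, by = 0.005), shift = 0)
  res <- ensemble_spectrogram(planted_ensemble(list(tr)), edge)
  expect_equal(energy_integrated_trace(res), res$integrated,
               tolerance = 1e-12)
  # window far from the line ~ 0
  line_ev <- (-0.40 + 10) * units_au$hartree_ev
  off <- energy_integrated_trace(res, c(268, 272))
  peak <- energy_integrated_trace(res, c(line_ev - 2, line_ev + 2))
  expect_lt(max(off / peak), 1e-3)
  # two windows covering the grid sum to the total (shared boundary point)
  lo <- energy_integrated_trace(res, c(250, 260))
  hi <- energy_integrated_trace(res, c(260, 272))
  expect_equal(lo + hi, res$integrated, tolerance = 1e-6)
  expect_error(energy_integrated_trace(res, c(300, 310)), "window")
})

test_that("TSV export writes both the matrix and the trace", {
  core <- data.frame(site = "X1", element = "X", energy = -10)
  tr <- planted_spectral_trajectory(c(0, 0.5), c(1L, 1L), c(-0.4, -0.35),
                                    core, rbind(c(0.09, 0.09)))
  res <- ensemble_spectrogram(planted_ensemble(list(tr)),
                              edge_config("X", seq(259, 264, 0.05),
                                          shift = 0))
  base <- withr::local_tempfile()
  write_trxas_tsv(res, base)
  long <- read.delim(paste0(base, ".tsv"))
  expect_equal(nrow(long), 2 * length(res$energies))
  expect_equal(max(long$sigma_au), max(res$sigma), tolerance = 1e-9)
})
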