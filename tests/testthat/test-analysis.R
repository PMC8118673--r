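test_that("populations: uncoupled ground start stays at 1", {
  p <- lvc_parameters(c(0.002, 0.003), c(0.40, 0.43),
                      rbind(c(0.002, -0.001), c(-0.003, 0.002)),
                      array(0, c(2, 2, 2)))
  sam <- sample_wigner_modes(p, 3, seed = 2)
  cfg <- fssh_config(dt = 0.5, t_total = 50, initial_state = 1, seed = 5)
  pc <- state_populations(run_ensemble(sam, cfg, make_lvc_pes(p)))
  expect_equal(pc$populations[, 1], rep(1, 101))
  expect_equal(rowSums(pc$populations), rep(1, 101))
})

test_that("planted exponential decay is recovered within 10%", {
  # synthetic two-state ensemble: each trajectory switches 2 -> 1 at an
  # Exp(rate k) time; the fitted decay rate must come back within 10%
  k <- 0.04   # 1/fs  (25 fs lifetime)
  times <- seq(0, 150, by = 0.5)
  set.seed(31)
  n <- 500
  trajs <- lapply(seq_len(n), function(i) {
    tswitch <- rexp(1, rate = k)
    act <- ifelse(times < tswitch, 2L, 1L)
    structure(list(times = times, active = act,
                   energies = matrix(rep(c(0.4, 0.44), each = length(times)),
                                     ncol = 2),
                   hops = data.frame(), flags = list(truncated = FALSE),
                   provenance = list(kind = "planted")),
              class = "fssh_trajectory")
  })
  pc <- state_populations(planted_ensemble(trajs))
  p2 <- pc$populations[, 2]
  fit <- lm(log(p2[p2 > 0.05]) ~ pc$times[p2 > 0.05])
  expect_equal(-unname(coef(fit)[2]), k, tolerance = 0.1)
})

test_that("sequential three-state relaxation has an interior intermediate
           maximum", {
  p <- lvc_preset("urea_cation_3state")
  sam <- sample_wigner_modes(p, 60, seed = 5)
  cfg <- fssh_config(dt = 0.5, t_total = 150, initial_state = 3, seed = 2)
  pc <- state_populations(run_ensemble(sam, cfg, make_lvc_pes(p)))
  p2 <- pc$populations[, 2]
  imax <- which.max(p2)
  expect_gt(imax, 1)
  expect_lt(imax, length(p2))
  expect_gt(max(p2), p2[1] + 0.1)
  expect_gt(max(p2), p2[length(p2)] + 0.1)
  # state 3 decays, state 1 grows
  expect_lt(pc$populations[301, 3], 0.1)
  expect_gt(pc$populations[301, 1], 0.7)
})

test_that("internal-coordinate matrices track planted motions", {
  # planted C-O stretch: distance follows the planted sinusoid exactly
  times <- seq(0, 20, by = 0.5)
  d0 <- 1.25; amp <- 0.08; per <- 12
  coords <- array(0, c(length(times), 3, 3))
  for (i in seq_along(times)) {
    d <- d0 + amp * sin(2 * pi * times[i] / per)
    coords[i, , ] <- rbind(c(0, 0, 0), c(d, 0, 0), c(-1.3, 0.4, 0))
  }
  ens <- cartesian_ensemble(list(coords), times, c("C", "O", "N"))
  spec <- internal_coordinate_spec(c("bond", "angle"),
                                   list(c(1, 2), c(2, 1, 3)))
  X <- internal_coordinate_matrix(ens, spec)
  expect_equal(X[, 1], d0 + amp * sin(2 * pi * times / per),
               tolerance = 1e-9, ignore_attr = TRUE)
  # windowing restricts the pooled samples
  Xw <- internal_coordinate_matrix(ens, spec, window = c(5, 10))
  expect_equal(nrow(Xw), sum(times >= 5 & times <= 10))
})

test_that("the default coordinate generator covers bonds, angles,
           dihedrals", {
  g <- molecular_geometry(c("O", "C", "N", "H"),
                          rbind(c(1.2, 0, 0), c(0, 0, 0),
                                c(-0.7, 1.1, 0), c(-0.4, 2.05, 0.1)))
  spec <- default_internal_coordinates(g)
  expect_setequal(unique(spec$kinds), c("bond", "angle", "dihedral"))
  expect_true(any(vapply(seq_along(spec$kinds), function(i) {
    spec$kinds[i] == "dihedral" && identical(sort(spec$indices[[i]]),
                                             c(1L, 2L, 3L, 4L))
  }, TRUE)))
})

test_that("Pearson correlations: exact limits and planted strength", {
  set.seed(12)
  n <- 1e4
  X <- matrix(rnorm(3 * n), n, 3, dimnames = list(NULL, c("a", "b", "c")))
  Y <- cbind(y1 = X[, 1], y2 = -X[, 2])
  ct <- pearson_correlations(X, Y)
  expect_equal(ct$matrix["a", "y1"], 1)
  expect_equal(ct$matrix["b", "y2"], -1)
  # planted r = 0.8
  r <- 0.8
  Yp <- r * X[, 1] + sqrt(1 - r^2) * rnorm(n)
  ct2 <- pearson_correlations(X, Yp)
  expect_equal(ct2$matrix["a", 1], r, tolerance = 0.02 / r)
  # affine invariance
  ct3 <- pearson_correlations(3 * X - 1, 10 * Yp + 5)
  expect_equal(ct3$matrix, ct2$matrix, tolerance = 1e-12)
  # degenerate inputs
  expect_error(pearson_correlations(X[1:2, ], Yp[1:2]), "3 samples")
  Xz <- cbind(X, z = 0)
  expect_warning(ct4 <- pearson_correlations(Xz, Yp), "zero-variance")
  expect_false("z" %in% rownames(ct4$matrix))
  expect_equal(nrow(top_correlations(ct2, 2)), 2)
})

test_that("PLSR: exact single-feature response gives that axis and R2 = 1", {
  # exactly orthogonal design so the sample cross-covariance is axis-pure
  set.seed(5)
  X <- qr.Q(qr(cbind(1, matrix(rnorm(400 * 4), 400, 4))))[, -1] * 20
  Y <- 2.5 * X[, 3]
  cc <- plsr_collective_coordinate(X, Y)
  expect_equal(abs(unname(cc$loadings[3])), 1, tolerance = 1e-10)
  expect_equal(cc$r2_y, 1, tolerance = 1e-10)
  expect_error(plsr_collective_coordinate(X, rep(0, 400)), "variance")
})

test_that("PLSR recovers a planted collective coordinate", {
  gen <- generate_planted_regression(2e4, 10, target_r2 = 0.77,
                                     x_share = 0.10, seed = 77)
  cc <- plsr_collective_coordinate(gen$X, gen$Y)
  cosine <- abs(sum(cc$loadings * gen$truth$direction_std))
  expect_gt(cosine, 0.95)
  expect_equal(cc$r2_y, 0.77, tolerance = 0.05 / 0.77)
  expect_equal(cc$x_share, 0.10, tolerance = 0.02 / 0.10)
  # single-component R2 never exceeds 1 nor falls below the best single
  # feature's squared correlation (within numerical tolerance)
  best_single <- max(cor(gen$X, gen$Y)^2)
  expect_lte(cc$r2_y, 1)
  expect_gte(cc$r2_y, best_single - 1e-8)
})

test_that("hand-rolled PLSR agrees with the mixOmics reference", {
  skip_if_not_installed("mixOmics")
  gen <- generate_planted_regression(3000, 6, target_r2 = 0.6,
                                     x_share = 0.3, seed = 9)
  cc <- plsr_collective_coordinate(gen$X, gen$Y)
  ref <- mixOmics::pls(gen$X, gen$Y, ncomp = 1, scale = TRUE,
                       mode = "regression")
  wref <- ref$loadings$X[, 1]
  wref <- wref / sqrt(sum(wref^2))
  expect_gt(abs(sum(cc$loadings * wref)), 0.9999)
})

test_that("Cartesian features are rigid-motion invariant and localize
           planted displacements", {
  ref <- molecular_geometry(c("O", "C", "H"),
                            rbind(c(0, 0, 0), c(1.2, 0, 0),
                                  c(1.8, 0.9, 0)))
  times <- seq(0, 5, by = 0.5)
  nt <- length(times)
  # rotated/translated copies -> identical feature rows
  rot <- array(0, c(nt, 3, 3))
  for (i in seq_len(nt)) {
    th <- 0.3 * i
    R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
    rot[i, , ] <- ref$coords %*% t(R) + i * 0.5
  }
  ens <- cartesian_ensemble(list(rot), times, ref$symbols)
  Xf <- cartesian_feature_matrix(ens, ref)
  expect_lt(max(abs(sweep(Xf, 2, Xf[1, ]))), 1e-8)
  # planted H displacement dominates the variance
  mov <- array(0, c(nt, 3, 3))
  set.seed(2)
  for (i in seq_len(nt)) {
    c2 <- ref$coords
    c2[3, 1] <- c2[3, 1] + 0.4 * sin(2 * pi * times[i] / 4)
    mov[i, , ] <- c2
  }
  ens2 <- cartesian_ensemble(list(mov), times, ref$symbols)
  X2 <- cartesian_feature_matrix(ens2, ref)
  v <- apply(X2, 2, var)
  # alignment spreads some apparent counter-motion onto O/C, but the
  # moving hydrogen must still dominate the variance budget
  expect_true(which.max(v) %in% 7:9)
  expect_gt(sum(v[7:9]) / sum(v), 0.5)
  # atom-count mismatch
  two <- molecular_geometry(c("O", "C"), rbind(c(0, 0, 0), c(1.2, 0, 0)))
  expect_error(cartesian_feature_matrix(ens2, two), "mismatch|atom")
})

test_that("proton-transfer detection: threshold, first crossing, direction", {
  times <- seq(0, 100, by = 0.5)
  # static dimer at ~1.9 A: no transfer
  tr_static <- structure(list(times = times,
                              distances = cbind(fwd = rep(1.9, 201),
                                                rev = rep(1.92, 201))),
                         class = "fssh_trajectory")
  rec <- detect_proton_transfer(tr_static, id = 1)
  expect_false(rec$transferred)
  expect_true(is.na(rec$transfer_time))
  # crossing planted at exactly t = 50
  d <- ifelse(times < 50, 1.6, 1.1)
  tr_cross <- structure(list(times = times,
                             distances = cbind(fwd = d, rev = 1.9)),
                        class = "fssh_trajectory")
  rec2 <- detect_proton_transfer(tr_cross, id = 2)
  expect_true(rec2$transferred)
  expect_equal(rec2$transfer_time, 50)
  expect_equal(rec2$direction, "fwd")
  # oscillation across the threshold: first crossing only, no re-arming
  osc <- 1.3 + 0.2 * sin(2 * pi * times / 10)
  tr_osc <- structure(list(times = times,
                           distances = cbind(fwd = osc, rev = 1.9)),
                      class = "fssh_trajectory")
  rec3 <- detect_proton_transfer(tr_osc, id = 3)
  first <- times[which(osc < 1.25)[1]]
  expect_equal(rec3$transfer_time, first)
  # Cartesian route: distance computed from atom indices
  coords <- array(0, c(length(times), 2, 3))
  coords[, 2, 1] <- ifelse(times < 20, 1.8, 1.0)
  ens <- cartesian_ensemble(list(coords), times, c("O", "H"))
  rec4 <- detect_proton_transfer(ens$trajectories[[1]], donor_h = 2,
                                 acceptor_o = 1, id = 4)
  expect_true(rec4$transferred)
  expect_equal(rec4$transfer_time, 20)
})

test_that("transfer statistics recover planted fraction and t50", {
  ens <- generate_planted_transfers(300, fraction = 0.7, t50 = 50, tau = 8,
                                    seed = 13)
  truth <- attr(ens, "truth")
  rec <- proton_transfer_records(ens)
  expect_equal(rec$transferred, truth$transferred)
  st <- transfer_statistics(rec)
  expect_equal(st$fraction, mean(truth$transferred))
  expect_equal(st$fraction, 0.7, tolerance = 3 * sqrt(0.7 * 0.3 / 300) / 0.7)
  expect_equal(st$fit$t50, 50, tolerance = 5 / 50)
  expect_equal(st$fit$plateau, sum(truth$transferred),
               tolerance = 0.05)
  # independent seeds scatter within the fit's uncertainty scale
  st2 <- transfer_statistics(proton_transfer_records(
    generate_planted_transfers(300, 0.7, 50, 8, seed = 14)))
  expect_lt(abs(st2$fit$t50 - st$fit$t50), 5)
  # degenerate cases
  none <- generate_planted_transfers(20, fraction = 0, seed = 3)
  st0 <- transfer_statistics(proton_transfer_records(none))
  expect_equal(st0$fraction, 0)
  expect_null(st0$fit)
})

test_that("ensemble splitting is a disjoint exhaustive partition whose
           spectrograms recombine exactly", {
  core <- data.frame(site = "X1", element = "X", energy = -10)
  times <- seq(0, 10, by = 0.5)
  mk <- function(hl, cross) {
    tr <- planted_spectral_trajectory(times, rep(1L, length(times)),
                                      c(hl, hl + 0.05), core,
                                      rbind(c(0.09, 0.09)))
    tr$distances <- cbind(fwd = if (cross) c(rep(1.5, 10), rep(1.0, 11))
                          else rep(1.6, 21), rev = rep(1.9, 21))
    tr
  }
  ens <- planted_ensemble(list(mk(-0.40, TRUE), mk(-0.42, FALSE),
                               mk(-0.44, TRUE), mk(-0.38, FALSE),
                               mk(-0.36, TRUE)))
  rec <- proton_transfer_records(ens)
  parts <- split_ensemble(ens, rec)
  expect_equal(length(parts$with$trajectories) +
                 length(parts$without$trajectories), 5)
  expect_equal(length(parts$with$trajectories), 3)
  edge <- edge_config("X", seq(255, 268, by = 0.01), shift = 0)
  full <- ensemble_spectrogram(ens, edge)
  w <- ensemble_spectrogram(parts$with, edge)
  wo <- ensemble_spectrogram(parts$without, edge)
  f <- 3 / 5
  expect_equal(full$sigma, f * w$sigma + (1 - f) * wo$sigma,
               tolerance = 1e-12)
})

test_that("edge intensities correlate with the planted intensity-carrying
           mode and PLSR finds it", {
  # the three-state preset's O/N site dipoles depend linearly on mode 1
  # with opposite signs, so O and N intensities anticorrelate and the
  # PLSR direction for either intensity points along mode 1
  p <- lvc_preset("urea_cation_3state")
  sam <- sample_wigner_modes(p, 25, seed = 3)
  cfg <- fssh_config(dt = 0.5, t_total = 60, initial_state = 1, seed = 6)
  ens <- run_ensemble(sam, cfg, make_lvc_pes(p))
  edges <- list(edge_config("N", seq(395, 420, by = 0.05), shift = 0),
                edge_config("O", seq(500, 522, by = 0.05), shift = 0))
  Y <- edge_intensity_matrix(ens, edges, window = c(0, 50))
  X <- do.call(rbind, lapply(ens$trajectories, function(tr) {
    tr$pos[tr$times <= 50, ]
  }))
  colnames(X) <- paste0("Q", seq_len(ncol(X)))
  ct <- pearson_correlations(X, Y)
  expect_gt(ct$matrix["Q1", "O"], 0.5)
  expect_lt(ct$matrix["Q1", "N"], -0.5)
  expect_lt(cor(Y[, "N"], Y[, "O"]), -0.5)
  cc <- plsr_collective_coordinate(X, Y[, "O"])
  expect_equal(which.max(abs(cc$loadings)), 1L, ignore_attr = TRUE)
})
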