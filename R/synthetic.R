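#' Built-in LVC model presets
#'
#' Desk-scale model systems with known structure, used to exercise every
#' pipeline stage without an electronic-structure engine:
#'
#' * `two_state_1d`: single-mode avoided crossing (omega = 0.001,
#'   kappa = +/-0.01, lambda = 0.0066 a.u.; diabatic gap at the crossing =
#'   2 lambda). The attached `setup` attribute documents the standard
#'   single-passage initial conditions (Q0 = -8, P0 = 20, dt = 0.025 fs,
#'   18 fs) used for Landau-Zener comparisons.
#' * `urea_cation_3state`: three coupled hole states over eight
#'   skeletal-range modes with vertical binding energies 0.41 / 0.44 /
#'   0.465 hartree; couplings placed so a state-3 start relaxes
#'   sequentially (3 -> 2 -> 1) with the bulk of the decay inside about
#'   100 fs; the documented relaxation horizon (> 90% ground state) is
#'   300 fs. Carries four synthetic core sites (C / N1 / N2 / O classes)
#'   whose per-state dipoles mimic hole localization, so spectrograms show
#'   the blueshift-upon-relaxation mechanism.
#' * `dimer_pt_2state`: two electronic states over three modes, with mode 1
#'   a large-amplitude transfer coordinate mapped to a donor-H acceptor-O
#'   distance d = 1.9 + 0.2 Q1 Angstrom (threshold crossing at
#'   Q1 = -3.25). Both states share mode 1's gradient, so the transfer
#'   statistics are exactly the analytic barrier-crossing probability of
#'   the ground-state Wigner ensemble; `fraction` sets that probability by
#'   solving for the gradient shift.
#'
#' @param name preset name.
#' @param fraction target transfer fraction (dimer preset only).
#' @return an [lvc_parameters()] object with a `setup` attribute holding
#'   the documented run parameters and ground-truth quantities.
#' @export
lvc_preset <- function(name = c("two_state_1d", "urea_cation_3state",
                                "dimer_pt_2state"), fraction = 0.7) {
  name <- tryCatch(match.arg(name), error = function(e) {
    stop("unknown preset '", name[1], "'; available: two_state_1d, ",
         "urea_cation_3state, dimer_pt_2state")
  })
  if (name == "two_state_1d") {
    omega <- 0.001; kap <- 0.01; lam <- 0.0066
    lambda0 <- rbind(c(0, lam), c(lam, 0))   # constant diabatic coupling
    p <- lvc_parameters(omega, c(0.5, 0.5), rbind(kap, -kap),
                        array(0, c(2, 2, 1)), lambda0 = lambda0)
    attr(p, "setup") <- list(
      Q0 = -8, P0 = 20, dt = 0.025, t_total = 18, initial_state = 1,
      lz = list(lambda = lam, dkappa = 2 * kap, omega = omega),
      note = "single diabatic passage; hop fraction vs Landau-Zener")
    return(p)
  }
  if (name == "urea_cation_3state") {
    # Eight skeletal-range modes (350-660 cm^-1) chosen so a 0.5 fs
    # velocity-Verlet step conserves energy below 1e-5 hartree over
    # 300 fs; per-mode reorganization energies kappa^2/2omega stay below
    # half the state gaps, so no spurious charge-transfer wells open on
    # the ground adiabat.  Vertical binding energies 0.41/0.44/0.465 Ha
    # (11.2/12.0/12.7 eV); constant + linear couplings sized so a state-3
    # start relaxes sequentially (3 -> 2 -> 1) with the bulk of the decay
    # inside ~100 fs and > 90% ground-state population by 300 fs.
    omega <- c(0.0016, 0.0018, 0.0021, 0.0023, 0.0025, 0.0027, 0.0029,
               0.0030)
    offsets <- c(0.41, 0.44, 0.465)
    kappa <- rbind(
      rep(0, 8),
      c(0.0045, -0.0040, 0.0050, 0.0000, 0.0045, -0.0030, 0.0000, 0.0040),
      c(0.0060, 0.0050, -0.0045, 0.0050, 0.0000, 0.0045, 0.0050,
        -0.0040)) * 1.3
    lambda <- array(0, c(3, 3, 8))
    lambda[1, 2, ] <- lambda[2, 1, ] <- c(0, 0.0015, 0, 0.0012, 0, 0.0010,
                                          0, 0)
    lambda[2, 3, ] <- lambda[3, 2, ] <- c(0.0015, 0, 0.0015, 0, 0.0012, 0,
                                          0, 0)
    lambda[1, 3, ] <- lambda[3, 1, ] <- c(0.0008, 0, 0, 0, 0, 0, 0.0008, 0)
    lambda0 <- matrix(0, 3, 3)
    lambda0[1, 2] <- lambda0[2, 1] <- 0.007
    lambda0[2, 3] <- lambda0[3, 2] <- 0.008
    lambda0[1, 3] <- lambda0[3, 1] <- 0.003
    core <- data.frame(site = c("C1", "N1", "N2", "O1"),
                       element = c("C", "N", "N", "O"),
                       energy = c(-10.6, -14.8, -14.8, -19.2),
                       stringsAsFactors = FALSE)
    # per-state transition dipoles: state 1 (HOMO hole) bright at O,
    # state 2 at N, state 3 at O; weak everywhere at C.  Linear terms give
    # geometry-intensity correlation along modes 1-2.
    lin8 <- function(a, b) rbind(c(a, b, rep(0, 6)), rep(0, 8), rep(0, 8))
    dip <- list(
      C1 = list(const = rbind(c(0.05, 0, 0), c(0.04, 0, 0), c(0.06, 0, 0)),
                linear = lin8(0.010, 0.004)),
      N1 = list(const = rbind(c(0.22, 0, 0), c(0.42, 0, 0), c(0.18, 0, 0)),
                linear = lin8(-0.050, 0.012)),
      N2 = list(const = rbind(c(0.22, 0, 0), c(0.42, 0, 0), c(0.18, 0, 0)),
                linear = lin8(-0.050, 0.012)),
      O1 = list(const = rbind(c(0.45, 0, 0), c(0.20, 0, 0), c(0.50, 0, 0)),
                linear = lin8(0.085, -0.020)))
    p <- lvc_parameters(omega, offsets, kappa, lambda, lambda0 = lambda0,
                        core_levels = core, dipole_model = dip)
    attr(p, "setup") <- list(initial_state = 3, relaxation_horizon = 300,
                             dt = 0.5, t_total = 300)
    return(p)
  }
  # dimer_pt_2state
  stopifnot(fraction >= 0, fraction <= 1)
  omega <- c(0.002, 0.004, 0.005)
  q_star <- 3.25                      # |Q1| where d crosses 1.25 Angstrom
  s <- .pt_shift_for_fraction(fraction, q_star)
  kappa <- rbind(c(s * omega[1], 0.000, 0.000),
                 c(s * omega[1], 0.010, -0.008))
  offsets <- c(0.38, 0.42)
  lambda <- array(0, c(2, 2, 3))
  lambda[1, 2, 3] <- lambda[2, 1, 3] <- 0.004
  lambda0_d <- rbind(c(0, 0.003), c(0.003, 0))
  core <- data.frame(site = c("O_acceptor", "O_donor"),
                     element = c("O", "O"),
                     energy = c(-19.2, -19.0), stringsAsFactors = FALSE)
  dip <- list(
    O_acceptor = list(const = rbind(c(0.40, 0, 0), c(0.25, 0, 0)),
                      linear = rbind(c(0.05, 0, 0), rep(0, 3), rep(0, 3))),
    O_donor = list(const = rbind(c(0.35, 0, 0), c(0.30, 0, 0)),
                   linear = rbind(c(-0.04, 0, 0), rep(0, 3), rep(0, 3))))
  p <- lvc_parameters(omega, offsets, kappa, lambda, lambda0 = lambda0_d,
                      core_levels = core, dipole_model = dip)
  attr(p, "setup") <- list(
    initial_state = 1, dt = 0.5, t_total = 300,
    distance = list(d_eq = 1.9, slope = 0.2, mode = 1, threshold = 1.25,
                    q_star = q_star),
    shift = s, target_fraction = fraction,
    expected_fraction = .pt_fraction_given_shift(s, q_star))
  p
}

# Transfer-fraction calibration.  With kappa_1 = +s*omega the mode-1
# potential omega Q^2/2 + s omega Q has its minimum at -s, biased toward
# the crossing threshold at Q1 = -q_star.  A harmonic trajectory reaches
# Q1 <= -q_star iff its amplitude A = sqrt((Q0 + s)^2 + P0^2) >= q_star - s.
# Under the ground-state Wigner distribution (Q0, P0 ~ N(0, 1/2)),
# 2 A^2 ~ noncentral chi-square with 2 dof and ncp = 2 s^2, so the transfer
# probability is available in closed form and invertible in s.
#' @keywords internal
.pt_fraction_given_shift <- function(s, q_star) {
  if (s >= q_star) return(1)
  stats::pchisq(2 * (q_star - s)^2, df = 2, ncp = 2 * s^2,
                lower.tail = FALSE)
}

#' @keywords internal
.pt_shift_for_fraction <- function(fraction, q_star) {
  if (fraction >= 1) return(q_star)
  if (fraction <= 0) return(-q_star)  # minimum pushed away from threshold
  stats::uniroot(function(s) .pt_fraction_given_shift(s, q_star) - fraction,
                 interval = c(-q_star, q_star), tol = 1e-10)$root
}

#' Planted linear-response regression data
#'
#' Gaussian features with a planted unit direction `w` carrying a chosen
#' share of the total feature variance, and responses that are linear in
#' the projection X w plus Gaussian noise calibrated to a target
#' population R^2. Ground truth is returned alongside the data so tests
#' never hard-code derived numbers.
#'
#' @param n_samples,n_features dimensions.
#' @param target_r2 population R^2 of Y given the projection, in (0, 1].
#' @param x_share fraction of total feature variance along `w`, in (0, 1].
#' @param loading planted unit direction (default: a deterministic random
#'   direction drawn under `seed`).
#' @param seed integer seed.
#' @return list `X` (n x p), `Y` (n x 1), `truth` (direction in raw and
#'   standardized space, slope, noise_sd, variance parameters).
#' @export
generate_planted_regression <- function(n_samples, n_features,
                                        target_r2 = 0.77, x_share = 0.10,
                                        loading = NULL, seed = 1L) {
  stopifnot(target_r2 > 0, target_r2 <= 1, x_share > 0, x_share <= 1)
  set.seed(seed)
  p <- n_features
  w <- if (is.null(loading)) {
    v <- stats::rnorm(p); v / sqrt(sum(v^2))
  } else {
    stopifnot(length(loading) == p)
    loading / sqrt(sum(loading^2))
  }
  a <- if (x_share < 1) (p - 1) * x_share / (1 - x_share) else Inf
  if (!is.finite(a)) stop("x_share = 1 requires n_features = 1")
  Z <- matrix(stats::rnorm(n_samples * p), n_samples, p)
  X <- Z + (sqrt(a) - 1) * (Z %*% w) %*% t(w)
  t_true <- as.numeric(X %*% w)
  noise_sd <- if (target_r2 < 1) sqrt(a * (1 - target_r2) / target_r2) else 0
  Y <- matrix(t_true + stats::rnorm(n_samples, sd = noise_sd), ncol = 1)
  sdx <- sqrt(1 + (a - 1) * w^2)      # population per-feature sd
  wstd <- w * sdx
  wstd <- wstd / sqrt(sum(wstd^2))
  list(X = X, Y = Y,
       truth = list(direction = w, direction_std = wstd, slope = 1,
                    noise_sd = noise_sd, var_along = a, var_perp = 1,
                    target_r2 = target_r2, x_share = x_share))
}

#' Planted proton-transfer ensembles
#'
#' Per trajectory, a smooth donor-H acceptor-O distance curve that either
#' stays above the detection threshold or crosses it at a
#' logistic-distributed time (midpoint `t50`, scale `tau`). Transferring
#' trajectories are randomly assigned one of the two symmetry-equivalent
#' directions. The result is packaged as a standard ensemble so
#' [detect_proton_transfer()] runs unmodified; ground truth rides along.
#'
#' @param n_trajectories ensemble size.
#' @param fraction probability a trajectory transfers, in \[0, 1\].
#' @param t50 logistic midpoint of the transfer times (fs).
#' @param tau logistic scale (fs).
#' @param t_total,dt time grid (fs).
#' @param threshold detection threshold the curves are built around
#'   (Angstrom).
#' @param seed master seed (same splitting rule as the samplers).
#' @return an `fssh_ensemble` whose trajectories carry `times` and a
#'   2-column `distances` matrix (directions "fwd"/"rev"); attribute
#'   `truth` is a data.frame of planted outcomes.
#' @export
generate_planted_transfers <- function(n_trajectories, fraction = 0.7,
                                       t50 = 50, tau = 8, t_total = 300,
                                       dt = 0.5, threshold = 1.25,
                                       seed = 1L) {
  stopifnot(fraction >= 0, fraction <= 1, t50 > 0, tau > 0)
  times <- seq(0, t_total, by = dt)
  d_eq <- 1.9; d_min <- 1.0; width <- 3
  s_star <- (d_eq - threshold) / (d_eq - d_min)
  u_star <- log(s_star / (1 - s_star))
  trajs <- vector("list", n_trajectories)
  truth <- data.frame(trajectory_id = seq_len(n_trajectories),
                      transferred = FALSE, planted_time = NA_real_,
                      direction = NA_character_, stringsAsFactors = FALSE)
  for (i in seq_len(n_trajectories)) {
    set.seed(.child_seed(seed, i))
    transfer <- stats::runif(1) < fraction
    wig <- 0.05 * sin(2 * pi * times / stats::runif(1, 25, 60) +
                        stats::runif(1, 0, 2 * pi))
    safe <- d_eq + wig
    if (transfer) {
      tc <- stats::qlogis(stats::runif(1), location = t50, scale = tau)
      while (tc < 5 || tc > t_total - 10) {
        tc <- stats::qlogis(stats::runif(1), location = t50, scale = tau)
      }
      mid <- tc - width * u_star
      curve <- d_eq - (d_eq - d_min) / (1 + exp(-(times - mid) / width)) +
        0.02 * sin(2 * pi * times / 40)
      # enforce the exact first crossing at the planted time
      curve[times < tc & curve < threshold + 0.01] <- threshold + 0.01
      dir <- if (stats::runif(1) < 0.5) "fwd" else "rev"
      D <- if (dir == "fwd") cbind(fwd = curve, rev = safe) else
        cbind(fwd = safe, rev = curve)
      truth$transferred[i] <- TRUE
      truth$planted_time[i] <- tc
      truth$direction[i] <- dir
    } else {
      D <- cbind(fwd = safe, rev = d_eq + 0.04 * cos(2 * pi * times / 45))
    }
    trajs[[i]] <- structure(
      list(times = times, distances = D,
           provenance = list(kind = "planted_transfer",
                             seed_id = .child_seed(seed, i)),
           flags = list(truncated = FALSE)),
      class = "fssh_trajectory")
  }
  ens <- structure(list(trajectories = trajs, failed = list(),
                        config = list(dt = dt, t_total = t_total,
                                      seed = seed)),
                   class = "fssh_ensemble")
  attr(ens, "truth") <- truth
  ens
}

#' Assemble a Cartesian ensemble from explicit coordinate frames
#'
#' Test/analysis helper: wraps externally constructed coordinate time
#' series (e.g. planted geometric motions) in trajectory containers so the
#' geometric analyses run on them unmodified.
#'
#' @param coord_list list (one per trajectory) of `nt x natoms x 3` arrays
#'   in Angstrom.
#' @param times frame times (fs).
#' @param symbols element symbols.
#' @return an `fssh_ensemble` of Cartesian trajectories (no electronic
#'   data).
#' @export
cartesian_ensemble <- function(coord_list, times, symbols) {
  trajs <- lapply(coord_list, function(cc) {
    stopifnot(length(dim(cc)) == 3, dim(cc)[1] == length(times),
              dim(cc)[2] == length(symbols))
    pos <- t(vapply(seq_along(times), function(i) {
      as.numeric(t(.ang2bohr(cc[i, , ])))
    }, numeric(3 * length(symbols))))
    structure(list(times = times, pos = pos, symbols = symbols,
                   provenance = list(kind = "cartesian",
                                     coord = "cartesian"),
                   flags = list(truncated = FALSE)),
              class = "fssh_trajectory")
  })
  structure(list(trajectories = trajs, failed = list(),
                 config = list(dt = if (length(times) > 1)
                   diff(times)[1] else NA_real_)),
            class = "fssh_ensemble")
}
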