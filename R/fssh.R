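#' Surface-hopping run configuration
#'
#' @param dt nuclear time step in fs (default 0.5).
#' @param t_total total propagation time in fs (default 300).
#' @param n_substeps electronic integration substeps per nuclear step.
#' @param initial_state 1-based index of the hole state populated at t = 0
#'   (1 = lowest cation state, i.e. the HOMO hole).
#' @param seed master integer seed; trajectory i runs under a child seed
#'   derived by the same splitting rule as [sample_wigner()].
#' @param frustrated what to do with classically forbidden (frustrated)
#'   hops: `"reject"` leaves velocities untouched (default), `"reverse"`
#'   inverts the velocity component along the coupling vector.
#' @param allow_hops set `FALSE` for plain adiabatic MD on the initial
#'   surface (used by conservation tests).
#' @return object of class `fssh_config`.
#' @export
fssh_config <- function(dt = 0.5, t_total = 300, n_substeps = 100L,
                        initial_state = 1L, seed = 1L,
                        frustrated = c("reject", "reverse"),
                        allow_hops = TRUE) {
  frustrated <- match.arg(frustrated)
  stopifnot(dt > 0, t_total >= dt, n_substeps >= 1)
  structure(list(dt = dt, t_total = t_total,
                 n_substeps = as.integer(n_substeps),
                 initial_state = as.integer(initial_state),
                 seed = as.integer(seed), frustrated = frustrated,
                 allow_hops = isTRUE(allow_hops)),
            class = "fssh_config")
}

#' Instantaneous quantum-classical trajectory state
#'
#' @param time_fs time in fs.
#' @param x coordinates in the provider's coordinate system (mode space for
#'   LVC, bohr for Cartesian backends).
#' @param v velocities (coordinate units per atomic time unit).
#' @param masses effective masses per coordinate (a.u.).
#' @param active 1-based active adiabatic state.
#' @param coeff complex electronic amplitudes, unit norm.
#' @param eval the [pes_evaluation()] at `x` (phase-aligned).
#' @return object of class `trajectory_state`.
#' @export
trajectory_state <- function(time_fs, x, v, masses, active, coeff, eval) {
  nrm <- sum(Mod(coeff)^2)
  if (abs(nrm - 1) > 1e-6) stop("electronic amplitudes not normalized")
  stopifnot(active <= length(coeff))
  structure(list(time_fs = time_fs, x = x, v = v, masses = masses,
                 active = as.integer(active), coeff = coeff, eval = eval),
            class = "trajectory_state")
}

#' Kinetic + active-surface potential energy of a state (hartree)
#' @param state a [trajectory_state()].
#' @export
total_energy <- function(state) {
  sum(state$masses * state$v^2) / 2 +
    state$eval$state_energies[state$active]
}

#' Velocity-Verlet step on the active adiabatic surface
#'
#' Advances positions and velocities by one nuclear step using the active
#' state's gradient, evaluates the PES at the new geometry and fixes the
#' electronic phase against the previous evaluation.
#'
#' @param state a [trajectory_state()].
#' @param dt time step in fs.
#' @param pes a `pes_provider` (see [make_lvc_pes()]).
#' @return the advanced [trajectory_state()] (amplitudes not yet updated).
#' @export
propagate_nuclei <- function(state, dt, pes) {
  dt_au <- .fs2au(dt)
  a0 <- -state$eval$state_gradients[state$active, ] / state$masses
  vh <- state$v + 0.5 * dt_au * a0
  xn <- state$x + dt_au * vh
  ev <- tryCatch(pes$fun(xn), error = function(e) {
    stop("PES evaluation failed at t = ", state$time_fs + dt, " fs: ",
         conditionMessage(e), call. = FALSE)
  })
  ev <- fix_phase_continuity(state$eval, ev)
  a1 <- -ev$state_gradients[state$active, ] / state$masses
  vn <- vh + 0.5 * dt_au * a1
  trajectory_state(state$time_fs + dt, xn, vn, state$masses, state$active,
                   state$coeff, ev)
}

#' @keywords internal
.vdot_nac <- function(eval, v) {
  ns <- length(eval$state_energies)
  K <- matrix(0, ns, ns)
  for (k in seq_along(v)) K <- K + eval$nac[, , k] * v[k]
  K
}

#' Integrate the electronic amplitudes across one nuclear step
#'
#' Solves i dc_k/dt = E_k c_k - i sum_j (v . d_kj) c_j with 4th-order
#' Runge-Kutta over `n_substeps`, linearly interpolating state energies and
#' scalar couplings between the two ends of the nuclear step. Norm drift
#' below 1e-6 is renormalized away; larger drift triggers one retry with
#' four times the substeps before the step is flagged.
#'
#' @param state state at the beginning of the step (carries `coeff`).
#' @param next_state state at the end of the step ([propagate_nuclei()]
#'   output, phase-fixed).
#' @param dt nuclear step in fs.
#' @param n_substeps electronic substeps.
#' @return complex amplitude vector at the end of the step (unit norm),
#'   with attribute `norm_drift`.
#' @export
propagate_coefficients <- function(state, next_state, dt, n_substeps = 100L) {
  dt_au <- .fs2au(dt)
  E0 <- state$eval$state_energies
  E1 <- next_state$eval$state_energies
  K0 <- .vdot_nac(state$eval, state$v)
  K1 <- .vdot_nac(next_state$eval, next_state$v)
  run <- function(nsub) {
    h <- dt_au / nsub
    cc <- state$coeff
    for (s in seq_len(nsub)) {
      f0 <- (s - 1) / nsub; f1 <- s / nsub; fm <- (f0 + f1) / 2
      dfun <- function(ci, f) {
        -1i * ((E0 + f * (E1 - E0)) * ci) - (K0 + f * (K1 - K0)) %*% ci
      }
      k1 <- dfun(cc, f0)
      k2 <- dfun(cc + h / 2 * k1, fm)
      k3 <- dfun(cc + h / 2 * k2, fm)
      k4 <- dfun(cc + h * k3, f1)
      cc <- cc + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
    cc
  }
  cc <- run(n_substeps)
  drift <- abs(sqrt(sum(Mod(cc)^2)) - 1)
  if (drift >= 1e-6) {
    cc <- run(4L * n_substeps)
    drift <- abs(sqrt(sum(Mod(cc)^2)) - 1)
  }
  out <- as.vector(cc) / sqrt(sum(Mod(cc)^2))
  attr(out, "norm_drift") <- drift
  out
}

#' Tully fewest-switches hop probabilities
#'
#' g(a -> j) = max(0, 2 dt Re\[c_a* c_j (v.d_aj)\] / |c_a|^2), with the sum
#' over targets clipped to 1. Probabilities are zeroed (with a warning)
#' when the active amplitude has decayed below 1e-10.
#'
#' @param state a [trajectory_state()] carrying end-of-step amplitudes.
#' @param dt nuclear step in fs.
#' @return numeric vector of per-state hop probabilities (0 for the active
#'   state).
#' @export
hop_probability <- function(state, dt) {
  dt_au <- .fs2au(dt)
  a <- state$active
  pa <- Mod(state$coeff[a])^2
  ns <- length(state$coeff)
  g <- numeric(ns)
  if (pa < 1e-10) {
    warning("active-state population below 1e-10; hop probabilities zeroed")
    return(g)
  }
  K <- .vdot_nac(state$eval, state$v)
  for (j in seq_len(ns)) {
    if (j == a) next
    g[j] <- max(0, 2 * dt_au * Re(Conj(state$coeff[a]) * state$coeff[j] *
                                    K[a, j]) / pa)
  }
  if (sum(g) > 1) g <- g / sum(g)
  g
}

#' Attempt a surface hop with energy-conserving velocity rescaling
#'
#' The velocity component along the nonadiabatic coupling vector d(a,
#' target) is rescaled so total energy is conserved. If the available
#' kinetic energy along that direction cannot bridge an uphill gap, the hop
#' is frustrated and handled per `frustrated` ("reject": nothing changes;
#' "reverse": that velocity component is inverted). A near-zero coupling
#' vector (norm < 1e-12) falls back to rescaling along the full velocity,
#' and the event is flagged.
#'
#' @param state end-of-step [trajectory_state()].
#' @param target 1-based target state (!= active).
#' @param frustrated `"reject"` or `"reverse"`.
#' @return list `state` (possibly hopped), `event` (data.frame row: time,
#'   from, to, accepted, gap, flagged).
#' @export
attempt_hop <- function(state, target, frustrated = "reject") {
  a <- state$active
  stopifnot(target != a)
  h <- state$eval$nac[a, target, ]
  flagged <- FALSE
  if (sqrt(sum(h^2)) < 1e-12) {
    h <- state$v
    flagged <- TRUE
  }
  A <- 0.5 * sum(h^2 / state$masses)
  B <- sum(state$v * h)
  dE <- state$eval$state_energies[target] - state$eval$state_energies[a]
  disc <- B^2 - 4 * A * dE
  accepted <- disc >= 0 && A > 0
  if (accepted) {
    roots <- c((-B + sqrt(disc)) / (2 * A), (-B - sqrt(disc)) / (2 * A))
    gam <- roots[which.min(abs(roots))]
    state$v <- state$v + gam * h / state$masses
    state$active <- as.integer(target)
  } else if (identical(frustrated, "reverse") && A > 0) {
    state$v <- state$v + (-B / A) * h / state$masses
  }
  list(state = state,
       event = data.frame(time = state$time_fs, from = a, to = target,
                          accepted = accepted, gap = dE, flagged = flagged))
}

#' Propagate a single FSSH trajectory with an R-level PES provider
#'
#' Reference implementation shared by all backends; LVC ensembles normally
#' go through the compiled fast path in [run_ensemble()], which follows the
#' identical algorithm. PES failures mid-trajectory truncate the
#' trajectory and set `flags$truncated` rather than dropping it silently.
#'
#' @param pes a `pes_provider`.
#' @param x0,v0 initial coordinates / velocities (provider units).
#' @param config an [fssh_config()].
#' @param seed_id integer seed for this trajectory's hop draws.
#' @return an `fssh_trajectory`.
#' @export
run_trajectory <- function(pes, x0, v0, config, seed_id = config$seed) {
  set.seed(seed_id)
  nsteps <- round(config$t_total / config$dt)
  ns <- pes$n_states
  coeff <- complex(real = as.numeric(seq_len(ns) == config$initial_state),
                   imaginary = rep(0, ns))
  ev0 <- pes$fun(x0)
  st <- trajectory_state(0, x0, v0, pes$masses, config$initial_state,
                         coeff, ev0)
  nt <- nsteps + 1
  ndof <- length(x0)
  rec <- list(times = numeric(nt), pos = matrix(NA_real_, nt, ndof),
              vel = matrix(NA_real_, nt, ndof),
              active = integer(nt), energies = matrix(NA_real_, nt, ns),
              coeff = matrix(NA_complex_, nt, ns), etot = numeric(nt),
              norm_err = numeric(nt),
              hole_levels = matrix(NA_real_, nt, ns))
  hops <- list()
  put <- function(i, s) {
    rec$times[i] <<- s$time_fs
    rec$pos[i, ] <<- s$x; rec$vel[i, ] <<- s$v
    rec$active[i] <<- s$active
    rec$energies[i, ] <<- s$eval$state_energies
    rec$coeff[i, ] <<- s$coeff
    rec$etot[i] <<- total_energy(s)
    if (!is.null(s$eval$hole_levels)) {
      rec$hole_levels[i, ] <<- s$eval$hole_levels
    }
  }
  put(1, st)
  truncated <- FALSE
  for (step in seq_len(nsteps)) {
    nx <- tryCatch(propagate_nuclei(st, config$dt, pes),
                   error = function(e) e)
    if (inherits(nx, "error")) {
      truncated <- TRUE
      warning("trajectory truncated at step ", step, ": ",
              conditionMessage(nx))
      break
    }
    cc <- propagate_coefficients(st, nx, config$dt, config$n_substeps)
    nx$coeff <- cc
    rec$norm_err[step + 1] <- attr(cc, "norm_drift")
    if (config$allow_hops) {
      g <- hop_probability(nx, config$dt)
      xi <- stats::runif(1)
      cum <- 0
      for (j in seq_len(ns)) {
        if (j == nx$active) next
        cum <- cum + g[j]
        if (xi < cum) {
          res <- attempt_hop(nx, j, config$frustrated)
          nx <- res$state
          hops[[length(hops) + 1]] <- res$event
          break
        }
      }
    }
    st <- nx
    put(step + 1, st)
  }
  n_done <- if (truncated) step else nt
  keep <- seq_len(min(n_done, nt))
  structure(list(times = rec$times[keep], pos = rec$pos[keep, , drop = FALSE],
                 vel = rec$vel[keep, , drop = FALSE],
                 active = rec$active[keep],
                 energies = rec$energies[keep, , drop = FALSE],
                 coeff = rec$coeff[keep, , drop = FALSE],
                 etot = rec$etot[keep], norm_err = rec$norm_err[keep],
                 hole_levels = rec$hole_levels[keep, , drop = FALSE],
                 hops = if (length(hops)) do.call(rbind, hops) else
                   data.frame(time = numeric(), from = integer(),
                              to = integer(), accepted = logical(),
                              gap = numeric(), flagged = logical()),
                 core_levels = ev0$core_levels,
                 dip2 = NULL,
                 provenance = list(config = config, seed_id = seed_id,
                                   kind = pes$kind),
                 flags = list(truncated = truncated)),
            class = "fssh_trajectory")
}

#' @export
print.fssh_trajectory <- function(x, ...) {
  cat("<fssh_trajectory> ", length(x$times), " frames, ",
      ncol(x$energies), " states, ",
      sum(x$hops$accepted), " accepted hops",
      if (isTRUE(x$flags$truncated)) " [TRUNCATED]" else "", "\n", sep = "")
  invisible(x)
}

#' @keywords internal
.lvc_traj_from_cpp <- function(raw, params, config, seed_id) {
  nt <- nrow(raw$Q)
  vcom <- as.numeric(raw$Q^2 %*% params$omega) / 2
  hole_levels <- -(raw$energies - vcom)
  dip2 <- NULL
  if (!is.null(params$dipole_model)) {
    nsite <- length(params$dipole_model)
    ns <- params$n_states
    dip2 <- array(0, c(nt, nsite, ns))
    for (s in seq_len(nsite)) {
      dm <- params$dipole_model[[s]]
      shift <- if (is.null(dm$linear)) matrix(0, nt, 3) else
        raw$Q %*% t(dm$linear)
      for (a in seq_len(ns)) {
        d <- sweep(shift, 2, dm$const[a, ], "+")
        dip2[, s, a] <- rowSums(d^2)
      }
    }
  }
  structure(list(times = seq(0, by = config$dt, length.out = nt),
                 pos = raw$Q, vel = raw$V, active = as.integer(raw$active),
                 energies = raw$energies,
                 coeff = matrix(complex(real = raw$coeff_re,
                                        imaginary = raw$coeff_im),
                                nt, params$n_states),
                 etot = as.numeric(raw$etot),
                 norm_err = as.numeric(raw$norm_err),
                 hole_levels = hole_levels,
                 hops = cbind(raw$hops,
                              flagged = logical(nrow(raw$hops))),
                 core_levels = params$core_levels,
                 dip2 = dip2,
                 provenance = list(config = config, seed_id = seed_id,
                                   kind = "lvc"),
                 flags = list(truncated = FALSE,
                              degenerate_evals = raw$degenerate_evals)),
            class = "fssh_trajectory")
}

#' Run an FSSH trajectory ensemble
#'
#' Propagates one trajectory per initial-condition sample. LVC providers
#' use the compiled propagator; any other provider goes through
#' [run_trajectory()]. Trajectory i is seeded from `config$seed` and the
#' sample's `seed_id` by the fixed splitting rule, so the ensemble is
#' bit-reproducible. Failed (truncated) trajectories are returned in
#' `$failed`, never merged into `$trajectories`.
#'
#' @param samples either the output of [sample_wigner_modes()] (LVC mode
#'   space: list with `Q`, `P` matrices) or a list of `phase_space_sample`
#'   objects for Cartesian providers.
#' @param config an [fssh_config()].
#' @param pes a `pes_provider`.
#' @return object of class `fssh_ensemble` with `trajectories`, `failed`,
#'   `config`.
#' @export
run_ensemble <- function(samples, config, pes) {
  mode_samples <- is.list(samples) && !is.null(samples$Q)
  n <- if (mode_samples) nrow(samples$Q) else length(samples)
  stopifnot(n >= 1)
  dt_au <- .fs2au(config$dt)
  nsteps <- round(config$t_total / config$dt)
  trajs <- list()
  failed <- list()
  for (i in seq_len(n)) {
    sid <- .child_seed(config$seed, i)
    if (identical(pes$kind, "lvc") && mode_samples) {
      p <- pes$params
      set.seed(sid)
      raw <- .lvc_fssh_cpp(p$omega, p$offsets, p$kappa, p$lambda,
                           p$lambda0, samples$Q[i, ], samples$P[i, ],
                           dt_au, nsteps,
                           config$n_substeps, config$initial_state,
                           config$allow_hops,
                           identical(config$frustrated, "reverse"))
      tr <- .lvc_traj_from_cpp(raw, p, config, sid)
    } else {
      s <- samples[[i]]
      if (inherits(s, "phase_space_sample")) {
        x0 <- as.numeric(t(.ang2bohr(s$coords)))
        v0 <- as.numeric(t(s$velocities)) / units_au$bohr_ang * units_au$au_fs
      } else {
        x0 <- s$x; v0 <- s$v
      }
      tr <- run_trajectory(pes, x0, v0, config, seed_id = sid)
    }
    if (isTRUE(tr$flags$truncated)) {
      failed[[length(failed) + 1]] <- tr
    } else {
      trajs[[length(trajs) + 1]] <- tr
    }
  }
  if (!length(trajs)) stop("all trajectories failed")
  structure(list(trajectories = trajs, failed = failed, config = config),
            class = "fssh_ensemble")
}

#' @export
print.fssh_ensemble <- function(x, ...) {
  cat("<fssh_ensemble> ", length(x$trajectories), " trajectories (",
      length(x$failed), " failed), ", length(x$trajectories[[1]]$times),
      " frames each\n", sep = "")
  invisible(x)
}

#' Ensemble archive round trip
#'
#' Single-file archive of a trajectory ensemble (or sample list) using R's
#' native serialization; round trips are bit-exact.
#'
#' @param x object to store.
#' @param path file path (conventionally `.rds`).
#' @export
write_ensemble <- function(x, path) {
  saveRDS(x, path)
  invisible(path)
}

#' @rdname write_ensemble
#' @export
read_ensemble <- function(path) readRDS(path)

#' Export a Cartesian trajectory as multi-frame XYZ
#'
#' @param trajectory an `fssh_trajectory` whose coordinates are Cartesian
#'   (bohr), e.g. from an ab initio backend.
#' @param symbols element symbols in atom order.
#' @param path output path.
#' @export
export_xyz_trajectory <- function(trajectory, symbols, path) {
  frames <- lapply(seq_along(trajectory$times), function(i) {
    molecular_geometry(symbols,
                       .bohr2ang(matrix(trajectory$pos[i, ], ncol = 3,
                                        byrow = TRUE)))
  })
  write_xyz(frames, path, times = trajectory$times)
}
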