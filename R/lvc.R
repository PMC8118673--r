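#' Linear vibronic coupling (LVC) model parameters
#'
#' Diabatic model Hamiltonian over dimensionless normal-mode coordinates Q:
#' \deqn{H_{ab}(Q) = \delta_{ab}\Big(\sum_k \tfrac{\omega_k}{2} Q_k^2 + E^0_a
#'   + \sum_k \kappa_{a,k} Q_k\Big) + (1-\delta_{ab}) \sum_k \lambda_{ab,k} Q_k}
#' with harmonic frequencies `omega` (hartree), state offsets `offsets`
#' (hartree), intra-state gradients `kappa` and inter-state couplings
#' `lambda` (hartree per unit Q). An analytically differentiable stand-in
#' for ab initio hole-state surfaces: energies, gradients and nonadiabatic
#' couplings are all exact.
#'
#' Optional spectroscopy fields give each synthetic "core site" a fixed 1s
#' level and a transition-dipole model, so model ensembles produce pre-edge
#' absorption lines whose positions track the electronic state (the
#' blueshift-upon-relaxation mechanism) without claiming ab initio numbers.
#'
#' @param omega mode frequencies, hartree (> 0).
#' @param offsets vertical state energies E0_a at Q = 0, hartree. The model
#'   reference (neutral) energy is 0, so offsets are the vertical binding
#'   energies of the hole states.
#' @param kappa n_states x n_modes matrix of linear intra-state couplings.
#' @param lambda n_states x n_states x n_modes array, symmetric in the
#'   first two indices with zero diagonal.
#' @param lambda0 optional n_states x n_states symmetric constant diabatic
#'   coupling matrix (zero diagonal); the Q-independent part of the
#'   inter-state coupling, zero by default. A constant coupling is what
#'   makes a one-dimensional two-state model a true avoided crossing (a
#'   purely linear coupling vanishes at its own crossing seam).
#' @param core_levels optional data.frame with columns `site`, `element`,
#'   `energy` (1s orbital energy, hartree, negative).
#' @param dipole_model optional list, one entry per core site:
#'   `list(const = <n_states x 3>, linear = <3 x n_modes> or NULL)`. The
#'   transition dipole of site s in active state a at Q is
#'   `const[a, ] + linear %*% Q`.
#' @return object of class `lvc_parameters`.
#' @export
lvc_parameters <- function(omega, offsets, kappa, lambda, lambda0 = NULL,
                           core_levels = NULL, dipole_model = NULL) {
  omega <- as.numeric(omega)
  offsets <- as.numeric(offsets)
  n_modes <- length(omega)
  n_states <- length(offsets)
  stopifnot(all(omega > 0))
  kappa <- matrix(as.numeric(kappa), n_states, n_modes)
  lambda <- array(as.numeric(lambda), c(n_states, n_states, n_modes))
  for (k in seq_len(n_modes)) {
    lk <- lambda[, , k]
    if (max(abs(lk - t(lk))) > 1e-12 || any(abs(diag(as.matrix(lk))) > 1e-12)) {
      stop("lambda must be symmetric in (a, b) with zero diagonal")
    }
  }
  if (is.null(lambda0)) lambda0 <- matrix(0, n_states, n_states)
  lambda0 <- matrix(as.numeric(lambda0), n_states, n_states)
  if (max(abs(lambda0 - t(lambda0))) > 1e-12 ||
      any(abs(diag(lambda0)) > 1e-12)) {
    stop("lambda0 must be symmetric with zero diagonal")
  }
  if (!is.null(dipole_model)) {
    dipole_model <- lapply(dipole_model, function(d) {
      d$const <- matrix(as.numeric(d$const), ncol = 3)
      if (nrow(d$const) == 1L) {
        d$const <- matrix(rep(d$const, each = n_states), n_states, 3)
      }
      if (!is.null(d$linear)) d$linear <- matrix(d$linear, 3, n_modes)
      d
    })
  }
  structure(list(omega = omega, offsets = offsets, kappa = kappa,
                 lambda = lambda, lambda0 = lambda0,
                 n_states = n_states, n_modes = n_modes,
                 core_levels = core_levels, dipole_model = dipole_model),
            class = "lvc_parameters")
}

#' @export
print.lvc_parameters <- function(x, ...) {
  cat("<lvc_parameters> ", x$n_states, " states, ", x$n_modes, " modes",
      if (!is.null(x$core_levels)) {
        paste0(", ", nrow(x$core_levels), " core sites")
      } else "", "\n", sep = "")
  invisible(x)
}

#' Per-geometry electronic-structure result
#'
#' The common currency of all PES backends: adiabatic hole-state energies
#' (ascending), per-state gradients, the antisymmetric matrix of
#' nonadiabatic coupling vectors, and the descriptors needed for core-level
#' spectra (1s energies per site, per-state valence-hole levels and
#' transition dipoles).
#'
#' @param state_energies ascending cation-state energies (hartree).
#' @param state_gradients n_states x n_dof matrix (hartree / unit coord).
#' @param nac n_states x n_states x n_dof array, antisymmetric in (i, j).
#' @param reference_energy neutral-species energy the state energies are
#'   measured against (hartree).
#' @param core_levels data.frame (`site`, `element`, `energy`).
#' @param hole_levels per-state effective valence-hole orbital energy
#'   (hartree): `reference_energy - electronic state energy`.
#' @param hole_dipoles n_sites x n_states x 3 array of transition dipoles
#'   (a.u.), or NULL.
#' @param state_vectors optional matrix whose columns represent the
#'   electronic states (eigenvectors / MO coefficients); used for phase
#'   tracking.
#' @param flags named list of diagnostic flags.
#' @return object of class `pes_evaluation`.
#' @export
pes_evaluation <- function(state_energies, state_gradients = NULL, nac = NULL,
                           reference_energy = 0, core_levels = NULL,
                           hole_levels = NULL, hole_dipoles = NULL,
                           state_vectors = NULL, flags = list()) {
  n <- length(state_energies)
  if (is.unsorted(state_energies)) stop("state_energies must be ascending")
  if (!is.null(nac)) {
    stopifnot(dim(nac)[1] == n, dim(nac)[2] == n)
  }
  if (!is.null(state_gradients)) stopifnot(nrow(state_gradients) == n)
  structure(list(state_energies = state_energies,
                 state_gradients = state_gradients, nac = nac,
                 reference_energy = reference_energy,
                 core_levels = core_levels, hole_levels = hole_levels,
                 hole_dipoles = hole_dipoles, state_vectors = state_vectors,
                 flags = flags),
            class = "pes_evaluation")
}

#' Evaluate the LVC model at a mode-space point
#'
#' Builds and diagonalizes the diabatic potential matrix, then forms exact
#' adiabatic gradients (Hellmann-Feynman) and nonadiabatic coupling vectors
#' \eqn{d_{ij,k} = \langle i | \partial H/\partial Q_k | j\rangle /
#' (E_j - E_i)}. Near-degenerate pairs (gap below `gap_floor`) get the
#' denominator floored and are flagged (`flags$degenerate_pairs`).
#'
#' @param params an [lvc_parameters()] object.
#' @param Q numeric vector of dimensionless mode coordinates.
#' @param gap_floor smallest |E_j - E_i| used in the NAC denominator.
#' @return a [pes_evaluation()]; `hole_levels[a]` is the electronic part of
#'   state a with the common harmonic term removed and sign flipped, i.e.
#'   the model's orbital energy of the vacated level.
#' @export
evaluate_lvc <- function(params, Q, gap_floor = 1e-10) {
  stopifnot(inherits(params, "lvc_parameters"),
            length(Q) == params$n_modes)
  ns <- params$n_states
  nm <- params$n_modes
  vcom <- sum(params$omega * Q^2) / 2
  H <- diag(params$offsets + as.numeric(params$kappa %*% Q), ns, ns)
  H <- H + params$lambda0
  for (k in seq_len(nm)) H <- H + params$lambda[, , k] * Q[k]
  diag(H) <- diag(H) + vcom
  eg <- eigen(H, symmetric = TRUE)
  ord <- order(eg$values)
  E <- eg$values[ord]
  U <- eg$vectors[, ord, drop = FALSE]
  # fix an arbitrary but deterministic per-column sign
  for (i in seq_len(ns)) {
    pk <- which.max(abs(U[, i]))
    if (U[pk, i] < 0) U[, i] <- -U[, i]
  }
  grads <- matrix(0, ns, nm)
  nac <- array(0, c(ns, ns, nm))
  degen <- 0L
  for (k in seq_len(nm)) {
    W <- params$lambda[, , k]
    diag(W) <- params$kappa[, k] + params$omega[k] * Q[k]
    M <- t(U) %*% W %*% U
    grads[, k] <- diag(M)
    for (i in seq_len(ns)) {
      for (j in seq_len(ns)) {
        if (i == j) next
        dE <- E[j] - E[i]
        if (abs(dE) < gap_floor) {
          dE <- sign(dE + (dE == 0)) * gap_floor
          degen <- degen + 1L
        }
        nac[i, j, k] <- M[i, j] / dE
      }
    }
  }
  dip <- NULL
  if (!is.null(params$dipole_model)) {
    nsite <- length(params$dipole_model)
    dip <- array(0, c(nsite, ns, 3))
    for (s in seq_len(nsite)) {
      dm <- params$dipole_model[[s]]
      shift <- if (is.null(dm$linear)) c(0, 0, 0) else as.numeric(dm$linear %*% Q)
      for (a in seq_len(ns)) dip[s, a, ] <- dm$const[a, ] + shift
    }
  }
  pes_evaluation(state_energies = E, state_gradients = grads, nac = nac,
                 reference_energy = 0, core_levels = params$core_levels,
                 hole_levels = -(E - vcom), hole_dipoles = dip,
                 state_vectors = U,
                 flags = list(degenerate_pairs = degen))
}

#' Align electronic-state phases between consecutive evaluations
#'
#' Eigenvector signs are arbitrary; along a trajectory they must be chosen
#' continuously or the coupling time series (and hence the electronic
#' propagation) acquires spurious sign jumps. Each state of `cur` is
#' re-signed so its overlap with the same state at `prev` is positive, and
#' the NAC rows/columns are re-signed consistently. When no state vectors
#' are available the NAC matrix itself is aligned against the previous one.
#'
#' @param prev,cur [pes_evaluation()] objects with the same state count.
#' @return `cur` with consistent signs.
#' @export
fix_phase_continuity <- function(prev, cur) {
  n <- length(cur$state_energies)
  stopifnot(length(prev$state_energies) == n)
  signs <- rep(1, n)
  if (!is.null(prev$state_vectors) && !is.null(cur$state_vectors)) {
    ov <- crossprod(prev$state_vectors, cur$state_vectors)
    signs <- ifelse(diag(ov) < 0, -1, 1)
  } else if (n > 1 && !is.null(prev$nac) && !is.null(cur$nac)) {
    # choose per-state signs greedily to maximize agreement of coupling rows
    for (i in seq_len(n)[-1]) {
      agree <- sum(prev$nac[, i, ] * cur$nac[, i, ] *
                     outer(signs, rep(1, dim(cur$nac)[3])))
      if (agree < 0) signs[i] <- -1
    }
  }
  if (all(signs == 1)) return(cur)
  if (!is.null(cur$state_vectors)) {
    cur$state_vectors <- sweep(cur$state_vectors, 2, signs, "*")
  }
  if (!is.null(cur$nac)) {
    for (k in seq_len(dim(cur$nac)[3])) {
      cur$nac[, , k] <- diag(signs) %*% cur$nac[, , k] %*% diag(signs)
    }
  }
  cur
}

#' Wrap an LVC model as a PES provider for the propagator
#'
#' The returned object carries the evaluation closure, the effective masses
#' of the dimensionless mode coordinates (1/omega, so that kinetic energy is
#' `sum(omega * P^2) / 2` with momentum P = v / omega), and the state count.
#'
#' @param params an [lvc_parameters()] object.
#' @return a `pes_provider` list with elements `fun(Q)`, `masses`,
#'   `n_states`, `kind = "lvc"`, `params`.
#' @export
make_lvc_pes <- function(params) {
  structure(list(fun = function(Q) evaluate_lvc(params, Q),
                 masses = 1 / params$omega,
                 n_states = params$n_states,
                 kind = "lvc", params = params),
            class = "pes_provider")
}

#' Write / read LVC parameters as a YAML config
#'
#' Plain-text round trip of all model fields. `lambda` is stored sparsely
#' as `(a, b, mode, value)` rows.
#'
#' @param params an [lvc_parameters()] object.
#' @param path file path.
#' @export
write_lvc <- function(params, path) {
  lam <- list()
  for (k in seq_len(params$n_modes)) {
    for (a in seq_len(params$n_states)) {
      for (b in seq_len(params$n_states)) {
        if (b > a && abs(params$lambda[a, b, k]) > 0) {
          lam[[length(lam) + 1]] <- list(a = a, b = b, mode = k,
                                         value = params$lambda[a, b, k])
        }
      }
    }
  }
  lam0 <- list()
  for (a in seq_len(params$n_states)) {
    for (b in seq_len(params$n_states)) {
      if (b > a && abs(params$lambda0[a, b]) > 0) {
        lam0[[length(lam0) + 1]] <- list(a = a, b = b,
                                         value = params$lambda0[a, b])
      }
    }
  }
  obj <- list(states = params$n_states, modes = params$n_modes,
              frequencies = as.list(params$omega),
              offsets = as.list(params$offsets),
              kappa = lapply(seq_len(params$n_states),
                             function(a) as.list(params$kappa[a, ])),
              lambda = lam, lambda0 = lam0)
  if (!is.null(params$core_levels)) {
    obj$core_levels <- lapply(seq_len(nrow(params$core_levels)), function(i) {
      as.list(params$core_levels[i, c("site", "element", "energy")])
    })
  }
  if (!is.null(params$dipole_model)) {
    obj$dipole_model <- lapply(params$dipole_model, function(d) {
      o <- list(const = lapply(seq_len(nrow(d$const)),
                               function(a) as.list(d$const[a, ])))
      if (!is.null(d$linear)) {
        o$linear <- lapply(1:3, function(r) as.list(d$linear[r, ]))
      }
      o
    })
  }
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_lvc
#' @export
read_lvc <- function(path) {
  obj <- yaml::read_yaml(path)
  ns <- obj$states
  nm <- obj$modes
  lambda <- array(0, c(ns, ns, nm))
  for (e in obj$lambda) {
    lambda[e$a, e$b, e$mode] <- e$value
    lambda[e$b, e$a, e$mode] <- e$value
  }
  lambda0 <- matrix(0, ns, ns)
  for (e in obj$lambda0) {
    lambda0[e$a, e$b] <- e$value
    lambda0[e$b, e$a] <- e$value
  }
  core <- NULL
  if (!is.null(obj$core_levels)) {
    core <- do.call(rbind, lapply(obj$core_levels, as.data.frame))
  }
  dm <- NULL
  if (!is.null(obj$dipole_model)) {
    dm <- lapply(obj$dipole_model, function(d) {
      out <- list(const = do.call(rbind, lapply(d$const, unlist)))
      if (!is.null(d$linear)) {
        out$linear <- do.call(rbind, lapply(d$linear, unlist))
      }
      out
    })
  }
  lvc_parameters(unlist(obj$frequencies), unlist(obj$offsets),
                 do.call(rbind, lapply(obj$kappa, unlist)), lambda,
                 lambda0 = lambda0, core_levels = core, dipole_model = dm)
}
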