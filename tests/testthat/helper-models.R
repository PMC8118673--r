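# Shared model fixtures, all built in code.

# minimal coupled 2-state, 2-mode LVC model with both constant and linear
# inter-state coupling
tiny_lvc <- function(lam0 = 0.004, lam_lin = 0.002) {
  lambda <- array(0, c(2, 2, 2))
  lambda[1, 2, 2] <- lambda[2, 1, 2] <- lam_lin
  lvc_parameters(omega = c(0.002, 0.003), offsets = c(0.40, 0.43),
                 kappa = rbind(c(0.002, -0.001), c(-0.003, 0.002)),
                 lambda = lambda,
                 lambda0 = rbind(c(0, lam0), c(lam0, 0)))
}

# water-like geometry for geometry-level tests
water_geometry <- function() {
  molecular_geometry(c("O", "H", "H"),
                     rbind(c(0, 0, 0.1173),
                           c(0, 0.7572, -0.4692),
                           c(0, -0.7572, -0.4692)))
}

# analytic harmonic-bond Hessian of a diatomic along z (hartree/bohr^2)
diatomic_hessian <- function(k = 0.3) {
  H <- matrix(0, 6, 6)
  H[3, 3] <- H[6, 6] <- k
  H[3, 6] <- H[6, 3] <- -k
  H
}

# mock analytic "HF engine": a closed-shell diatomic whose total energy and
# orbital energies are smooth functions of the internuclear distance only
# (hence exactly invariant under rigid motions).  Two "core" orbitals
# localized one per atom, three valence orbitals.  The AO basis is one
# function per orbital per atom with identity-ish overlap so Mulliken
# populations are transparent.
mock_hf_backend <- function() {
  function(symbols, coords, charge = 0, multiplicity = 1, basis = "mock") {
    stopifnot(length(symbols) == 2)
    r <- sqrt(sum((coords[1, ] - coords[2, ])^2)) / units_au$bohr_ang  # bohr
    r0 <- 2.0
    e_hf <- -20 + 0.25 * (r - r0)^2
    eps <- c(-15.0 - 0.02 * (r - r0),        # core on atom 1
             -11.0 + 0.015 * (r - r0),       # core on atom 2
             -0.80 + 0.05 * (r - r0),
             -0.55 - 0.08 * (r - r0) + 0.01 * (r - r0)^2,
             -0.40 + 0.06 * (r - r0))
    nbf <- 6
    # orbital mixing angle varies with r so Loewdin overlaps change
    th <- 0.2 * (r - r0)
    C <- matrix(0, nbf, 5)
    C[1, 1] <- 1                      # core 1 on atom 1 AO
    C[4, 2] <- 1                      # core 2 on atom 2 AO
    C[2, 3] <- cos(th); C[5, 3] <- sin(th)
    C[2, 4] <- -sin(th); C[5, 4] <- cos(th)
    C[3, 5] <- 0.8; C[6, 5] <- 0.6
    dip <- array(0, c(2, 5, 3))
    dip[1, , 1] <- c(0, 0, 0.3, 0.2 + 0.05 * (r - r0), 0.1)
    dip[2, , 1] <- c(0, 0, 0.1, 0.25, 0.15)
    list(e_hf = e_hf, eps_occ = eps, mo_coeff = C, overlap = diag(nbf),
         ao_atom = c(1, 1, 1, 2, 2, 2),
         dipole_blocks = list(core_idx = c(1, 2), d = dip))
  }
}

mock_geometry <- function(r_ang = 2.0 * units_au$bohr_ang) {
  molecular_geometry(c("O", "C"), rbind(c(0, 0, 0), c(0, 0, r_ang)))
}

# hand-constructed trajectory with prescribed spectral descriptors
planted_spectral_trajectory <- function(times, active, hole_level_by_state,
                                        core_levels, dip2_by_state) {
  nt <- length(times)
  ns <- length(hole_level_by_state)
  nsite <- nrow(core_levels)
  hl <- matrix(rep(hole_level_by_state, each = nt), nt, ns)
  dip2 <- array(0, c(nt, nsite, ns))
  for (s in seq_len(nsite)) {
    for (a in seq_len(ns)) dip2[, s, a] <- dip2_by_state[s, a]
  }
  structure(list(times = times, active = as.integer(active),
                 energies = -hl, hole_levels = hl,
                 core_levels = core_levels, dip2 = dip2,
                 hops = data.frame(), provenance = list(kind = "planted"),
                 flags = list(truncated = FALSE)),
            class = "fssh_trajectory")
}

planted_ensemble <- function(trajs) {
  structure(list(trajectories = trajs, failed = list(),
                 config = list(dt = NA)), class = "fssh_ensemble")
}
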