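#' The external Hartree-Fock backend contract
#'
#' A backend is a function
#' `function(symbols, coords, charge, multiplicity, basis)` (coords in
#' Angstrom) returning a list with at least:
#' \describe{
#'   \item{e_hf}{converged neutral HF total energy (hartree)}
#'   \item{eps_occ}{occupied orbital energies, ascending (hartree)}
#'   \item{mo_coeff}{AO x occupied-MO coefficient matrix}
#'   \item{overlap}{AO overlap matrix}
#'   \item{ao_atom}{1-based atom index of each AO row}
#'   \item{dipole_blocks}{optional: `core_idx` (MO indices) and `d`
#'     (length(core_idx) x n_occ x 3 array of MO-basis transition dipoles,
#'     a.u.)}
#' }
#' SCF failures should be signalled as errors; they are surfaced with the
#' offending geometry attached.
#'
#' @name hf_backend_contract
NULL

#' Replay backend for recorded engine output
#'
#' Wraps a directory of plain-text single-point output from an external
#' Hartree-Fock engine as a backend. The replay refuses geometries other
#' than the recorded one (within `tol` Angstrom after optimal matching of
#' atom order is NOT attempted - atom order must agree).
#'
#' @param dir directory with `header.json`, `mo_occ_coeff.txt`,
#'   `overlap_utri.txt`, `core_dipoles.txt`.
#' @param tol coordinate agreement tolerance (Angstrom).
#' @return a backend function; its `geometry` attribute holds the recorded
#'   [molecular_geometry()] and `basis` the recorded basis label.
#' @export
recorded_hf_backend <- function(dir, tol = 1e-5) {
  hdr <- jsonlite::read_json(file.path(dir, "header.json"),
                             simplifyVector = TRUE)
  nbf <- hdr$n_basis
  nocc <- hdr$n_occ
  C <- matrix(scan(file.path(dir, "mo_occ_coeff.txt"), quiet = TRUE,
                   comment.char = "#"), nbf, nocc, byrow = TRUE)
  ut <- scan(file.path(dir, "overlap_utri.txt"), quiet = TRUE,
             comment.char = "#")
  S <- matrix(0, nbf, nbf)
  # stored row-major by upper-triangle row; equals column-major order of
  # the lower triangle for a symmetric matrix
  S[lower.tri(S, diag = TRUE)] <- ut
  S <- S + t(S) - diag(diag(S))
  dd <- matrix(scan(file.path(dir, "core_dipoles.txt"), quiet = TRUE,
                    comment.char = "#"), ncol = 3, byrow = TRUE)
  n_core <- nrow(dd) / nocc
  dip <- aperm(array(t(dd), c(3, nocc, n_core)), c(3, 2, 1))
  geom <- molecular_geometry(hdr$symbols,
                             matrix(hdr$coords_angstrom, ncol = 3))
  out <- list(e_hf = hdr$e_hf_hartree, eps_occ = hdr$eps_occ_hartree,
              mo_coeff = C, overlap = S, ao_atom = hdr$ao_atom,
              dipole_blocks = list(core_idx = seq_len(n_core), d = dip))
  backend <- function(symbols, coords, charge = 0, multiplicity = 1,
                      basis = hdr$basis) {
    if (!identical(as.character(symbols), geom$symbols) ||
        !identical(basis, hdr$basis) || charge != hdr$charge ||
        max(abs(coords - geom$coords)) > tol) {
      stop("recorded backend only holds ", hdr$basis, " output for its ",
           "recorded geometry; requested point differs")
    }
    out
  }
  attr(backend, "geometry") <- geom
  attr(backend, "basis") <- hdr$basis
  attr(backend, "engine") <- hdr$engine
  backend
}

#' Packaged urea HF/6-31+G* reference backend
#'
#' Single-point output at the optimized neutral geometry, recorded from a
#' restricted Hartree-Fock engine (see the package vignette for
#' provenance and validation of the recorded data).
#'
#' @return a replay backend (see [recorded_hf_backend()]).
#' @export
urea_hf_backend <- function() {
  recorded_hf_backend(system.file("extdata", "urea_hf",
                                  package = "holehop", mustWork = TRUE))
}

#' Gross Mulliken population of each occupied MO on each atom
#'
#' @param mo_coeff AO x MO matrix.
#' @param overlap AO overlap.
#' @param ao_atom atom index per AO.
#' @param n_atoms atom count.
#' @return n_MO x n_atoms matrix (rows sum to 1 for normalized MOs).
#' @export
mulliken_mo_populations <- function(mo_coeff, overlap, ao_atom, n_atoms) {
  SC <- overlap %*% mo_coeff
  contrib <- mo_coeff * SC
  t(rowsum(contrib, group = ao_atom, reorder = TRUE))[, seq_len(n_atoms),
                                                      drop = FALSE]
}

#' Hole states of the ionized molecule via Koopmans' theorem
#'
#' Builds the cation manifold from a neutral HF calculation: a state with
#' a hole in occupied orbital i has energy E_i = E_HF - eps_i, so the
#' ground cation state is the HOMO hole and binding energies are -eps_i.
#' Core 1s orbitals (Mulliken population above `core_threshold` on a
#' single atom and orbital energy below `core_energy_cutoff`) are excluded
#' from the valence manifold and reported as core levels, assigned to
#' elements by their dominant atom.
#'
#' @param geometry a [molecular_geometry()].
#' @param n_states number of tracked valence hole states (counted down
#'   from the HOMO).
#' @param backend a backend function (see [hf_backend_contract]).
#' @param charge,multiplicity,basis forwarded to the backend (neutral
#'   closed-shell defaults).
#' @param core_threshold single-atom Mulliken population above which an
#'   orbital counts as a core candidate (default 0.9).
#' @param core_energy_cutoff orbital energy (hartree) below which core
#'   candidates are accepted; separates 1s levels from deep valence.
#' @return a [pes_evaluation()]: `state_energies` ascending (hartree,
#'   relative to the same zero as `reference_energy = e_hf`),
#'   `hole_levels` = orbital energies of the vacated valence MOs,
#'   `core_levels` data.frame, `hole_dipoles` (core site x state x 3) when
#'   the backend provides dipole blocks. Gradients/NACs are left NULL
#'   here; see [koopmans_fd_gradients()].
#' @export
evaluate_koopmans_states <- function(geometry, n_states, backend,
                                     charge = 0, multiplicity = 1,
                                     basis = NULL, core_threshold = 0.9,
                                     core_energy_cutoff = -5) {
  args <- list(geometry$symbols, geometry$coords, charge, multiplicity)
  if (!is.null(basis)) args$basis <- basis
  out <- tryCatch(do.call(backend, args), error = function(e) {
    stop("backend failed (", conditionMessage(e), ") at geometry:\n",
         paste(utils::capture.output(print(geometry)), collapse = "\n"),
         call. = FALSE)
  })
  eps <- out$eps_occ
  nocc <- length(eps)
  pop <- mulliken_mo_populations(out$mo_coeff, out$overlap, out$ao_atom,
                                 n_atoms(geometry))
  dominant <- apply(pop, 1, which.max)
  dom_pop <- pop[cbind(seq_len(nocc), dominant)]
  is_core <- dom_pop > core_threshold & eps < core_energy_cutoff
  valence <- which(!is_core)
  if (length(valence) < n_states) {
    stop("requested ", n_states, " hole states but only ", length(valence),
         " occupied valence orbitals are available")
  }
  # hole states counted down from the HOMO (= largest orbital energy)
  hole_mos <- valence[order(eps[valence], decreasing = TRUE)][seq_len(n_states)]
  E <- out$e_hf - eps[hole_mos]           # ascending: HOMO hole first
  core_idx <- which(is_core)
  core_atoms <- dominant[core_idx]
  core <- data.frame(
    site = paste0(geometry$symbols[core_atoms], core_atoms),
    element = geometry$symbols[core_atoms],
    energy = eps[core_idx], mo = core_idx, atom = core_atoms,
    population = dom_pop[core_idx], stringsAsFactors = FALSE)
  dip <- NULL
  if (!is.null(out$dipole_blocks)) {
    db <- out$dipole_blocks
    rows <- match(core_idx, db$core_idx)
    if (!anyNA(rows)) {
      dip <- array(0, c(length(core_idx), n_states, 3))
      for (s in seq_along(rows)) {
        dip[s, , ] <- db$d[rows[s], hole_mos, ]
      }
    }
  }
  pes_evaluation(state_energies = E, reference_energy = out$e_hf,
                 core_levels = core, hole_levels = eps[hole_mos],
                 hole_dipoles = dip,
                 state_vectors = NULL,
                 flags = list(hole_mos = hole_mos, n_core = length(core_idx)))
}

#' Valence binding energies from a Koopmans evaluation (eV)
#'
#' @param eval output of [evaluate_koopmans_states()].
#' @return numeric vector, ascending (HOMO first).
#' @export
binding_energies <- function(eval) {
  .ha2ev(eval$state_energies - eval$reference_energy)
}

#' Rigid K-edge shifts implied by computed 1s binding energies
#'
#' The frozen-orbital (Koopmans) 1s binding energy -eps_1s overestimates
#' the experimental K-edge ionization potential because core-hole
#' relaxation is neglected; the difference is the rigid down-shift applied
#' to computed spectra. Same-element sites are averaged.
#'
#' @param eval output of [evaluate_koopmans_states()] (carries
#'   `core_levels`).
#' @param experimental_edges named experimental K-edge ionization
#'   potentials in eV.
#' @return data.frame: element, computed 1s binding energy (eV),
#'   experimental edge (eV), shift = computed - experimental (eV).
#' @export
koopmans_edge_shifts <- function(eval,
                                 experimental_edges = c(C = 289, N = 399,
                                                        O = 535)) {
  core <- eval$core_levels
  stopifnot(!is.null(core), nrow(core) > 0)
  be <- tapply(-.ha2ev(core$energy), core$element, mean)
  els <- intersect(names(experimental_edges), names(be))
  data.frame(element = els,
             computed_be = as.numeric(be[els]),
             experimental_edge = as.numeric(experimental_edges[els]),
             shift = as.numeric(be[els] - experimental_edges[els]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' @keywords internal
.lowdin_orbitals <- function(mo_coeff, overlap) {
  eg <- eigen(overlap, symmetric = TRUE)
  shalf <- eg$vectors %*% (t(eg$vectors) * sqrt(pmax(eg$values, 0)))
  shalf %*% mo_coeff
}

#' Finite-difference gradients and couplings for live HF backends
#'
#' Hole-state gradients by central differences of E_HF - eps_i (step
#' `step` bohr), with orbitals at displaced geometries matched to the
#' reference by maximum overlap of Loewdin-orthogonalized MO coefficients
#' (ties broken by energy order). Nonadiabatic couplings from the
#' antisymmetrized finite-difference orbital overlap
#' (<i(R)|j(R+delta)> - <i(R-delta)|j(R)>)/(2 delta).
#'
#' This replaces analytic coupled-perturbed HF derivatives: adequate for
#' small molecules, and exact derivatives remain available through the LVC
#' backend for all dynamical tests.
#'
#' @param geometry a [molecular_geometry()].
#' @param n_states tracked hole states.
#' @param backend a live backend (callable at arbitrary geometries).
#' @param step displacement in bohr (default 1e-3).
#' @param ... forwarded to [evaluate_koopmans_states()].
#' @return the centre-point [pes_evaluation()] with `state_gradients`
#'   (n_states x 3N, hartree/bohr) and `nac` (1/bohr) filled in.
#' @export
koopmans_fd_gradients <- function(geometry, n_states, backend,
                                  step = 1e-3, ...) {
  ev0 <- evaluate_koopmans_states(geometry, n_states, backend, ...)
  out0 <- backend(geometry$symbols, geometry$coords, 0, 1)
  U0 <- .lowdin_orbitals(out0$mo_coeff, out0$overlap)
  hole0 <- ev0$flags$hole_mos
  n <- n_atoms(geometry)
  grads <- matrix(0, n_states, 3 * n)
  nac <- array(0, c(n_states, n_states, 3 * n))
  step_ang <- .bohr2ang(step)
  for (d in seq_len(3 * n)) {
    at <- (d - 1) %/% 3 + 1
    ax <- (d - 1) %% 3 + 1
    shift <- function(sgn) {
      g <- geometry
      g$coords[at, ax] <- g$coords[at, ax] + sgn * step_ang
      g
    }
    outp <- backend(geometry$symbols, shift(+1)$coords, 0, 1)
    outm <- backend(geometry$symbols, shift(-1)$coords, 0, 1)
    Up <- .lowdin_orbitals(outp$mo_coeff, outp$overlap)
    Um <- .lowdin_orbitals(outm$mo_coeff, outm$overlap)
    # match displaced orbitals to the reference holes by maximum overlap
    map_sign <- function(U1) {
      ov <- crossprod(U0[, hole0, drop = FALSE], U1)
      idx <- integer(n_states); sgn <- numeric(n_states)
      for (i in seq_len(n_states)) {
        j <- which.max(abs(ov[i, ]))
        idx[i] <- j; sgn[i] <- sign(ov[i, j])
      }
      list(idx = idx, sgn = sgn, ov = ov)
    }
    mp <- map_sign(Up); mm <- map_sign(Um)
    Ep <- outp$e_hf - outp$eps_occ[mp$idx]
    Em <- outm$e_hf - outm$eps_occ[mm$idx]
    grads[, d] <- (Ep - Em) / (2 * step)
    ovp <- crossprod(U0[, hole0, drop = FALSE],
                     sweep(Up[, mp$idx, drop = FALSE], 2, mp$sgn, "*"))
    ovm <- crossprod(U0[, hole0, drop = FALSE],
                     sweep(Um[, mm$idx, drop = FALSE], 2, mm$sgn, "*"))
    nac[, , d] <- (ovp - ovm) / (2 * step)
  }
  # enforce exact antisymmetry (finite differences break it at O(step^2))
  for (d in seq_len(3 * n)) {
    A <- nac[, , d]
    nac[, , d] <- (A - t(A)) / 2
  }
  ev0$state_gradients <- grads
  ev0$nac <- nac
  ev0
}

#' Wrap a live Koopmans backend as a PES provider
#'
#' Lets [run_trajectory()] propagate on ab initio hole-state surfaces.
#' Coordinates are flat Cartesian bohr; masses are per-dof atomic masses
#' in electron-mass units.
#'
#' @param geometry template [molecular_geometry()] (symbols, masses).
#' @param n_states tracked hole states.
#' @param backend live backend function.
#' @param step finite-difference step (bohr).
#' @param ... forwarded to the Koopmans evaluator.
#' @return a `pes_provider`.
#' @export
make_koopmans_pes <- function(geometry, n_states, backend, step = 1e-3,
                              ...) {
  masses <- rep(geometry$masses * units_au$amu_me, each = 3)
  fun <- function(x) {
    g <- geometry
    g$coords <- .bohr2ang(matrix(x, ncol = 3, byrow = TRUE))
    koopmans_fd_gradients(g, n_states, backend, step = step, ...)
  }
  structure(list(fun = fun, masses = masses, n_states = n_states,
                 kind = "koopmans", coord = "cartesian"),
            class = "pes_provider")
}
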