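#' Normal-mode set of a molecular minimum
#'
#' Equilibrium geometry, harmonic frequencies (cm^-1) and mass-weighted
#' Cartesian displacement vectors, orthonormal in the mass-weighted metric.
#' Translations/rotations are assumed already removed (`n_skipped` records
#' how many were discarded).
#'
#' @param equilibrium a [molecular_geometry()].
#' @param frequencies per-mode harmonic frequency in cm^-1, all > 0.
#' @param displacements 3N x n_modes matrix of mass-weighted displacement
#'   vectors (columns), orthonormal to 1e-6.
#' @param n_skipped number of discarded zero-frequency modes.
#' @return object of class `normal_mode_set`.
#' @export
normal_mode_set <- function(equilibrium, frequencies, displacements,
                            n_skipped = 6L) {
  stopifnot(inherits(equilibrium, "molecular_geometry"))
  displacements <- as.matrix(displacements)
  nm <- length(frequencies)
  stopifnot(ncol(displacements) == nm,
            nrow(displacements) == 3L * n_atoms(equilibrium))
  if (any(frequencies <= 0)) {
    stop("retained mode frequencies must be positive; offending mode(s): ",
         paste(which(frequencies <= 0), collapse = ", "))
  }
  orth <- crossprod(displacements) - diag(nm)
  if (max(abs(orth)) > 1e-6) {
    stop("displacement vectors are not orthonormal (max deviation ",
         format(max(abs(orth))), ")")
  }
  structure(list(equilibrium = equilibrium,
                 frequencies = as.numeric(frequencies),
                 displacements = displacements,
                 n_skipped = as.integer(n_skipped)),
            class = "normal_mode_set")
}

#' @export
print.normal_mode_set <- function(x, ...) {
  cat("<normal_mode_set> ", length(x$frequencies), " modes, ",
      n_atoms(x$equilibrium), " atoms; frequencies ",
      sprintf("%.1f", min(x$frequencies)), "-",
      sprintf("%.1f", max(x$frequencies)), " cm^-1\n", sep = "")
  invisible(x)
}

#' Normal modes from a Cartesian Hessian
#'
#' Mass-weights and diagonalizes a (mass-unweighted) Cartesian second
#' derivative matrix in hartree/bohr^2, discarding the 6 modes of smallest
#' |omega| (5 for linear molecules, detected from the rank of the inertia
#' tensor). Warns when more than the expected number of near-zero
#' frequencies (< 10 cm^-1) remain, which indicates a non-minimum geometry.
#'
#' @param geometry a [molecular_geometry()].
#' @param hessian symmetric 3N x 3N matrix, hartree/bohr^2.
#' @return a [normal_mode_set()].
#' @export
modes_from_hessian <- function(geometry, hessian) {
  n <- n_atoms(geometry)
  hessian <- as.matrix(hessian)
  stopifnot(nrow(hessian) == 3 * n, ncol(hessian) == 3 * n)
  if (max(abs(hessian - t(hessian))) > 1e-8) stop("hessian must be symmetric")
  m_me <- rep(geometry$masses * units_au$amu_me, each = 3)
  Hmw <- hessian / sqrt(outer(m_me, m_me))
  eg <- eigen(Hmw, symmetric = TRUE)
  omega_au <- sqrt(abs(eg$values)) * sign(eg$values)  # imaginary -> negative
  freq_cm <- omega_au / units_au$cm1_hartree

  # linear molecule: inertia tensor has one (near-)zero principal moment
  x <- .ang2bohr(geometry$coords)
  m <- geometry$masses
  x <- sweep(x, 2, colSums(x * m) / sum(m))
  I3 <- diag(sum(m * rowSums(x^2)), 3) - t(x * m) %*% x
  mom <- eigen(I3, symmetric = TRUE, only.values = TRUE)$values
  linear <- n > 1 && (min(abs(mom)) < 1e-8 * max(abs(mom), 1))
  n_skip <- if (n == 2 || linear) 5L else 6L
  n_skip <- min(n_skip, 3L * n)

  keep <- order(abs(freq_cm))[-seq_len(n_skip)]
  keep <- keep[order(freq_cm[keep])]
  if (sum(abs(freq_cm[keep]) < 10) > 0) {
    warning("near-zero retained frequencies; geometry is likely not a minimum")
  }
  normal_mode_set(geometry, freq_cm[keep],
                  eg$vectors[, keep, drop = FALSE], n_skipped = n_skip)
}

#' Plain-text normal-mode file IO
#'
#' Block format: a line `frequency <value cm^-1>` followed by 3N
#' displacement components, repeated per mode; preceded by the equilibrium
#' geometry as an embedded XYZ block.
#'
#' @param modes a [normal_mode_set()].
#' @param path file path.
#' @export
write_modes <- function(modes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  g <- modes$equilibrium
  writeLines(c(as.character(n_atoms(g)), "equilibrium geometry"), con)
  writeLines(sprintf("%-3s % .10f % .10f % .10f", g$symbols,
                     g$coords[, 1], g$coords[, 2], g$coords[, 3]), con)
  writeLines(sprintf("n_skipped %d", modes$n_skipped), con)
  for (k in seq_along(modes$frequencies)) {
    writeLines(sprintf("frequency %.8f", modes$frequencies[k]), con)
    writeLines(sprintf("% .12e", modes$displacements[, k]), con)
  }
  invisible(path)
}

#' @rdname write_modes
#' @export
read_modes <- function(path) {
  lines <- readLines(path)
  n <- as.integer(lines[1])
  parts <- do.call(rbind, strsplit(trimws(lines[3:(2 + n)]), "\\s+"))
  g <- molecular_geometry(parts[, 1], matrix(as.numeric(parts[, 2:4]), ncol = 3))
  i <- 3 + n
  n_skip <- as.integer(sub("n_skipped\\s+", "", lines[i]))
  i <- i + 1
  freqs <- numeric()
  disp <- NULL
  while (i <= length(lines) && grepl("^frequency", lines[i])) {
    freqs <- c(freqs, as.numeric(sub("frequency\\s+", "", lines[i])))
    v <- as.numeric(lines[(i + 1):(i + 3 * n)])
    disp <- cbind(disp, v)
    i <- i + 1 + 3 * n
  }
  normal_mode_set(g, freqs, disp, n_skipped = n_skip)
}

#' @keywords internal
.child_seed <- function(master, i) {
  as.integer((as.double(master) + as.double(i) * 1000003) %%
               (.Machine$integer.max - 1L)) + 1L
}

#' Sample the ground-state harmonic Wigner distribution
#'
#' For the vibrational ground state each mode's Wigner function is a
#' Gaussian in both the mass-weighted coordinate and its momentum:
#' Q_k ~ N(0, hbar / 2 omega_k), P_k ~ N(0, hbar omega_k / 2),
#' independently (temperature 0 K). Samples are transformed to Cartesian
#' positions (Angstrom) and velocities (Angstrom/fs); center-of-mass
#' translation and rigid rotation are projected out of the velocities so
#' ensembles do not carry spurious drift or rotational heating.
#'
#' Reproducibility: sample i is drawn under a child seed derived from
#' `seed` by a fixed splitting rule, so enlarging an ensemble leaves
#' earlier samples unchanged.
#'
#' @param modes a [normal_mode_set()].
#' @param n_samples ensemble size.
#' @param seed master integer seed.
#' @return list of `phase_space_sample` objects: `coords` (Angstrom),
#'   `velocities` (Angstrom/fs), `seed_id`.
#' @export
sample_wigner <- function(modes, n_samples, seed = 1L) {
  stopifnot(n_samples >= 1)
  om_au <- modes$frequencies * units_au$cm1_hartree
  if (any(om_au <= 0)) {
    stop("imaginary/zero frequency among retained modes: mode ",
         paste(which(om_au <= 0), collapse = ", "))
  }
  g <- modes$equilibrium
  m_me <- rep(g$masses * units_au$amu_me, each = 3)
  L <- modes$displacements
  x0_bohr <- as.numeric(t(.ang2bohr(g$coords)))  # x1 y1 z1 x2 ...
  out <- vector("list", n_samples)
  for (i in seq_len(n_samples)) {
    sid <- .child_seed(seed, i)
    set.seed(sid)
    Qk <- stats::rnorm(length(om_au), sd = sqrt(1 / (2 * om_au)))
    Pk <- stats::rnorm(length(om_au), sd = sqrt(om_au / 2))
    dx <- as.numeric(L %*% Qk) / sqrt(m_me)
    v <- as.numeric(L %*% Pk) / sqrt(m_me)     # bohr / a.u. time
    x <- x0_bohr + dx
    v <- .project_rigid_body(x, v, m_me)
    coords <- .bohr2ang(matrix(x, ncol = 3, byrow = TRUE))
    vel <- matrix(v, ncol = 3, byrow = TRUE) *
      units_au$bohr_ang / units_au$au_fs   # Angstrom / fs
    out[[i]] <- structure(list(coords = coords, velocities = vel,
                               seed_id = sid),
                          class = "phase_space_sample")
  }
  out
}

#' Remove net translation and rotation from a velocity field
#' @keywords internal
.project_rigid_body <- function(x_bohr, v_au, m_me) {
  xm <- matrix(x_bohr, ncol = 3, byrow = TRUE)
  vm <- matrix(v_au, ncol = 3, byrow = TRUE)
  m <- m_me[seq(1, length(m_me), by = 3)]
  M <- sum(m)
  # remove center-of-mass velocity
  vcm <- colSums(vm * m) / M
  vm <- sweep(vm, 2, vcm)
  # remove rigid rotation about the center of mass: v -> v - w x r
  com <- colSums(xm * m) / M
  r <- sweep(xm, 2, com)
  Lang <- colSums(m * cbind(r[, 2] * vm[, 3] - r[, 3] * vm[, 2],
                            r[, 3] * vm[, 1] - r[, 1] * vm[, 3],
                            r[, 1] * vm[, 2] - r[, 2] * vm[, 1]))
  I3 <- diag(sum(m * rowSums(r^2)), 3) - t(r * m) %*% r
  w <- tryCatch(solve(I3, Lang), error = function(e) {
    ig <- eigen(I3, symmetric = TRUE)
    keep <- ig$values > 1e-10 * max(ig$values)
    ig$vectors[, keep, drop = FALSE] %*%
      (crossprod(ig$vectors[, keep, drop = FALSE], Lang) / ig$values[keep])
  })
  vm <- vm - cbind(w[2] * r[, 3] - w[3] * r[, 2],
                   w[3] * r[, 1] - w[1] * r[, 3],
                   w[1] * r[, 2] - w[2] * r[, 1])
  as.numeric(t(vm))
}

#' Wigner samples for dimensionless LVC mode coordinates
#'
#' In dimensionless normal coordinates the ground-state Wigner distribution
#' is Q_k ~ N(0, 1/2), P_k ~ N(0, 1/2) for every mode; velocities are
#' `omega * P`. Uses the same seed-splitting rule as [sample_wigner()].
#'
#' @param params an [lvc_parameters()] object (frequencies set velocities).
#' @param n_samples ensemble size.
#' @param seed master integer seed.
#' @return list with elements `Q`, `P` (n_samples x n_modes) and `seeds`.
#' @export
sample_wigner_modes <- function(params, n_samples, seed = 1L) {
  nm <- params$n_modes
  Q <- P <- matrix(0, n_samples, nm)
  seeds <- integer(n_samples)
  for (i in seq_len(n_samples)) {
    seeds[i] <- .child_seed(seed, i)
    set.seed(seeds[i])
    Q[i, ] <- stats::rnorm(nm, sd = sqrt(0.5))
    P[i, ] <- stats::rnorm(nm, sd = sqrt(0.5))
  }
  list(Q = Q, P = P, seeds = seeds)
}

#' Net linear and angular momentum of a phase-space sample (a.u.)
#'
#' Diagnostic used by the sampling invariants: both should vanish after
#' rigid-body projection.
#'
#' @param sample a `phase_space_sample`.
#' @param geometry the parent [molecular_geometry()] (for masses).
#' @return list with `linear` (3-vector) and `angular` (3-vector), a.u.
#' @export
sample_momenta <- function(sample, geometry) {
  m <- geometry$masses * units_au$amu_me
  v <- sample$velocities / units_au$bohr_ang * units_au$au_fs  # bohr / a.u.
  x <- .ang2bohr(sample$coords)
  p <- v * m
  com <- colSums(x * m) / sum(m)
  r <- sweep(x, 2, com)
  list(linear = colSums(p),
       angular = colSums(cbind(r[, 2] * p[, 3] - r[, 3] * p[, 2],
                               r[, 3] * p[, 1] - r[, 1] * p[, 3],
                               r[, 1] * p[, 2] - r[, 2] * p[, 1])))
}
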