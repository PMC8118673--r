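#' Electronic-state populations of an ensemble
#'
#' Fraction of alive trajectories whose active state has a given energy
#' rank, per frame time. Rows sum to 1 over the alive trajectories.
#'
#' @param ensemble an `fssh_ensemble`.
#' @return object of class `population_curve`: `times` (fs), `populations`
#'   (time x state matrix), `n_alive`.
#' @export
state_populations <- function(ensemble) {
  trajs <- ensemble$trajectories
  stopifnot(length(trajs) >= 1)
  times <- trajs[[which.max(vapply(trajs, function(t) length(t$times),
                                   1L))]]$times
  ns <- ncol(trajs[[1]]$energies)
  nt <- length(times)
  counts <- matrix(0, nt, ns)
  alive <- integer(nt)
  for (tr in trajs) {
    m <- length(tr$times)
    idx <- cbind(seq_len(m), tr$active)
    for (i in seq_len(m)) counts[i, tr$active[i]] <- counts[i, tr$active[i]] + 1
    alive[seq_len(m)] <- alive[seq_len(m)] + 1L
  }
  pops <- counts / ifelse(alive > 0, alive, NA_real_)
  structure(list(times = times, populations = pops, n_alive = alive),
            class = "population_curve")
}

#' @export
print.population_curve <- function(x, ...) {
  cat("<population_curve> ", ncol(x$populations), " states, ",
      length(x$times), " frames; final populations: ",
      paste(sprintf("%.3f", x$populations[nrow(x$populations), ]),
            collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Internal-coordinate specification
#'
#' @param kinds character vector: "bond", "angle" or "dihedral".
#' @param indices list of integer vectors (2/3/4 atom indices, distinct
#'   within each entry).
#' @param labels optional coordinate names.
#' @return object of class `internal_coordinate_spec`.
#' @export
internal_coordinate_spec <- function(kinds, indices, labels = NULL) {
  need <- c(bond = 2L, angle = 3L, dihedral = 4L)
  stopifnot(all(kinds %in% names(need)), length(kinds) == length(indices))
  for (i in seq_along(indices)) {
    ix <- indices[[i]]
    if (length(ix) != need[[kinds[i]]] || anyDuplicated(ix)) {
      stop("entry ", i, ": ", kinds[i], " needs ", need[[kinds[i]]],
           " distinct atom indices")
    }
  }
  if (is.null(labels)) {
    labels <- vapply(seq_along(kinds), function(i) {
      paste0(substr(kinds[i], 1, 1), "(",
             paste(indices[[i]], collapse = "-"), ")")
    }, "")
  }
  structure(list(kinds = kinds, indices = indices, labels = labels),
            class = "internal_coordinate_spec")
}

#' All bonds, angles and proper dihedrals from a covalent bond graph
#'
#' Bonds are atom pairs closer than `scale` times the sum of covalent
#' radii; angles are centered on each atom bonded to two others; dihedrals
#' follow each bonded chain of four.
#'
#' @param geometry a [molecular_geometry()].
#' @param scale bond-detection tolerance factor (default 1.2).
#' @return an [internal_coordinate_spec()].
#' @export
default_internal_coordinates <- function(geometry, scale = 1.2) {
  n <- n_atoms(geometry)
  rad <- .atomic_data$covalent_radius[match(geometry$symbols,
                                            .atomic_data$symbol)]
  bonded <- matrix(FALSE, n, n)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      d <- sqrt(sum((geometry$coords[i, ] - geometry$coords[j, ])^2))
      bonded[i, j] <- bonded[j, i] <- d < scale * (rad[i] + rad[j])
    }
  }
  kinds <- character(); idx <- list()
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) if (bonded[i, j]) {
    kinds <- c(kinds, "bond"); idx[[length(idx) + 1]] <- c(i, j)
  }
  for (j in seq_len(n)) {
    nb <- which(bonded[j, ])
    if (length(nb) >= 2) {
      for (p in utils::combn(nb, 2, simplify = FALSE)) {
        kinds <- c(kinds, "angle"); idx[[length(idx) + 1]] <- c(p[1], j, p[2])
      }
    }
  }
  for (j in seq_len(n)) for (k in seq_len(n)) {
    if (j == k || !bonded[j, k]) next
    for (i in which(bonded[j, ])) for (l in which(bonded[k, ])) {
      if (i == k || l == j || i == l || i > l) next
      kinds <- c(kinds, "dihedral"); idx[[length(idx) + 1]] <- c(i, j, k, l)
    }
  }
  internal_coordinate_spec(kinds, idx)
}

#' @keywords internal
.traj_frames_ang <- function(tr) {
  if (!identical(tr$provenance$coord %||% "cartesian", "cartesian")) {
    stop("trajectory coordinates are not Cartesian")
  }
  lapply(seq_along(tr$times), function(i) {
    .bohr2ang(matrix(tr$pos[i, ], ncol = 3, byrow = TRUE))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Internal-coordinate sample matrix of an ensemble
#'
#' Evaluates every specified coordinate on every frame of every trajectory
#' inside the time window; samples are (trajectory, frame) pairs. Bonds in
#' Angstrom, angles/dihedrals in degrees; collinear degeneracies yield NA.
#'
#' @param ensemble `fssh_ensemble` with Cartesian trajectories.
#' @param spec an [internal_coordinate_spec()].
#' @param window length-2 time window in fs (default: all frames).
#' @return samples x coordinates matrix with `trajectory`/`time`
#'   attributes.
#' @export
internal_coordinate_matrix <- function(ensemble, spec, window = NULL) {
  rows <- list(); traj_id <- integer(); tvec <- numeric()
  for (ti in seq_along(ensemble$trajectories)) {
    tr <- ensemble$trajectories[[ti]]
    keep <- if (is.null(window)) seq_along(tr$times) else
      which(tr$times >= window[1] & tr$times <= window[2])
    frames <- .traj_frames_ang(tr)
    for (i in keep) {
      rows[[length(rows) + 1]] <- vapply(seq_along(spec$kinds), function(c) {
        coordinate_value(frames[[i]], spec$indices[[c]])
      }, 0.0)
      traj_id <- c(traj_id, ti); tvec <- c(tvec, tr$times[i])
    }
  }
  X <- do.call(rbind, rows)
  colnames(X) <- spec$labels
  attr(X, "trajectory") <- traj_id
  attr(X, "time") <- tvec
  X
}

#' Per-frame edge-intensity sample matrix
#'
#' Energy-integrated pre-edge intensity of each frame at each requested
#' edge (same-element core sites summed), pooled over (trajectory, frame)
#' samples within the window. This is the response matrix the
#' correlation/PLSR analyses pair with geometric features.
#'
#' @param ensemble `fssh_ensemble` with spectral descriptors.
#' @param edges list of [edge_config()] objects.
#' @param window length-2 time window in fs (default: all frames).
#' @return samples x edges matrix with `trajectory`/`time` attributes.
#' @export
edge_intensity_matrix <- function(ensemble, edges, window = NULL) {
  labs <- vapply(edges, function(e) e$element, "")
  rows <- list(); traj_id <- integer(); tvec <- numeric()
  for (ti in seq_along(ensemble$trajectories)) {
    tr <- ensemble$trajectories[[ti]]
    keep <- if (is.null(window)) seq_along(tr$times) else
      which(tr$times >= window[1] & tr$times <= window[2])
    for (i in keep) {
      a <- tr$active[i]
      rows[[length(rows) + 1]] <- vapply(edges, function(e) {
        sig <- frame_spectrum(tr$core_levels, tr$hole_levels[i, a],
                              tr$dip2[i, , a], e)
        pracma::trapz(e$energy_grid, sig)
      }, 0.0)
      traj_id <- c(traj_id, ti); tvec <- c(tvec, tr$times[i])
    }
  }
  Y <- do.call(rbind, rows)
  colnames(Y) <- labs
  attr(Y, "trajectory") <- traj_id
  attr(Y, "time") <- tvec
  Y
}

#' Pearson correlations between features and responses
#'
#' Plain product-moment correlations per (feature, response) pair.
#' Zero-variance columns are dropped with a warning; rows with NA in a pair
#' are dropped pairwise.
#'
#' @param X samples x features matrix.
#' @param Y samples x responses matrix (or vector).
#' @return object of class `correlation_table`: long data.frame
#'   (`feature`, `response`, `r`) sortable by |r|.
#' @export
pearson_correlations <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (is.null(colnames(Y))) colnames(Y) <- paste0("y", seq_len(ncol(Y)))
  if (nrow(X) < 3) stop("need at least 3 samples")
  vx <- apply(X, 2, stats::var, na.rm = TRUE)
  vy <- apply(Y, 2, stats::var, na.rm = TRUE)
  if (any(vx == 0 | is.na(vx))) {
    warning("dropping zero-variance feature(s): ",
            paste(colnames(X)[vx == 0 | is.na(vx)], collapse = ", "))
    X <- X[, vx > 0 & !is.na(vx), drop = FALSE]
  }
  if (any(vy == 0 | is.na(vy))) {
    warning("dropping zero-variance response(s): ",
            paste(colnames(Y)[vy == 0 | is.na(vy)], collapse = ", "))
    Y <- Y[, vy > 0 & !is.na(vy), drop = FALSE]
  }
  if (!ncol(X) || !ncol(Y)) stop("no non-degenerate columns left")
  R <- stats::cor(X, Y, use = "pairwise.complete.obs")
  tbl <- data.frame(feature = rep(rownames(R), times = ncol(R)),
                    response = rep(colnames(R), each = nrow(R)),
                    r = as.vector(R), stringsAsFactors = FALSE)
  structure(list(table = tbl, matrix = R), class = "correlation_table")
}

#' Strongest (anti)correlated features
#'
#' @param ct a [pearson_correlations()] result.
#' @param k how many features to keep (ranked by max |r| over responses).
#' @return subset of the long table, strongest first.
#' @export
top_correlations <- function(ct, k = 10) {
  score <- apply(abs(ct$matrix), 1, max)
  keep <- names(sort(score, decreasing = TRUE))[seq_len(min(k, length(score)))]
  tbl <- ct$table[ct$table$feature %in% keep, ]
  tbl[order(-abs(tbl$r)), ]
}

#' Single-component PLSR collective coordinate
#'
#' Finds the direction in feature space with maximal covariance to the
#' responses: the dominant left singular vector of the X'Y cross-covariance
#' after column standardization of both blocks. Reports the loading vector
#' (unit norm, standardized space), the fraction of response variance a
#' one-component regression on the projection explains (R^2), and the share
#' of total feature variance the projection carries.
#'
#' @param X samples x features.
#' @param Y samples x responses (or vector).
#' @return object of class `collective_coordinate`: `loadings`,
#'   `loadings_raw` (divided by feature sd, renormalized), `r2_y`,
#'   `x_share`, `scores` (per-sample projection), `y_weights`.
#' @export
plsr_collective_coordinate <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  ok <- stats::complete.cases(X) & stats::complete.cases(Y)
  X <- X[ok, , drop = FALSE]; Y <- Y[ok, , drop = FALSE]
  n <- nrow(X)
  stopifnot(n >= 3)
  sx <- apply(X, 2, stats::sd)
  if (any(sx == 0)) stop("zero-variance feature column(s)")
  if (any(apply(Y, 2, stats::sd) == 0)) {
    stop("zero-variance response column(s): cross-covariance undefined")
  }
  Xs <- scale(X); Ys <- scale(Y)
  C <- crossprod(Xs, Ys) / (n - 1)
  if (max(abs(C)) < 1e-14) stop("zero cross-covariance: direction undefined")
  sv <- svd(C, nu = 1, nv = 1)
  w <- as.numeric(sv$u)
  # deterministic sign: strongest loading positive
  if (w[which.max(abs(w))] < 0) w <- -w
  tsc <- as.numeric(Xs %*% w)
  vt <- stats::var(tsc)
  b <- crossprod(Ys, tsc) / ((n - 1) * vt)        # per-response slope
  resid <- Ys - tsc %*% t(b)
  r2 <- 1 - sum(resid^2) / sum(Ys^2)
  names(w) <- colnames(X)
  wraw <- w / sx
  wraw <- wraw / sqrt(sum(wraw^2))
  structure(list(loadings = w, loadings_raw = wraw, r2_y = r2,
                 x_share = vt / ncol(Xs), scores = tsc,
                 y_weights = as.numeric(sv$v), n = n),
            class = "collective_coordinate")
}

#' @export
print.collective_coordinate <- function(x, ...) {
  cat("<collective_coordinate> R2(Y) = ", sprintf("%.3f", x$r2_y),
      ", X variance share = ", sprintf("%.3f", x$x_share), "\n", sep = "")
  top <- sort(abs(x$loadings), decreasing = TRUE)
  top <- top[seq_len(min(5, length(top)))]
  for (nm in names(top)) {
    cat(sprintf("  %-14s % .3f\n", nm, x$loadings[nm]))
  }
  invisible(x)
}

#' Rigid-body-aligned Cartesian feature matrix
#'
#' Every frame is superposed onto the reference geometry (least-squares
#' rotation + translation) before flattening to a 3N feature row, so the
#' features describe internal motion only. Used where a complete internal
#' coordinate set is impractical (e.g. intermolecular motion).
#'
#' @param ensemble `fssh_ensemble` with Cartesian trajectories.
#' @param reference a [molecular_geometry()] with matching atom count/order.
#' @param window length-2 time window in fs (default: all).
#' @return samples x 3N matrix (Angstrom) with `trajectory`/`time`
#'   attributes.
#' @export
cartesian_feature_matrix <- function(ensemble, reference, window = NULL) {
  nref <- n_atoms(reference)
  rows <- list(); traj_id <- integer(); tvec <- numeric()
  for (ti in seq_along(ensemble$trajectories)) {
    tr <- ensemble$trajectories[[ti]]
    frames <- .traj_frames_ang(tr)
    if (nrow(frames[[1]]) != nref) stop("atom-count mismatch with reference")
    keep <- if (is.null(window)) seq_along(tr$times) else
      which(tr$times >= window[1] & tr$times <= window[2])
    for (i in keep) {
      al <- superpose(frames[[i]], reference$coords)
      rows[[length(rows) + 1]] <- as.numeric(t(al))
      traj_id <- c(traj_id, ti); tvec <- c(tvec, tr$times[i])
    }
  }
  X <- do.call(rbind, rows)
  colnames(X) <- paste0(rep(seq_len(nref), each = 3), c("x", "y", "z"))
  attr(X, "trajectory") <- traj_id
  attr(X, "time") <- tvec
  X
}

#' Detect a proton-transfer event in one trajectory
#'
#' Transfer is declared when the acceptor-oxygen-to-donor-hydrogen distance
#' first drops below `threshold` (default 1.25 Angstrom); the transfer time
#' is that first crossing, and later re-crossings do not reset it. Several
#' candidate (H, O) pairs - the two hydrogen bonds of a dimer - are checked
#' and the transferring direction recorded.
#'
#' @param trajectory an `fssh_trajectory`. Either Cartesian (distances are
#'   computed from `donor_h` / `acceptor_o` atom indices) or carrying a
#'   precomputed `distances` matrix (columns = labelled directions), as the
#'   planted synthetic ensembles do.
#' @param donor_h,acceptor_o equal-length integer vectors of candidate
#'   pairs (ignored when the trajectory carries `distances`).
#' @param threshold Angstrom.
#' @param id trajectory identifier for the record.
#' @return a one-row data.frame: `trajectory_id`, `transferred`,
#'   `transfer_time` (fs, NA when no transfer), `direction`.
#' @export
detect_proton_transfer <- function(trajectory, donor_h = NULL,
                                   acceptor_o = NULL, threshold = 1.25,
                                   id = NA_integer_) {
  if (!is.null(trajectory$distances)) {
    D <- trajectory$distances
    dirs <- colnames(D) %||% paste0("dir", seq_len(ncol(D)))
  } else {
    stopifnot(length(donor_h) == length(acceptor_o), length(donor_h) >= 1)
    frames <- .traj_frames_ang(trajectory)
    D <- vapply(seq_along(donor_h), function(p) {
      vapply(frames, function(f) {
        sqrt(sum((f[donor_h[p], ] - f[acceptor_o[p], ])^2))
      }, 0.0)
    }, numeric(length(frames)))
    dirs <- paste0("H", donor_h, ">O", acceptor_o)
  }
  first <- apply(D < threshold, 2, function(z) {
    w <- which(z)
    if (length(w)) w[1] else NA_integer_
  })
  if (all(is.na(first))) {
    return(data.frame(trajectory_id = id, transferred = FALSE,
                      transfer_time = NA_real_, direction = NA_character_,
                      stringsAsFactors = FALSE))
  }
  p <- which.min(ifelse(is.na(first), Inf, first))
  data.frame(trajectory_id = id, transferred = TRUE,
             transfer_time = trajectory$times[first[p]],
             direction = dirs[p], stringsAsFactors = FALSE)
}

#' Proton-transfer records for a whole ensemble
#'
#' @param ensemble an `fssh_ensemble`.
#' @param ... passed to [detect_proton_transfer()].
#' @return data.frame of per-trajectory records.
#' @export
proton_transfer_records <- function(ensemble, ...) {
  do.call(rbind, lapply(seq_along(ensemble$trajectories), function(i) {
    detect_proton_transfer(ensemble$trajectories[[i]], ..., id = i)
  }))
}

#' Transfer fraction and sigmoid timescale
#'
#' The cumulative number of completed transfers N(t) is fitted with the
#' logistic form A / (1 + exp(-(t - t50)/tau)) by nonlinear least squares;
#' t50 is reported as the transfer timescale.
#'
#' @param records data.frame from [proton_transfer_records()].
#' @param times evaluation grid in fs; defaults to an even grid over the
#'   observed transfer times padded by 3 tau-like margins.
#' @return list: `fraction`, `n`, `fit` (NULL when nothing transferred)
#'   with `t50`, `tau`, `slope` (= 1/tau), `plateau`, `cov`, `curve`.
#' @export
transfer_statistics <- function(records, times = NULL) {
  stopifnot(nrow(records) >= 10)
  n <- nrow(records)
  tt <- records$transfer_time[records$transferred]
  frac <- length(tt) / n
  if (!length(tt)) {
    return(list(fraction = 0, n = n, fit = NULL))
  }
  if (is.null(times)) {
    span <- diff(range(tt)) + 1e-6
    times <- seq(max(0, min(tt) - 0.5 * span), max(tt) + 0.5 * span,
                 length.out = 200)
  }
  N <- vapply(times, function(t) sum(tt <= t), 0L)
  start <- list(A = length(tt), t50 = stats::median(tt),
                tau = max(diff(stats::quantile(tt, c(0.25, 0.75))) / 2.2, 0.5))
  df <- data.frame(t = times, N = N)
  fit <- minpack.lm::nlsLM(N ~ A / (1 + exp(-(t - t50) / tau)),
                           data = df, start = start,
                           lower = c(A = 1e-6, t50 = -Inf, tau = 1e-3),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- stats::coef(fit)
  list(fraction = frac, n = n,
       fit = list(t50 = unname(cf["t50"]), tau = unname(cf["tau"]),
                  slope = unname(1 / cf["tau"]), plateau = unname(cf["A"]),
                  cov = stats::vcov(fit),
                  curve = data.frame(t = times, N = N,
                                     fitted = stats::fitted(fit))))
}

#' Split an ensemble by proton-transfer outcome
#'
#' Disjoint, exhaustive partition into transferring and non-transferring
#' subsets, each a full `fssh_ensemble` usable by [ensemble_spectrogram()]
#' and [energy_integrated_trace()].
#'
#' @param ensemble an `fssh_ensemble`.
#' @param records matching records from [proton_transfer_records()].
#' @param direction optional: keep only transfers in this direction in the
#'   "with" subset (others go to "without" is NOT done - they are dropped),
#'   mirroring one-direction selection for symmetry-equivalent pathways.
#' @return list `with`, `without` of `fssh_ensemble` objects.
#' @export
split_ensemble <- function(ensemble, records, direction = NULL) {
  stopifnot(nrow(records) == length(ensemble$trajectories))
  sel <- records$transferred
  if (!is.null(direction)) sel <- sel & records$direction %in% direction
  mk <- function(idx) {
    structure(list(trajectories = ensemble$trajectories[idx],
                   failed = list(), config = ensemble$config),
              class = "fssh_ensemble")
  }
  list(with = mk(which(sel)), without = mk(which(!records$transferred)))
}
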