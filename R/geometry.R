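#' Standard atomic masses (amu) and covalent radii (Angstrom)
#' @keywords internal
.atomic_data <- data.frame(
  symbol = c("H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne",
             "Na", "Mg", "Al", "Si", "P", "S", "Cl", "Ar"),
  mass = c(1.00783, 4.0026, 6.941, 9.0122, 10.811, 12.0000, 14.00307,
           15.99491, 18.99840, 20.1797, 22.98977, 24.305, 26.98154,
           28.0855, 30.97376, 32.065, 34.96885, 39.948),
  covalent_radius = c(0.31, 0.28, 1.28, 0.96, 0.84, 0.76, 0.71, 0.66,
                      0.57, 0.58, 1.66, 1.41, 1.21, 1.11, 1.07, 1.05,
                      1.02, 1.06),
  stringsAsFactors = FALSE
)

#' Molecular geometry container
#'
#' The nuclear configuration consumed by every other module: element
#' symbols, Cartesian coordinates in Angstrom, and atomic masses in amu.
#' Nuclei are treated as classical point particles throughout.
#'
#' @param symbols character vector of element symbols.
#' @param coords numeric matrix, one row per atom, columns x/y/z (Angstrom).
#' @param masses atomic masses in amu; looked up from standard isotopic
#'   masses when omitted.
#' @return An object of class `molecular_geometry`.
#' @examples
#' g <- molecular_geometry(c("O", "H", "H"),
#'                         rbind(c(0, 0, 0.117), c(0, 0.757, -0.469),
#'                               c(0, -0.757, -0.469)))
#' @export
molecular_geometry <- function(symbols, coords, masses = NULL) {
  coords <- matrix(as.numeric(coords), ncol = 3)
  stopifnot(length(symbols) == nrow(coords))
  if (is.null(masses)) {
    idx <- match(symbols, .atomic_data$symbol)
    if (anyNA(idx)) {
      stop("no tabulated mass for element(s): ",
           paste(unique(symbols[is.na(idx)]), collapse = ", "))
    }
    masses <- .atomic_data$mass[idx]
  }
  stopifnot(length(masses) == length(symbols), all(masses > 0))
  structure(list(symbols = as.character(symbols), coords = coords,
                 masses = as.numeric(masses)),
            class = "molecular_geometry")
}

#' @export
print.molecular_geometry <- function(x, ...) {
  cat("<molecular_geometry> ", length(x$symbols), " atoms (",
      paste(x$symbols, collapse = " "), ")\n", sep = "")
  invisible(x)
}

#' Number of atoms
#' @param geometry a `molecular_geometry`.
#' @export
n_atoms <- function(geometry) length(geometry$symbols)

#' Read geometries from an XYZ file
#'
#' Standard XYZ: atom count, comment line, then `symbol x y z` in Angstrom.
#' Multi-frame files are supported; a comment of the form `t = <value> fs`
#' is parsed into the frame time.
#'
#' @param path file path.
#' @return A list of `molecular_geometry` objects with attribute `times`
#'   (fs, `NA` where the comment carries none). A single-frame file returns
#'   a length-1 list.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  frames <- list()
  times <- numeric()
  i <- 1
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1; next }
    n <- as.integer(trimws(lines[i]))
    comment <- lines[i + 1]
    body <- lines[(i + 2):(i + 1 + n)]
    parts <- do.call(rbind, strsplit(trimws(body), "\\s+"))
    g <- molecular_geometry(parts[, 1],
                            matrix(as.numeric(parts[, 2:4]), ncol = 3))
    frames[[length(frames) + 1]] <- g
    tm <- regmatches(comment,
                     regexec("t\\s*=\\s*([-0-9.eE+]+)\\s*fs", comment))[[1]]
    times <- c(times, if (length(tm) == 2) as.numeric(tm[2]) else NA_real_)
    i <- i + 2 + n
  }
  attr(frames, "times") <- times
  frames
}

#' Write geometries to an XYZ file
#'
#' @param geometries a `molecular_geometry` or list of them.
#' @param path output path.
#' @param times optional frame times in fs, written into the comment line.
#' @export
write_xyz <- function(geometries, path, times = NULL) {
  if (inherits(geometries, "molecular_geometry")) geometries <- list(geometries)
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_along(geometries)) {
    g <- geometries[[k]]
    comment <- if (!is.null(times) && !is.na(times[k])) {
      sprintf("t = %.6f fs", times[k])
    } else ""
    writeLines(c(as.character(n_atoms(g)), comment), con)
    writeLines(sprintf("%-3s % .10f % .10f % .10f", g$symbols,
                       g$coords[, 1], g$coords[, 2], g$coords[, 3]), con)
  }
  invisible(path)
}

#' Internal coordinate values from Cartesian coordinates
#'
#' Bond lengths in Angstrom; bond angles and proper dihedrals in degrees.
#' Angles at (near-)collinear arrangements and dihedrals with collinear
#' inner atoms return `NA` rather than an arbitrary value.
#'
#' @param coords numeric matrix (atoms x 3, Angstrom).
#' @param idx integer vector of 2 (bond), 3 (angle) or 4 (dihedral) atom
#'   indices.
#' @return a single numeric value.
#' @export
coordinate_value <- function(coords, idx) {
  idx <- as.integer(idx)
  if (length(idx) == 2) {
    return(sqrt(sum((coords[idx[1], ] - coords[idx[2], ])^2)))
  }
  if (length(idx) == 3) {
    u <- coords[idx[1], ] - coords[idx[2], ]
    v <- coords[idx[3], ] - coords[idx[2], ]
    cn <- sqrt(sum(u^2) * sum(v^2))
    if (cn < 1e-12) return(NA_real_)
    cosang <- sum(u * v) / cn
    s2 <- 1 - cosang^2
    if (s2 < 1e-16 && abs(cosang) > 1 - 1e-10) {
      # exactly (anti)parallel is fine; near-degenerate cross products are not
      return(if (cosang > 0) 0 else 180)
    }
    return(acos(pmin(1, pmax(-1, cosang))) * 180 / pi)
  }
  if (length(idx) == 4) {
    b1 <- coords[idx[2], ] - coords[idx[1], ]
    b2 <- coords[idx[3], ] - coords[idx[2], ]
    b3 <- coords[idx[4], ] - coords[idx[3], ]
    n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
            b1[1] * b2[2] - b1[2] * b2[1])
    n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
            b2[1] * b3[2] - b2[2] * b3[1])
    if (sum(n1^2) < 1e-14 || sum(n2^2) < 1e-14) return(NA_real_)
    m1 <- c(n1[2] * b2[3] - n1[3] * b2[2], n1[3] * b2[1] - n1[1] * b2[3],
            n1[1] * b2[2] - n1[2] * b2[1])
    x <- sum(n1 * n2)
    y <- sum(m1 * n2) / sqrt(sum(b2^2))
    return(atan2(y, x) * 180 / pi)
  }
  stop("idx must have length 2, 3 or 4")
}

#' Least-squares rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation + translation minimizing the mass-unweighted
#' RMSD of `coords` onto `reference`, and returns the transformed
#' coordinates.
#'
#' @param coords,reference atoms x 3 matrices with identical atom order.
#' @return the aligned copy of `coords`, with attribute `rmsd`.
#' @export
superpose <- function(coords, reference) {
  stopifnot(all(dim(coords) == dim(reference)))
  cm_a <- colMeans(coords)
  cm_b <- colMeans(reference)
  A <- sweep(coords, 2, cm_a)
  B <- sweep(reference, 2, cm_b)
  H <- t(A) %*% B
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  out <- sweep(A %*% t(R), 2, cm_b, "+")
  attr(out, "rmsd") <- sqrt(mean(rowSums((out - reference)^2)))
  out
}
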