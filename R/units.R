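#' Physical constants and unit conversions
#'
#' All internal computation uses Hartree atomic units (hbar = m_e = e = 1).
#' User-facing interfaces follow the conventions of the field: geometries in
#' Angstrom, frequencies in cm^-1, times in femtoseconds, photon energies in
#' eV, cross sections in atomic units.
#'
#' @format A named list of conversion factors:
#' \describe{
#'   \item{hartree_ev}{1 hartree in eV (27.211386)}
#'   \item{au_fs}{1 atomic time unit in fs (0.02418884)}
#'   \item{bohr_ang}{1 bohr in Angstrom (0.52917721)}
#'   \item{amu_me}{1 unified atomic mass unit in electron masses}
#'   \item{cm1_hartree}{1 cm^-1 in hartree}
#'   \item{fine_structure}{fine-structure constant alpha}
#' }
#' @export
units_au <- list(
  hartree_ev     = 27.211386,
  au_fs          = 0.02418884,
  bohr_ang       = 0.52917721,
  amu_me         = 1822.888486,
  cm1_hartree    = 1 / 219474.6313632,
  fine_structure = 1 / 137.035999084
)

#' @keywords internal
.fs2au <- function(t_fs) t_fs / units_au$au_fs

#' @keywords internal
.ang2bohr <- function(x) x / units_au$bohr_ang

#' @keywords internal
.bohr2ang <- function(x) x * units_au$bohr_ang

#' @keywords internal
.ha2ev <- function(e) e * units_au$hartree_ev
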