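Package: holehop
Title: Surface-Hopping Dynamics of Valence-Ionized Molecules and Their
    Time-Resolved X-Ray Absorption Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates the ultrafast dynamics of valence-ionized molecules
    with Tully's fewest-switches surface hopping on Koopmans'-theorem
    hole-state potential energy surfaces, and computes the resulting
    time-resolved x-ray absorption spectra at element K-edges. Provides
    harmonic Wigner sampling of initial conditions, an analytic
    linear-vibronic-coupling model backend and an adapter contract for
    external Hartree-Fock engines, Lorentzian-broadened core-to-valence-hole
    cross sections, and the statistical post-processing used to interpret
    such spectra: electronic-state populations, Pearson correlation of
    internal coordinates with edge intensities, single-component
    partial-least-squares collective coordinates, and proton-transfer
    detection with sigmoid timescale fits. Includes synthetic-data
    generators with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    minpack.lm,
    pracma,
    stats,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    mixOmics,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
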