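# holehop

Surface-hopping dynamics of valence-ionized molecules and their
time-resolved x-ray absorption spectra (TRXAS), in R.

When an ionizing pump pulse removes a valence electron, the resulting
cation relaxes through nonadiabatic transitions between hole states while
its nuclei move - and, in hydrogen-bonded systems, may transfer a proton.
An x-ray probe sees all of this element-selectively through the pre-edge
resonance in which a 1s core electron refills the valence vacancy.
`holehop` simulates this experiment end to end and implements the
statistics used to interpret it:

* **Hole-state surfaces** via Koopmans' theorem, `E_i = E_HF - eps_i`,
  behind a small backend contract for external Hartree-Fock engines
  (`evaluate_koopmans_states`, `recorded_hf_backend`), plus an analytic
  linear-vibronic-coupling (LVC) model with exact gradients and
  nonadiabatic couplings (`lvc_parameters`, `evaluate_lvc`,
  `lvc_preset`).
* **Initial conditions** from the harmonic ground-state Wigner
  distribution: `Q_k ~ N(0, hbar/2w)`, `P_k ~ N(0, hbar w/2)`, rigid-body
  motion projected out (`modes_from_hessian`, `sample_wigner`).
* **Dynamics**: Tully's fewest-switches surface hopping - velocity Verlet
  on the active adiabat, RK4 electronic amplitudes, hop probability
  `g(a->j) = max(0, 2 dt Re[c_a* c_j (v.d_aj)]/|c_a|^2)`, energy-conserving
  velocity rescaling along the coupling vector (`fssh_config`,
  `run_ensemble`); compiled fast path for LVC models.
* **Spectra**: per-edge cross sections
  `sigma = (4/3) pi^2 w alpha |d|^2/3 L(w - dE)` with a 100 meV Lorentzian
  and rigid edge shifts (C/N/O defaults -21/-25/-24 eV)
  (`edge_config`, `ensemble_spectrogram`, `energy_integrated_trace`).
* **Statistics**: state populations, Pearson correlation of geometric
  features with edge intensities, single-component PLSR collective
  coordinates with R^2 and geometric-variance share, proton-transfer
  detection (acceptor O-H < 1.25 A, first crossing) and logistic
  timescale fits (`state_populations`, `pearson_correlations`,
  `plsr_collective_coordinate`, `detect_proton_transfer`,
  `transfer_statistics`, `split_ensemble`).
* **Synthetic data with ground truth** so every stage is testable without
  an electronic-structure engine (`generate_planted_regression`,
  `generate_planted_transfers`, `lvc_preset`).

See `vignettes/holehop-methods.Rmd` for the models, assumptions, numerical
choices and limitations.

## Worked example

Relaxation of a three-state model cation (the `urea_cation_3state`
preset) from its deepest hole state, with the blueshift of the oxygen-site
pre-edge line and the recovered statistics:

```r
library(holehop)

model <- lvc_preset("urea_cation_3state")
samples <- sample_wigner_modes(model, 100, seed = 7)
cfg <- fssh_config(dt = 0.5, t_total = 300, initial_state = 3, seed = 7)
ens <- run_ensemble(samples, cfg, make_lvc_pes(model))

pops <- state_populations(ens)
round(pops$populations[c(1, 51, 201, 601), ], 2)
#>      [,1] [,2] [,3]
#> [1,] 0.00 0.00 1.00
#> [2,] 0.65 0.27 0.08
#> [3,] 0.89 0.11 0.00
#> [4,] 0.95 0.04 0.01

edge <- edge_config("O", seq(500, 522, by = 0.02), shift = 0)
spec <- ensemble_spectrogram(ens, edge)
centroid <- function(row) sum(spec$energies * row) / sum(row)
c(t0 = centroid(spec$sigma[1, ]), t300 = centroid(spec$sigma[601, ]))
#>       t0     t300
#> 509.6519 512.8122
```

At t = 0 the ensemble sits in state 3 (fractions 0/0/1); within ~25 fs
two thirds have relaxed to the ground hole state, and by 300 fs 95% - the
sequential internal conversion the model plants. The oxygen pre-edge
centroid moves from 509.7 to 512.8 eV: electronic relaxation lowers the
valence-hole binding energy, widening the core-to-hole gap (a blueshift),
which is the fingerprint such experiments look for.

Proton-transfer statistics on a planted ensemble (70% transferring,
logistic midpoint 50 fs):

```r
ens <- generate_planted_transfers(300, fraction = 0.7, t50 = 50, tau = 8,
                                  seed = 37)
st <- transfer_statistics(proton_transfer_records(ens))
c(fraction = st$fraction, t50 = st$fit$t50)
#>   fraction        t50
#> 0.6766667 49.9547916
```

## Koopmans energetics of urea

The package ships recorded HF/6-31+G* single-point output for urea at its
optimized geometry (see the vignette for provenance and validation of the
recorded data):

```r
be <- urea_hf_backend()
ev <- evaluate_koopmans_states(attr(be, "geometry"), 3, be)
round(binding_energies(ev), 2)         # HOMO, HOMO-1, HOMO-2 (eV)
#> [1] 11.49 11.94 12.21
round(koopmans_edge_shifts(ev)[, c("element", "computed_be", "shift")], 1)
#>   element computed_be shift
#> 1       C       309.8  20.8
#> 2       N       424.3  25.3
#> 3       O       558.6  23.6
```

The three valence binding energies fall between 11 and 13 eV, overlapping
closely - which is why ionization of HOMO-1/HOMO-2 relaxes rapidly to the
HOMO hole. The frozen-orbital 1s binding energies exceed the experimental
K-edges (289/399/535 eV) by 20.8/25.3/23.6 eV for C/N/O: the rigid
down-shifts applied to computed spectra, within fractions of an eV of the
conventional 21/25/24 eV corrections.

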