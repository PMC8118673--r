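---
title: "Hole-state surface hopping and time-resolved x-ray absorption: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hole-state surface hopping and time-resolved x-ray absorption: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(holehop)
```

## The physical problem

Sudden removal of a valence electron - by an ionizing pump pulse - leaves a
molecule in one of several cation states and launches coupled electronic and
nuclear dynamics: internal conversion between hole states through
nonadiabatic transitions, vibrational motion on the ionized surface, and in
hydrogen-bonded systems possibly proton transfer. Time-resolved x-ray
absorption spectroscopy (TRXAS) probes these dynamics element-selectively: a
core (1s) electron can refill the valence vacancy, producing a pre-edge
resonance that exists only in the ionized molecule and whose position and
intensity track both the electronic state and the geometry.

`holehop` implements the complete simulation chain for this experiment
class, plus the statistical machinery used to interpret it:

1.  **Initial conditions**: Wigner sampling of the neutral ground
    vibrational state (`sample_wigner`).
2.  **Dynamics**: Tully's fewest-switches surface hopping (FSSH) over the
    manifold of valence hole states (`run_ensemble`).
3.  **Observables**: pre-edge absorption cross sections per element K-edge
    (`ensemble_spectrogram`).
4.  **Statistics**: state populations, structure-intensity correlations,
    single-component PLSR collective coordinates, proton-transfer detection
    and timescales (`state_populations`, `pearson_correlations`,
    `plsr_collective_coordinate`, `detect_proton_transfer`,
    `transfer_statistics`).

## Hole states from Koopmans' theorem

The ionized system is described at the frozen-orbital level: with
$E_\mathrm{HF}$ the neutral Hartree-Fock energy and $\epsilon_i$ the energy
of occupied orbital $i$, the state with a hole in orbital $i$ has

$$E_i \;=\; E_\mathrm{HF} - \epsilon_i ,$$

so binding energies are $-\epsilon_i$ and the cation ground state is the
HOMO hole. This costs no more than a neutral HF calculation per geometry
and extends naturally to deep valence holes. Its known biases - no orbital
relaxation, no correlation - are absorbed into rigid edge shifts for the
spectra (below).

The electronic-structure engine itself is *not* part of this package.
`evaluate_koopmans_states` consumes any backend obeying a small contract
(`?hf_backend_contract`): given symbols, coordinates, charge, multiplicity
and a basis label, return $E_\mathrm{HF}$, occupied orbital energies, MO
coefficients, the AO overlap matrix and optionally core-to-valence dipole
blocks. Two backends ship with the package:

* `recorded_hf_backend` replays stored single-point engine output (the
  standard adapter pattern for external engines). The packaged urea
  HF/6-31+G* data (`urea_hf_backend`) were produced by a purpose-built
  restricted Hartree-Fock code (McMurchie-Davidson integrals over contracted
  Cartesian Gaussians through d functions, DIIS convergence) whose integrals
  and energies were validated against independent oracles: the textbook
  H$_2$/STO-3G total energy, 3-D quadrature for overlap and kinetic blocks,
  exact translation/rotation invariance of the total energy, and ERI
  permutation symmetry. The geometry is the minimum of staged L-BFGS
  optimizations (6-31G, then 6-31G*, then 6-31+G*) with numerical
  gradients.
* any R function with the right signature is a live backend; the test suite
  uses an analytic mock engine with closed-form orbital energies so every
  derivative path has an exact oracle.

Core orbitals are identified by a Mulliken criterion - more than 90% (the
`core_threshold`) of an MO's gross population on a single atom together
with an orbital energy below `core_energy_cutoff` (default $-5$ hartree,
separating 1s levels near $-11\ldots-20$ hartree from valence levels above
$-1.6$) - and assigned to elements by their dominant atom.

**Derivatives.** The reference engine path obtains hole-state gradients by
central finite differences of $E_\mathrm{HF}-\epsilon_i$ (step $10^{-3}$
bohr, configurable) and nonadiabatic couplings from finite-difference
overlaps of Löwdin-orthogonalized orbitals, with displaced orbitals matched
to the reference by maximum overlap (ties broken by energy order). This
avoids re-implementing coupled-perturbed Hartree-Fock; the linear vibronic
coupling backend (below) has analytic derivatives everywhere and carries
all dynamical validation.

## The linear vibronic coupling (LVC) backend

Desk-scale dynamics run on an analytic diabatic model over dimensionless
normal coordinates $Q$:

$$H_{ab}(Q) = \delta_{ab}\Big(\textstyle\sum_k \tfrac{\omega_k}{2}Q_k^2
 + E^0_a + \sum_k \kappa_{a,k} Q_k\Big)
 + (1-\delta_{ab})\Big(\lambda^{(0)}_{ab} + \textstyle\sum_k \lambda_{ab,k} Q_k\Big).$$

Diagonalization gives adiabatic energies; Hellmann-Feynman gives exact
gradients; $d_{ij,k} = \langle i|\partial H/\partial Q_k|j\rangle/(E_j-E_i)$
gives exact coupling vectors. The constant coupling $\lambda^{(0)}$ is an
optional extension of the strictly linear model: a one-dimensional
two-state model with *only* linear coupling has zero coupling exactly at
its own crossing seam (a conical intersection, not an avoided crossing), so
the constant term is what makes the textbook avoided-crossing topology -
and hence Landau-Zener validation - expressible.

Three presets (`lvc_preset`) are the package's model systems:

* `two_state_1d` - a single-mode avoided crossing with documented
  single-passage initial conditions. The fewest-switches hop fraction over
  an ensemble is compared against the closed-form Landau-Zener probability
  $P = \exp(-2\pi\lambda^2/ v|\Delta\kappa|)$ with the crossing velocity
  taken from energy conservation.
* `urea_cation_3state` - three hole states over eight skeletal-range modes
  (350-660 cm$^{-1}$), vertical binding energies 11.2/12.0/12.7 eV.
  Parameters were chosen against three explicit contracts: (i) a 0.5 fs
  velocity-Verlet step conserves energy below $10^{-5}$ hartree over 300 fs
  (this bounds the mode frequencies, and per-mode reorganization energies
  $\kappa^2/2\omega$ are kept below half the state gaps so no spurious
  minima open on the ground adiabat); (ii) a state-3 start relaxes
  sequentially with the bulk of the decay inside $\sim$100 fs; (iii) more
  than 90% ground-state population by the 300 fs horizon. Four synthetic
  core sites with state-dependent transition dipoles make the relaxation
  visible as a blueshift in the model spectra - the same mechanism by which
  electronic relaxation appears in real pre-edge TRXAS - without claiming
  ab initio numbers.
* `dimer_pt_2state` - two states over three modes, of which mode 1 is a
  large-amplitude transfer coordinate mapped linearly to a donor-H
  acceptor-O distance ($d = 1.9 + 0.2\,Q_1$ Å, detection threshold
  1.25 Å). Both states share mode 1's gradient, so transfer statistics
  decouple from the hopping dynamics and the transfer probability of a
  Wigner ensemble is available in closed form (a noncentral
  $\chi^2_2$ tail); the `fraction` knob inverts that law.

## Wigner sampling

For the harmonic ground state each mode is Gaussian in both coordinate and
momentum: $Q_k \sim N(0, \hbar/2\omega_k)$, $P_k \sim N(0,
\hbar\omega_k/2)$, independently; temperature is fixed at 0 K (no thermal
option). After transforming to Cartesian coordinates, center-of-mass
translation and rigid rotation are projected out of the velocities -
over a 300 fs trajectory, residual angular momentum would otherwise feed
spurious rotational heating into the mode energies. Each ensemble member
draws under a child seed derived from the master seed by a fixed splitting
rule ($\mathrm{seed}_i = (\mathrm{seed} + 1000003\,i) \bmod (2^{31}-2) + 1$),
so enlarging an ensemble never reshuffles existing members.

`modes_from_hessian` builds the mode set from a Cartesian Hessian:
mass-weighted diagonalization, discarding the six smallest-|$\omega$| modes
(five for linear molecules, detected from the inertia tensor rank), with a
warning if near-zero frequencies remain among the retained modes.

## Fewest-switches surface hopping

Nuclei follow velocity Verlet on the active adiabatic surface. Electronic
amplitudes obey

$$i\,\dot c_k = E_k c_k - i \sum_j (\mathbf v\cdot\mathbf d_{kj})\, c_j,$$

integrated with classical RK4 over `n_substeps` (default 100) electronic
substeps per nuclear step, linearly interpolating $E_k$ and $\mathbf
v\cdot\mathbf d_{kj}$ between the step ends. Eigenvector phases are fixed
at every step against the previous one (`fix_phase_continuity`); without
this the coupling time series acquires sign jumps that scramble the
integration. Norm drift below $10^{-6}$ is renormalized away; above it the
step retries with four times the substeps and flags persistent failure.

Hopping follows Tully's prescription once per nuclear step, after the
coefficient update, using end-of-step quantities:

$$g_{a\to j} = \max\!\Big(0,\;
  \frac{2\,\Delta t\,\mathrm{Re}[c_a^* c_j\,(\mathbf v\cdot\mathbf d_{aj})]}
       {|c_a|^2}\Big),$$

with the sum over targets clipped to one. An accepted hop rescales the
velocity along the coupling vector $\mathbf d_{aj}$ to conserve total
energy; an energetically forbidden (frustrated) hop leaves the velocity
untouched by default (`frustrated = "reject"`), with sign reversal along
the coupling direction available by flag. No decoherence correction is
applied. Near-degenerate NAC denominators are floored at $10^{-8}$ hartree
and counted in the trajectory flags rather than triggering step-size
control; on the tested models true degeneracies are crossing seams of
measure zero and the floor was never the active constraint in practice.

Two implementations share this algorithm: a generic R propagator that
accepts any PES provider (`run_trajectory`; this is what an ab initio
backend drives), and a compiled fast path for LVC models used by
`run_ensemble`. The test suite checks them against each other frame by
frame on hop-free cases, and validates the stochastic element through the
Landau-Zener comparison (agreement to $\sim$1-2% at the preset's documented
velocity; the low-velocity regime, where Landau-Zener's own assumptions
fail, is excluded by design).

## Pre-edge absorption spectra

For photon energy $\omega$ and a transition dipole $\mathbf d$ between the
core orbital and the valence vacancy, the cross section of the lowest
pre-edge line is

$$\sigma(\omega) = \tfrac{4}{3}\pi^2\,\omega\,\alpha\,
  \tfrac{|\mathbf d|^2}{3}\; L_\Gamma(\omega - \Delta E),$$

with $\alpha$ the fine-structure constant, $|\mathbf d|^2/3$ the isotropic
average, and $L_\Gamma$ a unit-area Lorentzian whose full width at half
maximum (default 100 meV) stands in for the core-hole natural linewidth.
The transition energy per core site is $\Delta E = \epsilon_\mathrm{hole} -
\epsilon_\mathrm{core}$, the hole orbital being the *active* FSSH state's
vacancy - a deliberately classical-surface observable, consistent with how
populations are counted. Contributions of all same-element sites are
summed (e.g. the two nitrogens of urea).

Frozen-orbital transition energies overestimate the true pre-edge position
because the final state's core hole relaxes; the standard correction is a
rigid shift per element, defaulting to $-21/-25/-24$ eV for C/N/O - the
difference between computed 1s binding energies and the experimental K-edge
ionization potentials (about 289/399/535 eV). The shift relabels the
energy axis of the computed spectrum (cross sections are evaluated at the
unshifted transition energy), so shifting moves lines without altering any
intensity or integral.

`ensemble_spectrogram` averages frame spectra per time bin over all
trajectories alive in that bin; empty bins are `NA`, never zero. The time
grid defaults to the nuclear step. Energy-integrated traces use trapezoid
integration over the photon-energy grid, with arbitrary sub-windows via
`energy_integrated_trace`.

## Statistical post-processing

**Populations** are active-state fractions per frame over alive
trajectories (`state_populations`).

**Correlation analysis** pools samples as (trajectory, frame) pairs within
a configurable time window - all frames weighted equally, which is one of
two defensible conventions (per-trajectory averaging being the other) and
the simpler to reason about. Geometric features are either internal
coordinates (bonds in Å, angles/dihedrals in degrees; a generator derives
a complete bond/angle/dihedral set from covalent radii) or rigid-body
aligned Cartesian coordinates (`cartesian_feature_matrix`, least-squares
superposition per frame) where intermolecular motion defeats internal
coordinate sets. Responses are per-frame energy-integrated edge
intensities. `pearson_correlations` reports the plain product-moment
table.

**PLSR collective coordinate.** Both blocks are column-standardized; the
first partial-least-squares direction is the dominant left singular vector
of the cross-covariance $X_s^\top Y_s/(n-1)$. Reported diagnostics are the
fraction of response variance explained by a one-component regression on
the projection ($R^2$) and the share of total feature variance the
projection carries. Loadings are unit-norm in standardized space with a
raw-space conversion included. A single component is deliberate: the
analysis asks for *the* collective coordinate behind an intensity, not a
predictive multi-component model. The implementation is a few lines of
linear algebra; an independent cross-check against `mixOmics::pls` runs in
the test suite.

**Proton transfer** is declared when an acceptor-O-donor-H distance first
drops below 1.25 Å; the first crossing defines the transfer time and
re-crossings do not re-arm the detector (the rule is deliberately
monotone: "has transferred by time t"). Both hydrogen bonds of a dimer are
candidate directions and the transferring direction is recorded, enabling
the one-direction trajectory selection used for symmetry-equivalent
pathways. The ensemble timescale is the midpoint $t_{50}$ of a logistic
fit $N(t) = A/(1+\exp(-(t-t_{50})/\tau))$ to the cumulative transfer
count, by Levenberg-Marquardt least squares; the logistic form is a choice
(the fitted midpoint is insensitive to reasonable alternatives for
unimodal transfer-time distributions).

## Synthetic data with known ground truth

Because production ab initio ensembles are out of desk reach,
every statistical claim is validated on generators whose truth is known:

* `generate_planted_regression` builds Gaussian features with a planted
  unit direction carrying a chosen share of total variance and a response
  that is linear in the planted projection plus noise calibrated to a
  target population $R^2$. The truth record carries the direction in both
  raw and standardized space.
* `generate_planted_transfers` builds smooth distance curves crossing the
  1.25 Å threshold at logistic-distributed times for a chosen fraction of
  trajectories, packaged so the detection and fitting code runs unmodified.
* the LVC presets above, whose dynamical behavior is pinned by closed
  forms (Landau-Zener, noncentral-$\chi^2$ transfer fractions) or by
  documented contracts checked in the suite.

What passing these tests shows: the estimators and the pipeline plumbing
are correct at realistic signal strengths. What it does not show: that any
particular molecule's ab initio surfaces produce those signal strengths -
that depends on the electronic structure, which enters only through the
backend contract.

## Problem sizes and numerical choices

The shipped test and acceptance runs use: 2000 trajectories for the
Landau-Zener comparison; 20-600 trajectories for conservation, relaxation
and transfer checks; $10^5$ Wigner samples for moment recovery;
$2\times10^4$ samples for PLSR recovery; 300 planted trajectories for
transfer statistics. Tolerances follow the quantity's character: exact
identities at numerical precision, finite-difference oracles at the step's
accuracy order, stochastic recoveries at a few standard errors of the
planted value.

Known limitations: plain FSSH overcoherence (no decoherence correction, by
design, with an energy-based option left off by default); frozen-orbital
energetics with a rigid shift rather than state-specific core-hole
relaxation; classical nuclei (no tunneling contribution to proton
transfer); the recorded ab initio backend covers a single geometry and so
supports energetics and spectra at that point but not ab initio dynamics,
which require a live engine behind the backend contract.
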