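---
title: "Modelling carotenoid excited-state decay with surface hopping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling carotenoid excited-state decay with surface hopping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(carotdyn)
```

## The problem

Carotenoids in light-harvesting complexes absorb into the bright S2 state,
convert internally to the optically dark S1 within a couple of hundred
femtoseconds, and return to the ground state on picosecond timescales. A
spectroscopically distinct dark state, usually labelled S*, shows a shorter
lifetime and a blue-shifted excited-state absorption (ESA) and has been
proposed as the quencher of chlorophyll excitation during nonphotochemical
quenching. One mechanistic picture attributes S* to a minor conformer of the
carotenoid — a rotamer about a single C–C bond of the conjugated chain
(s-trans, dihedral ds2 near 180°, versus the dominant s-cis near 0°) — whose
decay is accelerated by two internal-conversion channels: inversion of the
bond-length alternation (BLA) and out-of-plane distortion of the lumenal
C=C bonds.

`carotdyn` packages the computational machinery needed to study this picture
at desk scale: a fewest-switches surface-hopping (FSSH) simulator on analytic
model potential-energy surfaces, the trajectory-analysis stack (population
kinetics, geometry descriptors, ESA spectra, Coulomb couplings), and a
synthetic-ensemble generator that emulates the statistical structure of
full-scale QM/MM surface-hopping production runs.

## The dynamics engine

Nuclei evolve classically on one adiabatic surface of a diabatic model
Hamiltonian (velocity Verlet, default timestep 0.1 fs). The electronic
amplitudes are integrated in a *locally diabatic* representation: the overlap
matrix between adiabatic eigenvectors at successive geometries is
Löwdin-orthonormalized and the interpolated Hamiltonian is applied over 100
midpoint sub-intervals per nuclear step. This avoids explicit nonadiabatic
coupling vectors entirely, which is why velocity rescaling at hops is
isotropic along the full velocity vector.

Hop probabilities follow the fewest-switches prescription computed from the
net population-flux matrix of each electronic step,
`g_k = max(0, N[active, k]) / |c_active|^2`, which for two states reduces
exactly to the fractional population loss of the active state. Accepted hops
rescale velocities so total energy is conserved; energetically frustrated
hops leave the state unchanged (velocities kept by default, reversal
available). Overcoherence is curable by two schemes:

* `overlap` (default): a frozen-Gaussian auxiliary-trajectory estimate. For
  each non-active state the engine accumulates the momentum/position offset
  driven by the force difference between that surface and the active one and
  collapses the wave function onto the active state once the Gaussian
  overlap drops below `1e-3` (widths 6 amu^1/2 Å, mass-weighted; both
  configurable). This is a deliberately simplified overlap-decay model: it
  retains the physical trigger (wavepacket separation) without propagating
  full auxiliary trajectories.
* `energy_based`: damping of non-active amplitudes with the standard
  gap/kinetic-energy time constant `tau = hbar/|dE| (1 + C/E_kin)`,
  `C = 0.1` Hartree.

Initial excited states are sampled proportionally to the squared
ground-to-excited transition dipoles, optionally inside an excitation-energy
window, from classical Boltzmann phase-space samples of the ground-state
well (normal-mode sampling at 300 K).

Numerical choices worth knowing: eigenvector phases follow a deterministic
largest-component-positive convention plus sign continuity along
trajectories, so runs are bitwise reproducible per seed (one independent RNG
stream per trajectory, seed = base + index); total-energy drift beyond
0.02 eV/ps aborts a trajectory with a diagnostic rather than silently
degrading; near-singular overlap matrices (steps too large) fall back to the
orthonormalized overlap with a warning.

## Model surfaces

Two families of analytic models ship with the package. The 1-D two-state
avoided crossing (`model_avoided_crossing()`) is the standard scattering
benchmark used to validate the engine against a numerically converged
quantum wavepacket reference. The three-state carotenoid surrogate
(`model_carotenoid()`) is the smallest model exhibiting both decay channels:
two reduced coordinates (BLA `b` in Å, mass 10 amu; one lumenal torsion
`theta`, mass 50 amu), a ground state with its BLA minimum at +0.10 Å, a
dark S1 with minimum near `b = 0`, a bright S2 whose crossing with S1 is
thermally accessible after vertical excitation, and an S0–S1 diabatic
coupling that switches on as the BLA goes negative and grows with torsional
distortion. The S0–S1 adiabatic gap is monotonically non-increasing as BLA
decreases below zero at fixed torsion — the surrogate encoding of the
strongly coupled region responsible for fast decay. A possible S3 state is
supported by the engine (state count is configurable) but the surrogate
keeps three states: the upper states are pooled before kinetic fitting
anyway.

Masses of 10 amu (BLA-like) and 50 amu (torsion-like) give femtosecond bond
dynamics and slower torsional motion at 300 K, the regime the analysis
expects.

## Population kinetics

`populations_from_ensemble()` turns an ensemble into per-state population
curves (the fraction of trajectories with a given active state). The
sequential kinetic model fitted by `fit_sequential_kinetics()` is: upper
pool (all states above S1, summed) decaying as `exp(-t/tau2)`; S1 fed
sequentially and decaying bi-exponentially,

S1(t) = Σ_i w_i · τ_i/(τ_i − τ₂) · (e^{−t/τ_i} − e^{−t/τ₂}),  w₂ = 1 − w₁,

with the analytic limit `(t/τ) e^{−t/τ}` when a component degenerates to
τ₂. Fitting is Levenberg–Marquardt least squares with unit weights; initial
guesses τ₂ = 100 fs, τ₁ = 1 ps, τ₁′ = 20 ps, w = 0.3. The weighted-average
lifetime is `w·τ₁ + (1−w)·τ₁′` exactly, reported to 0.1 ps; ratios to two
decimals. An independent bi-exponential fit of the S1 curve from its maximum
(`mode = "independent"`) is also provided; the sequential convolution is the
default because it uses the upper-state feed consistently.

```{r}
curves <- sequential_population_curves(135, 1.0, 21.2, 0.201)
fit_sequential_kinetics(curves)
```

## Geometry descriptors

BLA is the mean single-bond length minus the mean double-bond length over an
explicit conjugation topology (`conjugation_topology()`; the packaged
`polyene_topology()` is a 22-atom chain with nine named C=C dihedrals
dd1–dd9, lumenal dd1–dd4 / stromal dd5–dd9, and C–C dihedrals ds1–ds9,
numbered from the lumenal end). Dihedrals use the signed IUPAC convention in
(−180°, 180°]. The distortion index is

D = mean(1 − |cos θ_i|)

over a dihedral set: zero iff planar (0° or 180°), one at a uniform
90° twist, bounded in [0, 1]. This bounded mean form was chosen because it
is symmetric about planarity in both basins and scale-compatible with the
`D_Lum > 0.10` channel threshold (a ~26° mean twist); the set it averages
over is always explicit, so an alternative functional form can be swapped in
without touching the analysis. Conformers classify from ds2 alone
(|ds2| ≥ 90° → s-trans, with the boundary tie-break to s-trans);
trajectory-level labels aggregate frame labels by majority vote.

Hop-channel analysis (`characterize_hops()`) annotates S1→S0 hops with the
negative-BLA channel (BLA < −0.02 Å) and the lumenal-distortion channel
(D_Lum > 0.10 with BLA ≥ −0.02 Å) and reports counts and within-cutoff
percentages (default 2 ps). Photoisomerization detection flags a C=C
dihedral crossing 90° only if it settles in the opposite planar basin for a
dwell window (default 10 frames), so thermal excursions do not count.

## ESA spectra and couplings

`accumulate_esa()` adds, for every frame with the chosen active state
(default S1), one Gaussian per higher state at the energy gap, weighted by
the squared transition dipole, and normalizes by frame count. Defaults:
grid 1.5–3.5 eV at 0.005 eV, σ = 0.05 eV — broad enough for smooth spectra,
fine enough to resolve a 0.06 eV conformer shift. Frames are weighted
uniformly over the whole window; 1 ps time windows are available via the
`window` argument. Peaks are grid argmaxima refined by local quadratic
interpolation (ties break to the lower energy); shifts report ΔE from the
peak pair and Δλ from the two wavelengths, not from ΔE.

Coulomb couplings between chromophores use atomic transition charges:
`V = Σ q_i q_j / r_ij` in atomic units, reported in cm⁻¹
(1 Ha = 219474.6314 cm⁻¹, 1 bohr = 0.529177211 Å), with an optional scalar
screening factor (none by default — an embedding would supply it). The
charge representation is itself an approximation to full transition
densities; charge-derived couplings are expected to differ by a few tens of
cm⁻¹ from density-based ones while remaining in the same range, which is the
fidelity target here. The ideal point-dipole formula is provided as a
far-field cross-check and refuses geometries whose charge clouds are closer
than three cloud radii. `eet_favorability()` reports the fraction of frames
with the acceptor S1 below the donor Qy — the downhill-transfer fraction.

## The synthetic-ensemble generator

The generator emulates the *statistical* structure of surface-hopping
production ensembles so every analysis stage is testable without
quantum-chemistry data. Its defaults are the study conditions: 396 + 386 =
782 trajectories in two conformational sets over a 15 ps window; set A
purely s-cis, set B an equal s-cis/s-trans split; per-group sequential
kinetics (τ₂, τ₁, w, τ₁′) equal to the fitted constants of those ensembles;
ds2 centered at 180°/0° (±8°), ds1 at 80°/−50° (±10°); ground-state BLA
0.10 Å (s-trans broader, σ 0.020 vs 0.012 Å) relaxing to zero on S1;
chlorophyll Qy ~ N(2.00, 0.04) eV against a wide s-trans S1 distribution
(σ 0.45 eV) and a narrow s-cis one (σ 0.12 eV). Where a value is not pinned
by the conditions above (the descriptor spreads, the OU correlation time of
200 fs, the hop-geometry widths), it was set once to values typical of
room-temperature conjugated-chain fluctuations and kept.

Hop times are drawn from the sequential model (S2→S1 ~ Exp(τ₂), S1 dwell
from the bi-exponential mixture, truncated at the window; survivors are kept
and end on S1, mirroring a truncated production run). Fast-component hops
receive channel geometries — negative-BLA or lumenal-distortion — in a
configurable mix (`bla_channel_fraction`, default 33/49; the true mix is a
free parameter, not an assertion). Descriptor series are mean-reverting
Gaussian (Ornstein–Uhlenbeck) processes with state-dependent means.

What the generator deliberately does **not** emulate: quantum coherences,
frame-level energy conservation, correlations between descriptors and hop
probabilities, or anharmonic tails of real distributions. Passing analysis
tests on synthetic ensembles therefore demonstrates the correctness of the
estimators and fits, not the realism of any particular dynamical model.

## Validation strategy and problem sizes

The package validates itself at three levels, sized to run on a single CPU
in minutes:

1. closed-form and oracle checks of every operation (finite-difference
   gradients, matrix-exponential electronic propagation, per-term descriptor
   sums, hand-evaluated Coulomb sums);
2. engine-level physics: energy conservation on harmonic surfaces, internal
   consistency (ensemble surface fractions tracking mean electronic
   populations within sampling error, 1000 trajectories) and transmission
   probabilities on the 1-D avoided crossing benchmarked against an
   independent split-operator quantum wavepacket (2000 trajectories,
   3σ agreement);
3. end-to-end parameter recovery: sequential fits on noise-free curves
   recover their generating parameters to 1e-4 relative; stochastic
   ensembles of 400 (5000) trajectories recover the generating weighted
   lifetime within 25% (10%) at fixed seeds.

## Known limitations

Analytic surrogate surfaces cannot reproduce simulation-level observables of
the real pigment-protein system (absolute lifetimes, ESA peak positions,
coupling magnitudes); those require the original electronic-structure
surfaces. The FSSH variant implemented here (population-flux hopping,
isotropic rescaling) is one standard choice among several; on strongly
recrossing problems different conventions can differ measurably. The
overlap-decoherence scheme is a simplified frozen-Gaussian model, not a full
auxiliary-trajectory implementation. The generator's distributions are
Gaussian/OU idealizations of figure-level summaries.
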