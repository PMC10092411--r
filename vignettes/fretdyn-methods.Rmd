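---
title: "Models and methods behind fretdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind fretdyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fretdyn)
```

`fretdyn` connects the conformational dynamics of a flexibly tethered
chromophore pair to its photophysical observables. This vignette lays
out the models implemented, the assumptions they rest on, the
parameters that matter, and the design choices made where more than
one reasonable formulation exists.

## Förster theory on trajectories

The core quantities are the spectral overlap integral
$J = \int \bar F_D(\lambda)\,\varepsilon_A(\lambda)\,\lambda^4\,
d\lambda$ (donor emission area-normalized, trapezoidal quadrature on
the union wavelength grid with linear interpolation), the Förster
radius

$$R_0^6 = \frac{9000 \ln 10\; \kappa^2 \Phi_D^0}{128 \pi^5 N_A n^4}\,J,$$

and the efficiency $E = 1/(1 + (R_{DA}/R_0)^6)$. Units are nm
throughout (absorptivity in M$^{-1}$cm$^{-1}$); the single numeric
constant doing the unit bookkeeping lives in one internal table and is
cross-checked in the tests against the independent closed form
$R_0^6[\text{Å}^6] = 8.79\times 10^{-5}\,\kappa^2 n^{-4}\Phi_D^0 J$.
The quadrature is second-order: halving the grid spacing moves $J$ by
well under 0.5 % for smooth bands, which bounds the discretization
error far below the photophysical uncertainties.

The orientation factor
$\kappa^2 = (\sin\theta_D \sin\theta_A \cos\phi -
2\cos\theta_D\cos\theta_A)^2$ is computed per frame. Two routes exist
— the three Förster angles, or
$\kappa = \hat\mu_D\cdot\hat\mu_A -
3(\hat\mu_D\cdot\hat R)(\hat\mu_A\cdot\hat R)$ directly from vectors —
and the package checks them against each other to $10^{-10}$ on random
geometries. The dihedral $\phi$ is taken right-handed about
$\hat R$; $\kappa^2$ depends on it only through $\cos\phi$, so the
handedness convention is documentation, not physics. When a dipole is
parallel to the separation vector the dihedral is undefined; it is
reported as 0 by convention, which leaves $\kappa^2$ unchanged.

**Dynamic versus fixed $\kappa^2$.** Efficiency traces use the
instantaneous $\kappa^2(t)$ inside $R_0(t)$ by default, because the
joint fluctuation of distance and orientation is precisely what makes
tethered pairs interesting; a fixed-$\kappa^2$ policy (e.g. the
isotropic 2/3) is available for comparison and for rotation-invariance
checks. Distance stratification uses closed outer classes
($R_{DA} \le e_1$, $R_{DA} \ge e_2$) so boundary frames are assigned
deterministically, and the count-weighted class means rebuild the
global mean exactly.

**Anisotropy.** For one-photon excitation
$r_0 = 0.4\,(3\cos^2\beta - 1)/2$, where $\beta$ is the angle between
absorption and emission transition dipoles; a near-collinear
push-pull dye with $\beta \approx 15^\circ$ sits at $r_0 = 0.36$.
Homo-FRET hops depolarize: we model the observed anisotropy as the
mixture $\bar r = (1-p)\,r_0 + p\,r_{et}$ over the probability $p$
that a detected photon followed at least one hop, with the
post-transfer anisotropy defaulting to $r_{et} = 0.016$
(near-randomized orientation after a hop). This is a deliberately
minimal quantitative stand-in for a full depolarization cascade; it is
linear, invertible, and sufficient to translate between $\bar r$ and
hop probabilities.

## The synthetic-dynamics generator

The generator emulates what a long explicit-solvent simulation of a
two-chromophore tether provides to the analysis: metastable
conformational states with distinct distance and orientation
statistics, Markovian exchange between them, and frames written at a
5 ps cadence (40 000 frames for the default 200 ns). Each state emits
$R_{DA}$ from a log-normal (positivity, tunable spread) and Förster
angles from Gaussians around state means; dipoles realizing those
angles are constructed about a uniformly random separation direction.
Emissions are conditionally independent given the hidden state (pure
hidden-Markov emission, no intra-state autocorrelation by default), so
closed-form and Monte-Carlo oracles for per-state and mixture mean
efficiencies are exact.

What this does *not* emulate: solvent memory and inertial dynamics
(emissions decorrelate within one frame), anharmonic intra-state
relaxation, and any coupling between distance and orientation inside a
state. Passing tests therefore demonstrate the correctness of the
analysis chain on data satisfying its own assumptions — they do not
certify force-field realism.

Presets: `two-state-minimal` (folded 0.9 nm / unfolded 2.5 nm,
occupancies ≈ 0.7/0.3) for closed-form checks; `EZ-like` and
`EE-like` four-state tethers (folded medians 0.8–1.0 nm, unfolded
2.4–2.5 nm, the `EE` variant more folded); and `six-well`, six
well-separated states on a two-branch chain with a designed dominant
source→sink pathway (1→2→4→6), used to validate the full MSM pipeline
end to end. Preset geometry statistics are plausibility choices for a
dendrimer-linked dye pair, fixed once; a single seed governs all
draws and is recorded in every scenario and output.

## Markov state modelling

The MSM chain is tICA → k-means microstates → transition matrix →
PCCA+ → transition-path theory, with each stage testable on its own.

*tICA* solves the symmetrized generalized eigenproblem
$C(\tau)v = \lambda C(0) v$ on mean-free data, by whitening with
$C(0)^{-1/2}$ (diagonal regularization $\varepsilon = 10^{-10}$; null
directions dropped with a warning). Components are uncorrelated with
unit variance at lag 0, eigenvalues are autocorrelations at the lag,
and implied timescales are $-\tau/\ln|\lambda_i|$.

*k-means* is Lloyd iteration with k-means++ seeding under a recorded
seed; a cluster that empties is re-seeded at the point farthest from
its current center, so exactly $k$ populated microstates come back.
Defaults follow common practice for this pipeline: $k = 200$
microstates, $m = 6$ metastable sets, both configurable.

*Estimation* counts sliding-window transitions at the lag, restricts
to the largest strongly connected set (warning with the retained count
fraction), and row-normalizes (maximum likelihood, non-reversible) by
default. A detailed-balance estimator (fixed-point iteration on the
symmetrized count flux, tolerance $10^{-10}$) is available but not the
default, since nothing in the modelled physics forces the observed
window to be reversible. Markovianity is assessed, not assumed: the
implied-timescale plateau across lags and the Chapman–Kolmogorov test
(metastable-set self-transition probabilities of $[T(\tau)]^k$ versus
re-estimation at $k\tau$) are both exposed.

*PCCA+* follows the spectral simplex construction: the top-$m$ right
eigenvectors span an $m$-vertex simplex whose vertices are located by
farthest-point search with Gram–Schmidt deflation; memberships are the
barycentric transform clipped to the simplex and renormalized. If the
dominant block contains complex conjugate eigenvalue pairs (possible
for non-reversible estimates), the same real invariant subspace is
spanned by real and imaginary parts instead.

*Transition-path theory* computes forward and backward committors from
the linear systems, the gross reactive flux
$f_{ij} = \pi_i q^-_i T_{ij} q^+_j$, its net part, and coarse-grains
over the metastable partition. Pathways are peeled off by iterative
bottleneck removal (widest path by capacity-ordered Dijkstra, subtract
its bottleneck, repeat); a pathway's percentage is its flux divided by
the total reactive flux — the natural reading of "pathway percentage"
in a flux network. Decomposition stops when the remaining path
capacity drops below 1 % of the total, so reported percentages can sum
to slightly less than 100.

*Free-energy landscapes* are Boltzmann inversions $F = -\ln P$ (in
$k_BT$) of the 2-D histogram on the projected coordinates, minimum
shifted to zero. Empty bins are $+\infty$, not "max + 1": an
unvisited bin is unknown territory, and fabricating a finite barrier
there would bias basin-depth readings. The PCA cosine content
diagnostic flags random-walk-like (unconverged) projections: a pure
diffusion has content near 1, converged sampling near 0.

## Photoisomerization kinetics with FRET coupling

Chromophore units are treated as clean two-state photoswitches
(emissive E, dark Z; no triplets, no bleaching, no thermal
back-reaction). The mechanism is formalized in two layers.

**Per photon.** An excitation resident on unit $u$ either transfers
to a neighbour or stays and resolves locally (isomerization with the
resident isomer's quantum yield, otherwise decay). Pairwise transfer
probabilities — $p_{homo}$ between two E units, $p_{hetero}$ from E to
Z, zero from Z (dark donors) — are defined against local outcomes for
an isolated pair; with several acceptors the channels compete as
rates, implemented by renormalizing per-pair odds
$o = p/(1-p)$ to $E_{uj} = o_j/(1+\sum_k o_k)$. A single acceptor
recovers $E_{uj} = p$ exactly, and total transfer stays below one, so
the wandering excitation is an absorbing Markov chain solved exactly
through the fundamental matrix $(I-Q)^{-1}R$.

**Per species.** Each isomer configuration (E/Z over 1–3 units) is a
species; excitation arrives at each unit proportionally to its isomer
absorptivity at the irradiation wavelength, and each photon's fate
flips at most one unit. The resulting first-order generator (columns
sum to zero: mass conservation) is integrated by matrix exponentials —
the system is at most $8\times 8$ and linear, so a stiff integrator
would add nothing. Photostationary states come from the bordered
null-space solve, absorbance from Beer–Lambert additivity over units
(weak coupling), with the probe at 457 nm by default.

The package's reference parameter set — E band Gaussian
(457 nm, fwhm 90 nm, peak 48 700 M$^{-1}$cm$^{-1}$), Z band
(390 nm, 100 nm, 20 000), $\Phi_{EZ} = 0.03$, $\Phi_{ZE} = 0.50$,
$p_{homo} = 0.5$, $p_{hetero} = 0.6$ — was chosen once as a plausible
DCM-like regime in which the mechanism's two signatures are both
expressed across the 1/2/3-unit series: the PSS absorbance ratio
$A_{PSS\text{-}485}/A_{PSS\text{-}335}$ rises toward 1 (hetero-FRET
protects E units from net conversion under visible light) and the time
to reach the PSS falls (the hetero channel adds a fast Z→E back-path).
These are qualitative, mechanism-level statements; the package does
not fit experimental curves.

## TCSPC simulation and global fitting

Simulated decays are the multi-exponential impulse response discretely
convolved with the area-normalized IRF (FFT convolution, causal
truncation), scaled to a target peak count, plus constant background,
with per-channel Poisson draws under a fixed seed. Fitting minimizes
the Neyman-weighted residual $\sum_j (y_j-\hat y_j)^2/\max(y_j,1)$
(the $\max(\cdot,1)$ guard keeps empty channels finite) with lifetimes
shared across curves. The optimizer is variable projection:
amplitudes and background are non-negative linear parameters solved
per curve inside each Levenberg–Marquardt step over the shared
log-lifetimes, with five starts spread geometrically (×/÷3) around a
moment-based initial guess. Degenerate lifetime pairs (ratio < 1.2)
trigger a warning. Reported per model: shared lifetimes with
approximate standard errors, per-curve normalized amplitudes and
intensity fractions $f_i = a_i\tau_i/\sum_j a_j\tau_j$, and local plus
global reduced $\chi^2$. Two-decimal rounding is applied only at
report time. A sub-channel IRF shift parameter is deliberately absent:
synthetic fixtures are generated on-grid with zero shift, so the
parameter would never be exercised.

## Numerical choices and degenerate inputs

- Distances of exactly 0 with $R_0 > 0$ return the limit $E = 1$;
  $R_0 = 0$ returns $E = 0$; coincident reference points are an error.
- Negative reconstructed Z-isomer absorptivities (measurement noise in
  the photostationary inversion) are clipped to zero with a warning
  rather than rejected.
- Unit dipoles are renormalized on load only when off by more than
  $10^{-9}$ (so file round-trips are bit-exact) and rejected beyond
  10 %.
- Empty distance classes report `NA` means, never 0; empty trace
  windows return empty traces, not errors.
- Implied timescales for non-positive eigenvalues are `NA`
  (undefined), not clamped.
- All stochastic stages (scenario simulation, k-means, decay
  simulation, multi-start fitting) take explicit seeds recorded in
  their outputs.

## Problem sizes used in the validation suite

The shipped tests run the full MSM pipeline on the 40 000-frame
six-well scenario (the default 200 ns / 5 ps cadence), two-state
chains of $10^6$ steps for timescale recovery, $10^6$-draw Monte-Carlo
orientation averages, and a 50-seed lifetime-recovery study at $10^4$
peak counts; the whole suite completes in about a minute on a single
CPU. These sizes were chosen so that statistical test bands (3σ) sit
well inside the tolerances being asserted.

## Known limitations

- Förster point-dipole weak-coupling theory only: no exciton
  coupling, no dipole-orientation memory between frames, no
  refractive-index dispersion.
- The generator's states are conditionally independent emitters; real
  trajectories decorrelate over finite times, which an MSM lag must
  absorb.
- Photokinetics neglects excited-state absorption, triplets and
  thermal back-isomerization, and treats per-species FRET
  probabilities as free parameters (conformationally averaged values
  could be supplied from the trajectory module).
- The TCSPC module fits lifetimes and amplitudes, not anisotropy
  decays or lifetime distributions.
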