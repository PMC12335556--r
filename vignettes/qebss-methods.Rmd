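---
title: "Selecting MD ensembles by quality evaluation against NMR spin relaxation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting MD ensembles by quality evaluation against NMR spin relaxation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qebss)
```

## The problem

Multidomain proteins with intrinsically disordered regions sample broad,
heterogeneous conformational ensembles that no single experimental
technique resolves. Backbone ^15^N spin relaxation times (T1, T2) and the
heteronuclear NOE probe rotational motion from picoseconds to tens of
nanoseconds and are sensitive to both the conformational ensemble and its
dynamics. Molecular dynamics simulations produce candidate ensembles, but
force fields disagree and individual trajectories undersample; which
simulation to believe is not knowable a priori.

The approach implemented here evaluates every candidate trajectory
against experimental relaxation data, keeps the trajectories that
simultaneously reproduce all three observables, and combines them into a
single quality-evaluated ensemble. That ensemble — not any individual
simulation — is then characterized.

## From trajectory to observables

**Correlation functions.** For each residue the backbone amide N–H unit
vector is extracted per frame ([extractNHVectors()]); prolines and the
N-terminal residue carry no amide ^15^N–H vector and are excluded by
default. The second-order orientational autocorrelation

$$g(t) = \left\langle \tfrac{3}{2}\cos^2\theta_{t'+t} - \tfrac{1}{2}
\right\rangle_{t'}$$

is averaged over all time origins. `computeP2Acf()` evaluates this in
O(n log n) by expanding $\cos^2\theta$ into products of the six unique
entries of the outer product $vv^T$ and computing their autocorrelations
with FFTs; a brute-force double loop over origins is kept in the test
suite as the oracle and the two agree to 1e-12. The maximum lag defaults
to 50% of the trajectory duration (configurable); beyond that the
estimator averages too few origins to be useful.

**Timescale spectra.** Each correlation function is fitted to a sum of
exponential decays with fixed timescales,

$$C_\mathrm{fit}(t) = \sum_{i=1}^{N} \alpha_i e^{-t/\tau_i},
\qquad \alpha_i \ge 0,$$

on a grid of N = 100 timescales log-equidistant between 1 ps and 100 ns
(`buildTimescaleGrid()`). The weights are obtained by Lawson–Hanson
non-negative least squares on the full design matrix. No sum constraint
is imposed: $g(0) = 1$ keeps the total mass near one. The exponential
design is numerically rank-deficient (neighbouring columns are almost
collinear — the double-precision rank of the default design is about
half its column count), which NNLS tolerates but pivoted factorizations
do not; this is why the solver works on the full matrix rather than a
factorized reduction. On noiseless data built from grid timescales the
fit reproduces both the weights (to 1e-6) and the curve at all sampled
lags (to 1e-9).

**Spectral densities and Redfield rates.** The fitted spectrum has the
analytical Fourier transform

$$J(\omega) = \sum_i \alpha_i \frac{2\tau_i}{1 + (\omega\tau_i)^2},$$

a convention chosen so that the standard Redfield prefactors ($d^2/20$,
with $d = \mu_0\hbar\gamma_H\gamma_N / 4\pi\langle r_{NH}^3\rangle$)
reproduce textbook relaxation rates; the implementation is cross-checked
against an independently coded closed-form single-Lorentzian script to
1e-10 relative. `relaxationObservables()` evaluates T1 and T2 from the
dipolar and chemical-shift-anisotropy mechanisms with defaults
$\Delta\sigma = -160$ ppm and $r_{NH} = 0.101$ nm, and the NOE from the
already computed T1. J is even, and the ^15^N Larmor frequency is
negative, so magnitudes of the frequency combinations are used.

**The NOE sign convention.** Two cross-relaxation combinations circulate
in the literature: $6J(\omega_H+\omega_N) - J(\omega_H-\omega_N)$ and
$J(\omega_H-\omega_N) + 6J(\omega_H+\omega_N)$. Only the first can
produce the negative NOE values characteristic of highly flexible
residues, and it is the default (`standard_minus`); the plus variant
remains available as `noeSignConvention = "paper_plus"` for comparison
with sources that print it. This is a deliberately flagged choice, not a
silent correction.

**Effective correlation times.** $\tau_\mathrm{eff} = \sum_i \alpha_i
\tau_i$, the integral of the fitted correlation function. It is
deliberately *not* normalized by $\sum\alpha_i$: the weights already sum
to about one for a proper correlation function, and the unnormalized sum
is exactly the curve integral.

## Ranking, selection, combination

For each candidate simulation and each observable, the residue-averaged
RMSD against the experimental table is computed in native units
(seconds for T1/T2, dimensionless for the NOE); experimental errors are
not used as weights. Dividing by the smallest RMSD per observable gives
*comparison numbers* with the best simulation at exactly 1.0 (also when
the best RMSD is exactly zero, as in planted-truth fixtures).

A simulation enters the combined ensemble only when its comparison
numbers for T1, T2 *and* NOE are all strictly below the threshold
(default 1.5, i.e. within 150% of the best). The three tests are never
aggregated into one score: the observables are sensitive to different
timescales, and a simulation best on one axis can still be rejected on
another. Ties at exactly the threshold are rejected; the threshold is a
user parameter worth revisiting per data set. The combined ensemble's
observables come from residue-wise *averaged correlation functions* of
the selected simulations (`averageAcfs()`, then refit) — not from
averaging the observables, which would be wrong because the map from
correlation function to rates is nonlinear.

## Characterization

`radiusOfGyration()` (mass-weighted, per frame),
`orientationCorrelationMap()` (time-averaged dot products of unit
vectors connecting consecutive C$^\alpha$ positions; +1 parallel, −1
antiparallel, 0 uncorrelated), `minDistanceMap()` (per residue pair the
minimum over all atom pairs including hydrogens, sampled at 1 ns
intervals by default, then time-averaged), and `pcaEnsemble()`
(covariance of 3N C$^\alpha$ coordinates after least-squares
superposition of every frame onto the mean structure — computed once
after an initial alignment to the first frame and refit once — with
per-trajectory projections onto the first two eigenvectors).
`timescaleLandscape()` bins each residue's fitted weights into
user-chosen timescale windows; bin edges are a user parameter because no
single canonical binning exists (2, 6, 8, 12, 16 ns boundaries are all
in common use). Histogram binning for radius-of-gyration distributions
uses the Freedman–Diaconis rule by default.

## SAXS channel

Computed per-frame profiles (read from crysol-style `.int`/`.fit` files
or generic `q I [sigma]` text) are averaged pointwise on a shared q
grid, then fitted to experiment as $I_\mathrm{fit} = \mathrm{scale}
\times I_\mathrm{comp} + \mathrm{offset}$ using only q in [0.01, 0.3]
(input units; points outside the window verifiably never influence the
result). The model is linear in both parameters, so the
Levenberg–Marquardt iteration customarily quoted for this fit converges
to the closed-form linear least-squares solution, which is what is
computed (and cross-checked against an LM implementation in the tests).
Both curves are min–max normalized for display; the RMSE quality score
is computed on the raw fitted intensities by default, with the
normalized variant also reported (`rmseNormalized`), since both
definitions appear in practice. A coarse Debye-formula calculator over
C$^\alpha$ pseudo-atoms (`debyeProfile()`) exists so the fitting
machinery can be exercised self-contained; it is explicitly
non-quantitative.

## Synthetic generators and what passing tests mean

The generators exist so every stage runs and is tested without external
trajectory data:

* `makeAcf()` — exact multi-exponentials with optional additive noise
  (lag zero kept exact); inverts the fitting problem.
* `simulateIsotropicRotor()` — a unit vector evolved by per-step
  rotations of angle $\sqrt{4 D_r \Delta t}\,|N(0,1)|$ about an axis
  uniform in the tangent plane of the current vector. The axis must be
  perpendicular: a uniformly random 3D axis only displaces the vector by
  its perpendicular component and realizes $\tfrac{2}{3}D_r$. The P2
  autocorrelation then decays with $\tau_2 = 1/(6 D_r)$. Validity
  requires $4 D_r \Delta t \ll 1$; a warning fires above 0.1.
* `makeSelectionFixture()` — candidate simulations with distinct
  two-component timescale mixtures, plus an "experimental" table
  generated from one of them through the forward model (planted truth),
  optionally with relative Gaussian noise.
* `makeBeadEnsemble()` — rigid straight-rod domains joined by a freely
  jointed linker, redrawn independently each frame, with the exact
  ideal-chain $\langle R_g^2\rangle$ as the analytic reference in the
  single-bead-domain limit.

Every generator draws from its own seed-derived stream and restores the
global RNG state, so fixtures are reproducible and mutually independent.

These fixtures emulate the *structure* of the real problem (known
timescale mixtures, planted truth, flexible-linker architecture), not
real data: they contain no chemical-exchange broadening, no anisotropic
overall tumbling, no force-field artifacts, and frames of the bead
generator are temporally uncorrelated. Passing tests therefore
demonstrate that the estimators, fits and selection logic are correct —
not that any particular force field or trajectory is realistic.

## Numerical choices and problem sizes

* Times are picoseconds at all I/O boundaries (trajectory frames, lag
  grids, xvg files) and seconds inside the physics; the conversion
  happens exactly once, in `fitExponentialSum()`.
* Text writers emit full double precision (`%.17g`), so every
  reader/writer pair round-trips to 1e-12.
* The rotational-diffusion benchmark in the tests uses a 1 μs
  trajectory at 10 ps spacing (100 000 frames) with a 5 ns target; the
  intrinsic sampling error of a correlation-time estimate from a single
  trajectory of length $T$ scales like $\sqrt{2\tau_2/T}$, about 10%
  here, which sets the test tolerance. Because NNLS weights cannot be
  negative, noise in the correlation-function tail biases
  $\tau_\mathrm{eff}$ slightly upward rather than averaging out — a
  known small asymmetry of non-negative fits.
* Selection fixtures use 5 simulations × 6 residues with 2% relative
  noise and 100 replicates; these sizes give each replicate a
  comfortable signal-to-noise margin for the planted truth while
  keeping the whole suite quick on one CPU.
* Degenerate inputs error early and specifically: empty selections
  (with a hint to review the threshold), all-NaN correlation functions,
  constant SAXS profiles, residues without an amide H when explicitly
  requested, mismatched q grids (no silent interpolation in
  averaging), non-monotonic xvg times.

## Known limitations

* No chemical-exchange (R$_\mathrm{ex}$) contribution to T2: μs–ms
  conformational exchange is invisible to this analysis.
* Overall tumbling is treated through the timescale spectrum only; no
  anisotropic diffusion tensor or model-free parameterization is
  fitted.
* Trajectory input is limited to multi-model PDB and DCD (the formats
  the underlying parser reads); compressed binary formats should be
  converted upstream, or the pipeline can be fed precomputed
  correlation functions (xvg) directly, with no trajectory reading at
  all.
* Equilibration removal (`skipTime`) is a user decision, not
  auto-detected: judging "clear conformational changes" in a radius of
  gyration trace is not automated here.
* The SAXS channel consumes externally computed per-frame intensities;
  it does not model hydration shells or excluded volume itself.
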