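---
title: "Free-energy and entropy reconstruction from bidirectional steered pulling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Free-energy and entropy reconstruction from bidirectional steered pulling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(steerpmf)
```

## The experiment this package analyses

A ligand is driven out of (or into) a protein binding site by a harmonic
guide — a "virtual spring" of stiffness $\kappa$ whose anchor, the control
parameter $\lambda(t) = \lambda_0 + v t$, moves at constant velocity along
the unbinding coordinate.  The molecular observable is the collective
coordinate $\xi(t)$, here the scalar projection of the ligand–protein
centre-of-mass separation onto the pulling direction.  The guide potential
is

$$u(\xi, \lambda) = \tfrac{\kappa}{2}\,(\xi - \lambda)^2 ,$$

and the work performed on the system along one realization is the
force–extension contour integral $W(t) = \int \kappa(\lambda - \xi)\,
d\lambda$, with the initial energy stored in the spring subtracted so that
$W$ is the net work imparted.  Because such pulls are fast compared to the
molecular relaxation times, every realization dissipates work and $W$ is a
random variable; nonequilibrium work theorems (Jarzynski, Crooks) turn
ensembles of these works back into equilibrium free energies.

The package implements the complete inference chain — work accounting,
free-energy estimators along $\lambda$, unbiased potentials of mean force
$G(\xi)$, basin/barrier analysis, time-windowed quasiharmonic entropies and
geometric interaction profiles — together with an overdamped Langevin
simulator whose ground truth is known analytically, so every estimator can
be validated end to end.

The reference protocol (the package defaults in `run_config()`) uses
$\kappa = 1686.75$ kJ/mol/nm², $v = 5\times10^{-4}$ nm/ps, 5 ns pulls
sampled every 1 ps (5000 frames, 2.5 nm traversed), 10 realizations in each
direction at 300 K.  At this stiffness the thermal resolution of the guide,
$\sqrt{k_BT/\kappa} \approx 0.04$ nm, is comparable to the 0.025 nm
analysis bins — the stiff-spring regime in which $G(\xi)$ and
$\Delta F(\lambda)$ nearly coincide and the weighted-histogram unbiasing
supplies the remaining correction.

## Work conventions

Two conventions interact and are worth stating precisely.

*Stored records* follow the net-work convention: `accumulate_work()`
integrates the spring force over $\lambda$ by the trapezoidal rule (the
midpoint variant of a Riemann sum, second-order accurate) and subtracts the
realization's own frame-0 spring energy $u(\xi(0), \lambda(0))$.  For a
guide that starts at rest on the pulled coordinate the subtraction is zero;
for starts equilibrated under the guide it is a small ($\sim k_BT/2$)
fluctuating offset.  An ambiguity is inherent here — an ensemble-averaged
reference would be an equally defensible reading — and the package
deliberately keeps the subtraction per-trajectory so that raw records stay
faithful to each realization.

*Estimators* consume the raw switching work.  `resample_on_lambda_grid()`
aligns all realizations on a common $\lambda$ grid (flipping the reverse
time axis there and only there) and re-zeroes each realization's work at its
own start grid point, undoing the stored offset.  For initial states drawn
from the guide-extended equilibrium at the end states — which is how both
the simulator and the standard preparation protocol (equilibrated bound
snapshots forward, short guide-on relaxation of forward end points in
reverse) generate starts — the fluctuation theorems hold exactly for this
raw work, and the bidirectional curve then reproduces the Bennett solution
at the end states to machine precision.  Free-energy curves are anchored to
zero at $\lambda_a$; PMF profiles are anchored at their first occupied bin.
All additive constants are therefore explicit, never implicit.

A related numerical point: the simulator accumulates the work integral at
the integration time step (0.05 ps), not at the 1 ps sampling stride.
Quadrature on the sampled grid adds zero-mean noise of order 1 $k_BT$ per
5 ns trajectory, which exponential averaging converts into a systematic
$-\beta\sigma^2/2$ bias of several tenths of $k_BT$ — large enough to
swamp the estimator comparisons below.

## The estimator ladder

With forward works $W_F(\lambda)$ (from $\lambda_a$) and reverse works
$W_R(\lambda)$ (from $\lambda_b$) on a common grid:

* **Jarzynski, per direction** — $\Delta F(\lambda) = -\beta^{-1}\ln\langle
  e^{-\beta W(\lambda)}\rangle$, computed with log-sum-exp stabilization so
  $\beta W \in [-700, 700]$ cannot overflow.  Biased from above at finite
  sample size, increasingly so the further the system is driven.
* **Bennett acceptance ratio (BAR)** — the end-state difference solves
  $\sum_i [1 + \tfrac{n_F}{n_R} e^{\beta(W_{F,i} - \Delta F)}]^{-1} =
  \sum_j [1 + \tfrac{n_R}{n_F} e^{\beta(W_{R,j} + \Delta F)}]^{-1}$,
  by a damped fixed-point iteration (start 0, tolerance $10^{-8}$ kJ/mol,
  at most 1000 iterations) with bisection fallback on the monotone
  residual; the convergence flag is honest and a non-converged value is
  still returned, flagged.
* **Bidirectional curve (Minh–Adib weighting)** — each forward realization
  enters with weight $[n_F + n_R e^{\beta(\Delta F - W_{F,i}(\tau))}]^{-1}$
  and each reverse realization, represented by its time-reversed image with
  partial works $\hat W_j(\lambda) = W_{R,j}(\tau_\lambda) - W_{R,j}(\tau)$,
  with weight $[n_F + n_R e^{\beta(\Delta F + W_{R,j}(\tau))}]^{-1}$.  With
  $\Delta F$ from BAR these weights make the curve reduce to BAR exactly at
  both end states — an algebraic identity the test suite checks to
  $10^{-10}$ kJ/mol.
* **Chelli–Procacci-style curve** — the package's formulation evaluates the
  two unidirectional Jarzynski channels, re-references the reverse channel
  through the BAR end-state solution, and combines them with sample-size
  weights in the exponential domain:
  $e^{-\beta\Delta F(\lambda)} = [\,n_F \langle e^{-\beta W_F(\lambda)}
  \rangle + n_R\, e^{-\beta\Delta F_{\mathrm{BAR}}} \langle e^{-\beta
  W_R(\lambda)}\rangle\,]/(n_F + n_R)$.  This was a genuinely open design
  point; the formulation was chosen because it provably satisfies the
  properties that define this estimator family: it collapses to the
  Jarzynski equality when both channels agree (quasi-reversible pulls), it
  tracks the Minh–Adib curve in strongly dissipative pulls (the
  exponential average hands each $\lambda$ to the direction that reaches it
  with less dissipation), and it equals the Minh–Adib curve exactly on
  degenerate all-equal-works input.  Two alternatives — self-alignment of
  the reverse channel by its own total-work Jarzynski estimate, and a
  per-$\lambda$ Bennett balance on conjugate segment works — fail the
  dissipative-limit property by several $k_BT$ and were rejected.
* **Hummer–Szabo unbiasing to $G(\xi)$** — time-sliced, spring-biased
  samples are reweighted by $e^{-\beta W_t}$, normalized per slice by the
  Jarzynski estimate, histogrammed in $\xi$ and divided by the analytic
  bias factor $\sum_t e^{-\beta u(\xi, \lambda_t)} e^{\beta\Delta F_t}$.
  Bins are uniform and half-open (default 0.025 nm); bins never visited
  are reported as `NA`, never silently interpolated (`write_pmf_table()`
  offers clearly-labelled post-hoc interpolation).
* **Bidirectional $G(\xi)$** — method `"ma"` applies the Minh–Adib weights
  inside the Hummer–Szabo average, with the per-slice normalization from
  the bidirectional curve; method `"cp"` combines the two unidirectional
  Hummer–Szabo profiles the same way the Chelli–Procacci-style curve
  combines its channels.

`locate_basins_barriers()` then reports alternating interior minima and
maxima (plateaus collapse to their midpoint bin) after pruning
basin–barrier pairs of amplitude below `min_prominence` (default 1 kJ/mol;
the validation studies use 2 kJ/mol, about 0.8 $k_BT$, to ignore binning
ripple).  Barrier heights are directional — unbinding reads left-to-right,
binding right-to-left — and reported in kcal/mol.

## The synthetic simulator and what it does (not) emulate

`simulate_pulled_langevin()` integrates the overdamped Euler–Maruyama
update
$\xi \leftarrow \xi + F/\gamma\,dt + \sqrt{2 k_BT\,dt/\gamma}\;N(0,1)$
with $F = -G'_{\mathrm{true}}(\xi) + \kappa(\lambda(t) - \xi)$, in
compiled code, using R's RNG so a seed fixes the trajectory bit-for-bit.
One root seed spawns per-realization substreams up front, so ensembles are
reproducible regardless of execution order.  Inertial dynamics was
considered and rejected: estimator validation needs correct equilibrium
and work statistics, which the overdamped limit provides, not realistic
momenta.

Chosen study conditions, fixed once:

* **Friction** $\gamma = 2500$ amu/ps, i.e. a diffusion coefficient
  $D = k_BT/\gamma \approx 10^{-3}$ nm²/ps — typical of a small molecule
  in water at 300 K.  At the reference velocity this dissipates
  $\gamma v L \approx 1.3\,k_BT$ per 2.5 nm pull: mildly irreversible, as
  intended by a stiff-spring protocol.  A "restrained-solvent-like"
  condition (stiffer, less mobile environment) can be emulated by raising
  `friction`; the same estimators re-analyze it unchanged.
* **Time step** $dt = 0.05$ ps, keeping the stability number
  $dt\,(\kappa + \max|G''_{\mathrm{true}}|)/\gamma < 0.1$ (enforced as a
  precondition) and resolving the 1.2 ps spring relaxation time.
* **Ground truth** `gorge_potential()`: a linear ramp plus four Gaussians
  on $[0, 2.5]$ nm giving a deep bound basin near 0.25 nm, an intermediate
  bump near 1 nm, the main bottleneck barrier near 2 nm and a shallow
  exterior capture basin near 2.3 nm — a topological stand-in for a
  ligand-translocation profile, with a main unbinding barrier of
  ~53.6 kJ/mol (12.8 kcal/mol).  The coefficients are arguments, not
  constants.
* **Starts**: forward pulls equilibrate 50 ps under the guide at
  $\lambda_a$; each reverse pull relaxes its forward partner's end point
  50 ps under the guide at $\lambda_b$ (`make_reverse_start()`), mirroring
  the standard forward-snapshot / relaxed-endpoint preparation.  The
  synthetic forward starts are independent draws; autocorrelation between
  consecutive snapshots of a single equilibrium run is *not* emulated.

What passing tests on this simulator do **not** show about real data: there
is no orthogonal degree of freedom (the 1-D reduction is exact here, only
approximate for a molecular pull), no slow conformational gating, no
solvent memory, and the true profile is smooth at the bin scale.  The
validation demonstrates estimator correctness, not force-field realism.

## Quasiharmonic entropy

For a set of $N$ atoms (a "binding entity") sampled along the pull, the
mass-weighted covariance $\sigma = M^{1/2}\,\mathrm{cov}(x)\,M^{1/2}$
(Cartesian coordinates, atom-major flattening) defines quasiharmonic mode
frequencies $\omega_i = \sqrt{k_BT/\lambda_i}$ from its eigenvalues
$\lambda_i$ (amu nm²; these are distinct from the control parameter).  Two
entropy formulas are provided:

* quantum quasiharmonic:
  $S = k_B \sum_i [\,\alpha_i/(e^{\alpha_i}-1) - \ln(1 - e^{-\alpha_i})\,]$
  with $\alpha_i = \hbar\omega_i/k_BT$ — the default, because it damps the
  spurious contribution of soft Cartesian modes;
* Schlitter: $S = \tfrac{k_B}{2}\sum_i \ln(1 + k_BT e^2 \lambda_i/\hbar^2)$,
  an upper bound on the former (asserted property-style on random spectra).

Numerical choices: eigenvalues at or below $10^{-12}$ amu nm² are treated
as frozen and excluded (`n_retained` records the truncation — unavoidable
when a window holds fewer frames than $3N$, e.g. 400 frames against 1368
coordinates for a 456-atom entity); modes with $\alpha > 700$ contribute
exactly zero; no rigid-body superposition is applied before the covariance
by default, since that choice materially changes $S$ and should be the
caller's explicit decision.  Entropy is invariant under translation and
atom reordering (tested), but *not* claimed invariant under rotation — the
standard Cartesian quasiharmonic caveat.  The quasiharmonic merging of
multiple wells into one effective well means absolute values are upper
bounds; relative profiles are the meaningful quantity.

The time-resolved profile divides the synchronized frames of all
realizations into overlapping windows — `floor((n_frames - window_len) /
stride)` of them, a convention chosen because it reproduces the reference
arithmetic: 5000 frames in 400-frame windows advanced by 20 give exactly
230 windows, and $230 \times 0.01\,\mathrm{nm} + 0.2\,\mathrm{nm} =
2.5\,\mathrm{nm}$ covers the full pull (an inclusive-endpoint count would
give 231 and break that identity).  Each window pools the frames of every
realization (10 × 400 in the reference setup) into one covariance.
`relative_entropy_profile()` reports $T\Delta S$ in kcal/mol at the stated
temperature against a reference ensemble the caller must designate — the
bound state is the natural choice, but there is deliberately no silent
default, because which frames constitute "the bound state" is a scientific
decision.

## Interaction profiles

The geometric detectors use standard practice criteria, stated in the
configuration because the counts they produce are criterion-dependent:
hydrogen bonds require donor–acceptor distance < 0.35 nm *and*
donor–H···acceptor deviation from linearity < 30° (both strict); a water
bridge is exactly one water simultaneously hydrogen-bonded, in either role,
to both molecules (chains of two waters never count); hydrophobic contacts
are apolar heavy-atom pairs closer than 0.45 nm.  `build_planted_scene()`
constructs scenes whose ground truth is exact by construction and always
includes near-miss decoys 0.01 nm or 5° beyond the cutoffs, so false
positives are caught exactly.  Torsions follow the IUPAC sign convention
(cross-checked in the tests against an independent implementation), and
`dihedral_histogram()` uses circular adjacency with a prominence threshold
so a uniform series yields no peaks.

## Validation problem sizes

The shipped test suite and acceptance script validate at these sizes,
chosen to give comfortable statistical margins: the full reference protocol
(10+10 × 5 ns) for PMF recovery; 10+10 pulls at $v/50$ (250 ns each) and at
$10v$ (0.5 ns each) for the estimator limit checks; 1000 works per
direction for BAR recovery; 5000 frames for the oscillator entropy oracle;
50+50 pulls for the Crooks crossing property.  On the analytic gorge
profile the bidirectional estimator recovers the main barrier to within a
fraction of $k_BT$ and the full profile to < 0.5 $k_BT$ RMS, while both
unidirectional estimates deviate more on the same data — the qualitative
signature that motivates bidirectional pulling in the first place.

## Known limitations

Absolute quasiharmonic entropies are upper bounds and cannot be decomposed
into internal-coordinate contributions; the Chelli–Procacci-style weights
are this package's formulation of that estimator family, exact in its
limiting regimes but not a transcription of any single published weight
expression; kinetics are out of scope — a PMF barrier is not a proven
transition state, and no rate inference is offered; and the simulator's
1-D overdamped world validates estimators, not molecular mechanics.
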