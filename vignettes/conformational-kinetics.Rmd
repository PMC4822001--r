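---
title: "Markov state modelling of conformational exchange: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Markov state modelling of conformational exchange: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(conformakin)
```

# The model

`conformakin` analyses conformational dynamics by discretizing a
trajectory's phase space and estimating a master-equation model on the
discrete states. The pipeline was designed around the exchange of
calmodulin's C-terminal lobe between apo-like, holo-like and locally
unfolded sub-states, but every stage is generic.

## Featurization

Each frame is represented by the vector of minimum heavy-atom distances
over all residue pairs separated by at least `min_separation` residues in
sequence (default 3). This contact-map representation is invariant to
rigid motion and to atom ordering within a residue, and it resolves
localized rearrangements — aromatic stacking, binding-site formation,
helix unwinding — that a single global coordinate such as RMSD averages
away. The sequence-separation filter is interpreted literally as
`j - i >= 3`; the alternative reading "three residues between"
(`j - i >= 4`) is available through the argument.

Partial unfolding is classified from two inter-CA distances, Met124–Ala128
(helix G) and Ala128–Gly134 (second Ca²⁺-binding site), with lower cutoffs
of 11 and 15 Å. The two deformations are alternative local-unfolding
modes, so the shipped rule combines them with OR: either distance beyond
its cutoff marks the frame as partially unfolded. An AND variant is
exposed because the choice of connective is a genuine modelling decision;
OR is the default because the two order parameters report on distinct
structural elements whose unfolding events are observed separately.

Dihedrals use the IUPAC sign convention (cis = 0, trans = ±π), computed by
the standard projection formulation. Subset RMSD uses the least-squares
superposition (Kabsch) with the determinant correction so reflections are
never admitted.

## tICA

With features x(t), mean-free, the method solves

C(Δt) v = λ C(0) v,

where C(0) is the instantaneous covariance and C(Δt) the time-lagged
covariance, symmetrized as (C + Cᵀ)/2 before solving so the spectrum is
real. Lagged pairs are drawn strictly within trajectories. Numerical
choices:

* **Ridge regularization.** C(0) receives `eps = 1e-6 * trace/d` on the
  diagonal. Contact maps are rank-deficient whenever two distances are
  collinear; shrinkage keeps the generalized problem well-posed and
  deterministic, unlike a pseudo-inverse whose rank cut is
  tolerance-sensitive.
* **Normalization and sign.** Components are scaled to unit variance
  under C(0) and the largest-magnitude loading is made positive, removing
  the eigenvector sign ambiguity so plots and tests are reproducible.
* **Defaults.** Lag Δt = 40 ns and N = 20 retained components, the
  settings used for C-CaM; lags in ns are converted to frames through the
  trajectory's `frame_spacing` (0.1 ns by default, one snapshot per
  100 ps) and rounded with a warning when not exact.

Because components are whitened, the noise directions have the same unit
variance as the slow directions: clustering aimed at a specific slow
process should project onto the components that carry it (see the blind
recovery example below, which uses tIC1 only).

## Discretization

Microstates come from greedy farthest-point k-centers (default k = 100):
the first center is frame 1 (overridable, or random under a seed), each
subsequent center is the point farthest from the existing set, and points
join their nearest center. Greedy k-centers carries the classical
2-approximation guarantee on the covering radius, which the test suite
verifies against exhaustive subset search.

Macrostates (default 5) come from average-linkage agglomerative
clustering of a pairwise subset-RMSD matrix over the hydrophobic-interface
residues. Average linkage is the default because it is robust to the
non-Euclidean character of RMSD matrices; complete linkage and
Ward-on-embedding are configurable. The O(n²) matrix is built on a frame
subsample and remaining frames join the nearest representative.

## MSM estimation

Transition counts use a sliding window (every t pairs with t + τ),
maximizing data use; pairs never cross trajectory boundaries. Estimation
restricts to the largest strongly connected component of the count graph,
because the reversible estimator is undefined on disconnected sets. The
detailed-balance-constrained maximum-likelihood T(τ) is found by the
standard self-consistent iteration

x(i,j) ← (c(i,j) + c(j,i)) / (c(i)/x(i) + c(j)/x(j)),

iterated to a relative change below 1e-10 (cap 1e6 iterations), with
T(i,j) = x(i,j)/x(i) and π = x(i). Naive symmetrization (C + Cᵀ)/2 is
available behind a flag for comparison. The spectrum is computed from the
symmetric conjugate D^(1/2) T D^(-1/2), so eigenvalues are exactly real.

Implied timescales are t = −τ/ln μ. Eigenvalues within 1e-12 of 1 report
Inf; nonpositive eigenvalues have no timescale and report NA with a
warning. The lag scan declares a lag Markovian when the slowest timescale
changes by less than 10% relative to each of the next two tested lags — a
concrete realization of "convergence behaviour" that is configurable,
since no universal criterion exists.

Free-energy surfaces follow F(x,y) = −kT ln Σᵢ πᵢ hᵢ(x,y) with hᵢ the
normalized per-microstate histogram, shifted so the occupied minimum is
zero; empty bins are NA. Default kT = 0.5924 kcal/mol (room temperature,
298.15 K convention) and 100 bins per axis over the observed range.

## Transition path theory

Forward committors solve the linear boundary-value system
(I − T_II) q_I = T_IB·1 directly; backward committors use the
time-reversed chain (equal to 1 − q⁺ for reversible models, which the
tests assert to 1e-8). The net flux is decomposed by deterministic
widest-path subtraction: repeatedly find the maximum-bottleneck A→B path
(Dijkstra-style, ties broken toward the smallest state index), record it,
subtract its bottleneck along the path, stop at `stop_fraction` (default
0.9) of total flux. The fraction of flux "visiting" an intermediate set
is the flux carried by decomposed pathways containing at least one member
state; when states rather than frames define the set, a state counts as
partially unfolded when the majority of its frames are classified so.

## Kinetic Monte Carlo and observables

KMC trajectories draw the next state from the current row of T(τ), one
draw per lag time, starting from the most populated state. Observables are
realized by drawing a conformation uniformly from the visited state's
pool at each step — the minimal reading of "a random conformation
belonging to the relevant state" — with no sub-lag interpolation, since
the model has no information below τ.

Order parameters use the standard isotropic-ensemble formula

S² = (3(⟨x²⟩² + ⟨y²⟩² + ⟨z²⟩² + 2⟨xy⟩² + 2⟨xz⟩² + 2⟨yz⟩²) − 1)/2

over weighted unit bond vectors; MSM weighting assigns each frame
π(state)/n(state). Mutual information uses a bins × bins histogram
(default 24) in nats with a 20-permutation shuffle-null subtraction,
floored at zero. The default partition is equal-mass (quantile) bins per
axis over the observed range rather than a fixed grid over (−π, π]²: for
torsions confined to a single rotameric well a fixed circular grid leaves
most bins empty and the discretization loss is severe (≈0.09 nat on the
ρ = 0.8 Gaussian fixture), while equal-mass binning keeps it near
0.02 nat. The fixed circular grid remains available via
`binning = "fixed"` for data that genuinely span the circle.

# What the synthetic generators emulate

The generators provide the statistical structure the analysis assumes,
with exact ground truth:

* `sample_markov_chain` — discrete jump statistics with a known T, the
  ground truth for estimation, KMC, and TPT tests.
* `brownian_dynamics` — overdamped Euler–Maruyama diffusion on quartic
  multi-well potentials βU = h(x² − 1)², whose Boltzmann density is known
  in closed form; with h₁ ≫ h₂ in 2D the slow process is along x by
  construction, validating tICA's timescale separation.
* `toy_polymer` — a 12-bead chain switching between extended and hairpin
  geometries under Gaussian noise; the full blind pipeline must recover
  the hidden populations and switch rate.
* `correlated_torsions` — wrapped bivariate Gaussians with σ = 0.3 rad,
  so wrapping contributes below 1e-6 nat and MI = −½ ln(1 − ρ²) is exact.
* `cone_vectors` — uniform orientations within a cone of semi-angle θ₀,
  with S² = (cos θ₀ (1 + cos θ₀)/2)² exactly.

Every generator is a pure function of its arguments including the seed
(the global RNG stream is saved and restored), so documented runs are
bit-reproducible.

What they do **not** emulate: solvent and force-field detail, anharmonic
coupling between many degrees of freedom, non-Markovian memory from
projected dynamics, state-dependent noise, and the strongly non-uniform
trajectory lengths of adaptive-sampling data sets. Passing tests therefore
demonstrate correctness of the estimators and their closed-form limits,
not that a particular molecular system is well-described by an MSM at a
given lag — that judgement still rests on the implied-timescale scan and
Chapman–Kolmogorov behaviour on the data at hand.

# Validation sizes and statistical bounds

The validation suite uses 10⁶-step chains for parameter recovery (20
independent seeds; the slowest-timescale estimate is compared to truth
within 3 standard errors of the seed ensemble), 10⁵ frames for the blind
polymer recovery, 2×10⁶ Brownian steps for the landscape comparison, and
10⁶ samples for the S²/MI closed forms — sizes at which the closed-form
tolerances (0.01 on probabilities, 0.005 on S², 0.02 nat on MI,
0.15 kcal/mol on well free energies) are met with comfortable margin on
one CPU in well under a minute each.

Two statistical points are handled explicitly rather than loosely:

* Occupancy fractions of autocorrelated chains fluctuate with variance
  inflated by the integrated autocorrelation time; bounds on such
  fractions use 3·SE·sqrt(2 τ_int), not the naive binomial SE, so the
  tests have calibrated false-failure rates.
* "Well regions" for the double-well landscape comparison are the bins
  within 1 kT of each minimum. The steep flanks are excluded because
  finite bin width alone biases −kT ln(histogram) there by an amount
  comparable to the tolerance — a property of any histogram estimator,
  observable with no MSM in the loop.

# Known limitations

* The reversible MLE yields a point estimate; no Bayesian posterior over
  T(τ) (and hence no error bars on timescales from a single data set).
* Pathway decomposition is the deterministic widest-path scheme;
  stochastic decompositions of degenerate flux networks can differ while
  summing to the same totals.
* Hydrogen positions are not reconstructed; N–H vectors must be supplied
  or built upstream when computing backbone S² from heavy-atom data.
* PDB extraction refuses structures missing more than 20% of the residue
  range rather than modelling missing loops; completion is delegated to
  dedicated tools.
* The k-centers first-center default (frame 1) makes runs deterministic
  but means the microstate tessellation, like any k-centers tessellation,
  depends on frame ordering; use the seeded random override to probe
  sensitivity.

# A compact end-to-end run

```{r example, eval = FALSE}
tp  <- toy_polymer(20000, switch_prob = 0.02, noise_sigma = 0.3, seed = 42)
cf  <- contact_features(tp$trajectory)
mod <- fit_tica(cf, lag = 5, n_components = 2)
kc  <- k_centers(tica_project(mod, cf, n = 1), k = 2)
msm <- estimate_msm(count_transitions(kc$assignments, 1,
                                      frame_spacing = 0.1))
round(msm$T, 4)   # recovers the hidden 0.02 switch probability
msm$pi            # recovers the symmetric populations
```
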