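# conformakin

Markov state model (MSM) analysis of protein conformational dynamics in R.

Calmodulin's C-terminal lobe (C-CaM, residues E82–A147) exchanges between a
dominant apo-like conformation and a minor holo-like sub-state even in the
absence of Ca²⁺, and this pre-existing heterogeneity of its hydrophobic
binding interface is a candidate mechanism for conformational selection by
its many binding partners. Resolving such exchange from molecular-dynamics
data requires joining many short trajectories into one kinetic model.
`conformakin` implements the complete analysis chain for doing so:

1. **Featurization** — each frame becomes a vector |X⟩ of minimum
   heavy-atom distances over all residue pairs separated by at least three
   residues in sequence (the contact map), plus named inter-residue
   distances, torsion angles, subset RMSD with optimal superposition, and a
   two-cutoff (11 / 15 Å) classifier for partial unfolding.
2. **tICA** — time-lagged independent component analysis solves the
   generalized eigenproblem `C(Δt) v = λ C(0) v` on mean-free features; the
   eigenvectors (tICs, columns of the projection matrix P) are the most
   slowly decorrelating linear combinations of contact distances, and
   distances between conformations are measured as
   ‖Pᵀ|A⟩ − Pᵀ|B⟩‖₂ in the reduced space.
3. **Discretization** — greedy farthest-point k-centers clustering in tIC
   space (microstates), and average-linkage hierarchical clustering of a
   subset-RMSD matrix (interface-topology macrostates).
4. **MSM estimation** — sliding-window transition counts n(i,j) at lag τ;
   detailed-balance-constrained maximum-likelihood transition matrix T(τ)
   via the standard self-consistent iteration on the largest strongly
   connected component; stationary distribution π from the Perron
   eigenvector; implied timescales t = −τ / ln μ per eigenvalue μ; an
   implied-timescale lag scan to pick a Markovian lag.
5. **Transition path theory** — forward/backward committors from the
   boundary-value linear system, net reactive flux
   f⁺(i,j) = max(π_i q⁻_i T(i,j) q⁺_j − π_j q⁻_j T(j,i) q⁺_i, 0),
   deterministic widest-path decomposition into pathways, and flux
   fractions through intermediate state sets.
6. **Kinetic Monte Carlo** — trajectories sampled from the rows of T(τ)
   starting at the most populated state, with per-state conformation pools
   realizing observable time series.
7. **Ensemble observables** — free-energy landscapes
   F(x, y) = −kT ln Σᵢ πᵢ hᵢ(x, y); generalized NMR order parameters S²
   from weighted unit bond vectors; torsion mutual information in nats with
   a shuffle-null correction; Pearson correlation against experimental S²
   tables; projection of published PDB structures into a fitted tIC space.

Because the original 700 µs MD data set is far beyond desk scale, the
package ships synthetic generators with exactly known ground truth —
discrete Markov chains, overdamped Brownian dynamics on quartic multi-well
potentials, a two-state bead polymer, correlated torsion pairs, and
cone-restricted bond vectors — so every stage is validated end to end
against closed forms.

## Worked example

Blind recovery of a hidden two-state process. The toy polymer jumps between
an open and a compact 12-bead geometry with switch probability 0.02 per
frame under 0.3 Å coordinate noise; the pipeline sees only coordinates.

```r
library(conformakin)

tp  <- toy_polymer(20000, switch_prob = 0.02, noise_sigma = 0.3, seed = 42)
cf  <- contact_features(tp$trajectory)
#> <contact_features> 20000 frames x 45 residue pairs

mod <- fit_tica(cf, lag = 5, n_components = 2)
#> <tica_model> d = 45 features, N = 2 components, lag = 5 frames
#> eigenvalues: 0.82472 0.06671

proj <- tica_project(mod, cf, n = 1)     # tIC1 carries the switching
kc   <- k_centers(proj, k = 2)
msm  <- estimate_msm(count_transitions(kc$assignments, 1,
                                       frame_spacing = 0.1))
round(msm$T, 4)
#>        [,1]   [,2]
#> [1,] 0.9810 0.0190
#> [2,] 0.0199 0.9801
round(msm$pi, 3)
#> [1] 0.512 0.488
```

The leading tICA eigenvalue 0.825 matches the theoretical lag-5
autocorrelation of the hidden chain, (1 − 2·0.02)⁵ ≈ 0.815; the estimated
switch probabilities 0.0190 / 0.0199 recover the true 0.02, and the
populations recover the symmetric 50/50 split. Downstream stages run from
the same model:

```r
res <- transition_paths(msm, A = 1, B = 2, stop_fraction = 1)
#> <tpt> total flux 0.009726 per lag, |A| = 1, |B| = 1
#> 1 pathways capturing 100.0% of flux

kmc    <- sample_msm_trajectory(msm, 1000, seed = 1)
d      <- pair_distance(tp$trajectory, c(1, 12))
series <- realize_observables(kmc, kc$assignments, d, seed = 2)
head(series, 3)
#>   time_ns state frame     obs1
#> 1     0.0     1  8807 41.70205
#> 2     0.1     1 15902 42.11106
#> 3     0.2     1  9915 41.85440
```

`run_pipeline(trajectory, pipeline_config())` wires the stages together
with defaults mirroring the C-CaM study settings (tICA lag 40 ns, 20 tICs,
100 microstates, MSM lag 20 ns) and writes checksummed artifacts.

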