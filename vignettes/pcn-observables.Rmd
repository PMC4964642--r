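---
title: "Contact-network observables for folding-state discrimination: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contact-network observables for folding-state discrimination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcnfold)
```

This vignette records how `pcnfold`'s observables are defined, which
numerical and design choices were open, and why they were settled the way
they were. It states no empirical result beyond what the package's test
suite and `scripts/acceptance.R` themselves compute.

# From structure to network

A protein is reduced to its Cα trace: one node per residue, ordered by the
chain. The contact matrix holds all pairwise Euclidean distances; the
protein contact network (PCN) links residues `i ≠ j` with
`0 < d_ij ≤ 8 Å`. Points of note:

* **The 8 Å cutoff is inclusive.** "Upper threshold" is read as `≤`; at
  crystallographic coordinate precision the choice is immaterial, but it is
  fixed, tested at the boundary, and exposed (`run_config(threshold = …)`,
  CLI `--threshold`) for sensitivity analysis.
* **Backbone contacts belong to the full PCN.** Peptide-bonded neighbours
  sit 3.8 Å apart, well under the cutoff. They are removed only by the
  spectral module's backbone-reduction procedure, never globally.
* **Chain and conformer policy.** Default chain: the first that carries Cα
  atoms; multi-model files use the first model. Alternate locations keep
  the highest-occupancy conformer, ties broken by altLoc letter order.
  `MSE → M` and `SEC → C` are the only accepted substitutions — anything
  else fails loudly rather than being silently skipped, so a curated run
  cannot quietly lose residues.
* **Gaps.** Missing residues (sequence-number jumps) keep the observed
  residues as consecutive nodes and emit a warning with the gap count.
  Re-indexing keeps every matrix well-formed; the alternative (inserting
  disconnected placeholder nodes) would break the connectivity assumptions
  of the spectral module. Users who consider a gapped structure unusable
  can act on the warning.

Link weights for the entropy observables come from a 20×20 inter-residue
contact-potential matrix (the Miyazawa–Jernigan statistical contact
energies ship with the package; any symmetric 20×20 table can be
substituted). Potentials are negative, so each protein's link weights are
shifted by a per-protein constant making the *smallest link weight exactly
1* — entropies need positive weights, and anchoring the minimum at 1 makes
the integer-support ensemble (below) well-posed with `s_i ≥ k_i`
guaranteed.

# Ensemble entropies and S_R

For a weighted network with strengths `s_i` (row sums of weights) and
degrees `k_i` (row counts of links), two canonical maximum-entropy
ensembles over all node pairs are fitted:

* **Strength-only (`S_s`).** Pair weights are independent geometric
  variables on `{0, 1, 2, …}`: `π_ij(w) = (1 − x_i x_j)(x_i x_j)^w`,
  `x_i = e^{−α_i}`. The multipliers solve
  `⟨s_i⟩ = Σ_j x_i x_j / (1 − x_i x_j) = s_i`.
* **Strength + degree (`S_ks`).** `π_ij(0) = 1/Z_ij` and
  `π_ij(w ≥ 1) = y_i y_j (x_i x_j)^w / Z_ij`, matching both `⟨k_i⟩ = k_i`
  and `⟨s_i⟩ = s_i`.

Entropies (in nats) are summed per pair in closed form; the observable is
the ratio `S_R = S_s / S_ks ≥ 1`.

**Why integer weight support?** The constraint formalism only fixes the
*means* of strengths and degrees; the weight support is a modelling choice.
Nonnegative integers give closed-form geometric/Bernoulli pair
distributions, exact two-node reference solutions to validate the solver
against, and a natural meaning for the degree constraint (`P(w > 0)`).
A continuous-support variant would change absolute entropies but, sharing
the same constraint structure, largely cancels in the ratio. The
multipliers stay real-valued, so non-integer strengths are matched exactly.

**Solver.** Both fits minimise the convex dual (log-partition minus linear
term) by damped Newton with analytic Hessians: the full Newton step —
capped by a trust radius of 2 in log-multiplier space — is accepted
whenever it shrinks the residual; otherwise an Armijo backtracking line
search on the dual runs, with steepest descent as a final fallback. The
dual trajectory is recorded (`fit$dual_path`) and is monotone
non-increasing up to the Armijo roundoff slack (1e−12), which the tests
assert. Defaults: tolerance `1e−8` on the maximum absolute constraint
residual, `max_iter = 10000`; deterministic initialisation
`x_i = s_i/(1 + Σs)`, `y_i = k_i/(1 + Σk)`. Near machine precision the
dual saturates while the gradient still contracts, which is why
residual-shrinking Newton steps bypass the dual test; two-node reference
cases converge to residuals near 1e−14 this way.

**Degenerate inputs.**

* Isolated nodes (`s_i = k_i = 0`) are pinned to `π(0) = 1` and excluded
  from the solve; an empty network has zero entropy.
* Saturated degree constraints (a node linked to every possible partner,
  e.g. the two-node network with `k = (1, 1)`) place the optimum at
  infinite multipliers; the solver approaches it to any requested
  tolerance, reproducing the shifted-geometric closed form.
* If *every* node has `s_i = k_i` (all link weights exactly 1 — e.g. a flat
  potential), weights are almost surely 0/1 and the family collapses to the
  Bernoulli-link configuration model. This limit is solved explicitly,
  since finite weight multipliers do not exist there.
* `S_R` is undefined when `S_ks = 0` (e.g. a network forced to a single
  configuration); this raises an error rather than returning an infinity.
* The entropy sum runs over all `N(N−1)/2` pairs, not just observed links —
  required for the degree constraint to mean anything.

# Backbone reduction and Laplacian features

`b` is the smallest number of leading diagonals whose removal disconnects
the PCN, found by cumulative removal `d = 1, 2, …` with a connectivity
check after each step (a well-defined minimum; no tie-breaking needed).
Then `b − 1` diagonals are removed — by construction the most aggressive
backbone stripping that keeps one component, hence a unique spectrum with a
single zero eigenvalue. This filter is *protein-specific*, unlike the fixed
`d > 12` long-range convention used for `LRCO`.

The combinatorial Laplacian `L = D − A` is used (positive semi-definite;
eigenvalues are the squared frequencies of the network's vibrational
modes). The features are the three largest eigenvalues divided by `N_C` —
the residue count of the parsed trace, not the reduced network's edge
count — because the largest eigenvalues grow roughly linearly with chain
length and the observables should be size-independent. Eigenvalues come
from a full dense symmetric decomposition (`eigen(symmetric = TRUE)`),
deterministic and exact to ~1e−9 for every chain length in scope
(`N_C ≤ 2000`).

The procedure is deliberately *not* invariant under arbitrary node
relabelling — diagonals are defined by chain order — and the tests assert
this asymmetry.

# Link density R0 and classical comparators

`R_0` = (number of empty diagonals) / `N_C`, computed on the **full** PCN.
The denominator is `N_C`, not `N_C − 1`, so the maximum is
`(N_C − 1)/N_C < 1`; this normalisation is kept exactly as defined, and
adding links can only lower `R_0` (tested monotonicity).

`CO` is the *relative* contact order `(L_C N_C)^{-1} Σ |i − j|` over the
full PCN with no separation floor; `LRCO` is implemented as a per-residue
*count* of contacts with separation strictly greater than `min_sep = 12`.
Where a separation-weighted sum was conceivable instead, the count form of
the long-range-order convention was chosen; `min_sep` is exposed so the
sensitivity of any conclusion to this choice can be measured rather than
assumed. Mean hydropathy uses the Kyte–Doolittle scale shipped as data;
any complete 20-residue scale can be passed instead.

# Classification protocol

The classifier is Gaussian discriminant analysis. Both boundaries are
available; **quadratic is the default** (per-class covariances), with
`linear` (pooled covariance, the Fisher boundary) one flag away — the
source material describes the classifier both ways, and the package
surfaces the choice instead of hiding it. Priors are training-class
frequencies. Each class covariance receives a ridge of `1e−9 ×` the mean
feature variance: invisible at the scale of the data, but it keeps tiny
folds with correlated features invertible.

Cross-validation is 10-fold with re-randomised fold assignment over
`n_resamplings` repetitions (default 10000). Homology groups are an *input*
(the package does not compute homology); each group is dealt to the
currently smallest fold in random order, so folds stay balanced and no
group ever spans two folds. Per resampling, confusion counts are pooled
over the 10 test folds (positive class TS — MCC is invariant to the
choice); the report gives mean ± sd *across resamplings* of overall
accuracy, per-class accuracies, and MCC.

A note on that sd: it measures the fold-assignment variability of the CV
estimate on the fixed dataset. It converges to a constant as
`n_resamplings` grows — it is not a standard error and does not shrink as
`1/√n` — so the tests check that the mean stabilises between small and
large resampling counts and that the sd estimates agree, not that the sd
vanishes. On label-permuted data the pooled CV-MCC is known to be slightly
negative on average (the usual pessimistic bias of cross-validation under
the null), which is visible in the acceptance script's permuted-label
quantity.

# Synthetic generators: what they emulate, and what they do not

* `make_banded_network(n, occupied)` — exact banded adjacency; every
  diagonal-related quantity (`R_0`, profiles, `b`) has a hand-computable
  answer.
* `make_helix_trace(n)` — ideal α-helix geometry (rise 1.5 Å, radius
  2.3 Å, 100°/residue): a structure with *only* short-range order, whose
  contact pattern is length-independent.
* `make_random_globule(n, seed)` — self-avoiding chain growth with 3.8 Å
  bonds inside a sphere of radius `3.2 · n^{1/3}` Å (near globular-protein
  packing density), self-avoidance floor 3.5 Å, with per-step retries and
  whole-chain restarts. This produces connected PCNs with protein-like
  contact density and genuine long-range contacts (`b ≥ 2` typically) —
  enough to exercise every observable end to end.
* `make_two_class_features(...)` — Gaussian clouds with homology groups of
  chosen size and *known* Bayes error, the yardstick for the classifier
  tests.

All generators are pure functions of their arguments including the seed,
and they restore the global RNG state. What they do **not** emulate:
secondary-structure mixtures, native hydrogen-bond geometry, real
potential-weight correlations between sequence and structure, or realistic
homology (groups are label-pure blocks). Passing tests therefore
demonstrate the *correctness of the computations and the protocol*, not
biological classification performance; reproducing published TS/MS
accuracy requires a real annotated structure set (an id/label/group table
plus PDB files), which the pipeline accepts as user input.

# Problem sizes and determinism

The shipped tests run entirely offline on synthetic data: property sweeps
use ~100 random weighted networks of 6–13 nodes, exhaustive
backbone-break checks cover all band subsets of `{1..5}` up to 20 nodes,
classifier recovery uses 60 proteins × 1000 resamplings and a 200-protein
permutation null × 200 resamplings, and globule pipelines run at 30–150
residues. `scripts/acceptance.R` recomputes helix/globule observables (20
globules of 40–120 residues) and the classifier recovery quantities from a
single `--seed`. These sizes were chosen so the whole suite exercises every
code path in about a minute while keeping estimator noise far below the
asserted margins.

# Known limitations

* PDB input only (via `bio3d`); mmCIF is out of scope.
* The entropy ensembles assume independent pairs given the multipliers
  (canonical, soft constraints); microcanonical entropies and ensembles
  with distance or community constraints are not implemented.
* `S_R` on very sparse or near-degenerate networks inherits the
  numerical caveats above; `S_ks = 0` is refused.
* Homology grouping must be supplied; the package deliberately does not
  infer it.
* The discriminant assumes class-conditional Gaussians; for strongly
  non-elliptic feature clouds the reported accuracies are conservative
  lower bounds rather than optimal.
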