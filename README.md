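# pcnfold

Network observables of protein contact networks (PCNs) for discriminating
**two-state (TS)** from **multi-state (MS)** folding kinetics, with a
homology-aware cross-validated discriminant classifier.

## The problem

Experimentally, protein folding falls into two kinetic classes: two-state
folders flip between unfolded and native with no detectable intermediate,
while multi-state folders populate one or more intermediates. `pcnfold`
computes, from the native structure alone, physically interpretable network
observables that separate the two classes:

* **Ensemble-entropy ratio `S_R = S_s / S_ks`.** The protein is modelled as
  a weighted network: the PCN (Cα–Cα contacts within 8 Å) with
  contact-potential weights on its links, shifted per protein so the
  smallest weight is 1. Two maximum-entropy network ensembles are fitted
  with canonical (mean-value) constraints: one fixing only the node
  *strength* sequence `{s_i}` (entropy `S_s`), one fixing both strengths and
  *degrees* `{k_i}` (entropy `S_ks`). Per-pair link weights `w ∈ {0, 1, 2, …}`
  follow `π_ij(w) ∝ (x_i x_j)^w` (strength-only) or
  `π_ij(w≥1) ∝ y_i y_j (x_i x_j)^w` (strength+degree); entropies are summed
  over pairs in closed form. Since the second ensemble is more constrained,
  `S_s ≥ S_ks` and `S_R ≥ 1`. A large `S_R` means the strength sequence is
  compatible with many degree sequences — many candidate contact networks —
  the regime expected for multi-state folders.
* **Laplacian eigenvalue features `λ_N, λ_{N−1}, λ_{N−2}`.** The smallest
  number `b` of leading diagonals (links with sequence separation
  `|i − j| ≤ b`) whose removal disconnects the PCN is found per protein;
  `b − 1` diagonals are then removed — the strongest backbone stripping that
  keeps the network connected. The three largest eigenvalues of the
  combinatorial Laplacian `L = D − A` of this reduced network, divided by
  chain length `N_C`, are the highest vibrational frequencies of the
  protein's long-range contact structure.
* **Inter-residue link density `R_0`**: the fraction (over `N_C`) of
  sequence separations `d ∈ {1, …, N_C − 1}` whose diagonal carries no
  contact. Low `R_0` = diffuse, cooperative interactions at many separations.
* **Classical comparators**: chain length `N_C`, mean Kyte–Doolittle
  hydropathy `⟨h⟩`, relative contact order
  `CO = (L_C N_C)^{-1} Σ_{links} |i − j|`, and long-range contact order
  `LRCO = N_C^{-1} |{links with |i − j| > 12}|`.

Classification uses Gaussian discriminant analysis (quadratic by default,
linear available) with **homology-grouped 10-fold cross-validation**:
homologous proteins always land in the same fold, and the fold assignment is
re-randomised over many resamplings. Performance is reported as mean ± sd of
overall and per-class accuracy and the Matthews correlation coefficient

```
MCC = (TP·TN − FP·FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)).
```

## Worked example

```r
library(pcnfold)

g <- make_random_globule(80, seed = 7)        # compact synthetic Ca trace
pcn <- build_pcn(distance_matrix(g))          # 8 A contact network
print(pcn)
#> Protein contact network: 80 residues, 488 links

spectral_summary(pcn)
#> Spectral summary: b = 3 (2 diagonal(s) removed)
#>   lambda_N = 0.2673, lambda_N-1 = 0.2386, lambda_N-2 = 0.2194

round(pcn_features(g)[, c("N_C","b","lambda_N","lambda_N1","R0","S_R","CO","LRCO")], 4)
#>   N_C b lambda_N lambda_N1     R0    S_R     CO   LRCO
#> 1  80 3   0.2673    0.2386 0.1375 1.4832 0.1839 2.0125
```

Two leading diagonals are stripped before the spectrum is taken (`b = 3`);
only 7.5 tested separations in a hundred carry no contact (`R0 = 0.1375`, a
compact, cooperative fold); and the strength-only ensemble has 48% more
entropy than the strength+degree one (`S_R = 1.48`).

Classifying a synthetic two-class feature cloud shaped like the
`(λ_{N−1}, R_0)` plane:

```r
ds <- make_two_class_features(30, means = list(c(0.25, 0.30), c(0.35, 0.15)),
                              covariances = list(0.002 * diag(2), 0.002 * diag(2)),
                              group_size = 3, seed = 42,
                              feature_names = c("lambda_N1", "R0"))
grouped_kfold_cv(ds, k = 10, n_resamplings = 1000, seed = 1)
#> Grouped 10-fold CV (quadratic discriminant, 1000 resamplings, seed 1)
#>   features: lambda_N1, R0
#>   overall accuracy: 95.78 ± 0.83 %
#>   MS accuracy:      96.67 ± 0.00 %
#>   TS accuracy:      94.90 ± 1.66 %
#>   MCC:              0.92 ± 0.02
```

## Command line

A thin CLI wraps the same functions
(`system.file("cli", "pcnfold", package = "pcnfold")`):

```sh
pcnfold simulate --kind globule --n 60 --out g.pdb --seed 1
pcnfold features --out features.tsv g.pdb more/*.pdb
pcnfold classify --features features.tsv --labels labels.tsv \
        --subset lambda_N1,R0 --json report.json
```

`features` takes PDB files (or dense 0/1 contact-matrix files) and writes
one TSV row per protein with columns
`id chain N_C b lambda_N lambda_N1 lambda_N2 R0 S_s S_ks S_R h_mean CO LRCO`;
failures on individual structures are quarantined, and the run fails only
when nothing succeeds. `labels.tsv` has columns `id label group` with
labels `TS`/`MS` and homology-group identifiers. Exit codes: 0 success,
1 usage, 2 data error.

To analyse a real annotated protein set, build `labels.tsv` from your
annotation and point `features` at the corresponding PDB files — for
example, myoglobin (PDB `1A6N`, an MS folder, 151 residues in chain A)
yields `N_C = 151` and `b = 4` (3 backbone diagonals removed).

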