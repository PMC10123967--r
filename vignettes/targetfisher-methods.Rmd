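---
title: "Ensemble chemogenomic target prediction: models and methods"
author: "targetfisher"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble chemogenomic target prediction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the modeling idea

Target fishing asks, for a query compound, which proteins of a fixed panel
it is likely to bind. `targetfisher` treats this as chemogenomic binary
classification: a *compound–target pair* is one sample, represented by the
concatenation of a compound descriptor block and a protein descriptor
block, and a classifier learns to separate strong binders
(K~i~ ≤ 100 nM) from weak ones (K~i~ > 100 nM). Because the pair — not the
compound — is the sample, a single model covers every target on the panel,
and ranking the panel for a new compound is just scoring its pairs with
all panel members.

Six such classifiers are trained, one per combination of three compound
descriptor schemes (ECFP4, MACCS, Mol2D) and two protein schemes (ProA,
ProB), and fused into an ensemble. Multi-scale descriptors are the point:
structurally similar compounds with very different activities ("activity
cliffs") defeat any single representation, and descriptor families with
different blind spots compensate for one another.

## Labels

Replicate K~i~ measurements for one pair are aggregated by their median
when the spread is at most one order of magnitude (max/min ≤ 10, boundary
inclusive); pairs with a larger spread are contradictory and excluded.
Aggregated pairs are labeled positive iff K~i~ ≤ 100 nM (inclusive). The
median of an even number of replicates is the midpoint of the central two.

## Compound descriptors

* **ECFP4** — circular fingerprint of bond diameter 4 (radius 2), folded
  to 1024 bits. Computed by OpenBabel on the canonicalized structure and
  folded from 4096 to 1024 bits by OR (equivalent to hashing modulo 1024).
* **MACCS** — the 166 public substructure keys, via OpenBabel.
* **Mol2D** — 188 two-dimensional descriptors computed in-package from the
  heavy-atom graph: 30 constitutional, 25 topological, 44 connectivity
  (χ) indices, 7 κ shape indices, 21 Basak information indices, 25
  Gasteiger-charge descriptors and 36 MOE-type descriptors. The MOE-type
  family is three 12-bin sets of property-binned approximate van der
  Waals surface area (Labute-style sphere-cap subtraction), binned by
  partial charge, by a coarse atomic lipophilicity contribution, and by
  atomic polarizability. The fixed descriptor order is recorded by
  `mol2d_manifest()` and embedded in model bundles; prediction refuses to
  run when manifests disagree.

All structure handling goes through one canonical form (OpenBabel
canonical SMILES), so descriptor values cannot depend on how the input
SMILES was spelled. Standardization keeps the largest covalent fragment;
formal charges are left as drawn. Input SMILES that fail to parse are
logged and dropped, never fatal as long as one compound survives.

## Protein descriptors

**ProA** is sequence-derived: amino-acid composition (20),
autocorrelation (Moreau–Broto, Moran, Geary) over 8 standardized property
scales with lags 1–30, CTD composition/transition/distribution over 7
three-class property partitions (147), conjoint triads (343),
quasi-sequence-order (SOCN 30 + QSO 50), type-I pseudo-amino-acid
composition with λ = 30 (50), and principal-property window statistics
(5 scales × 7 windows × mean, sd = 70). Any sub-group wider than 50 is
PCA-compressed to min(50, N−1) components fitted on the panel. The group
budget on a rank-sufficient panel (N ≥ 51):

| group | raw | kept |
|---|---|---|
| amino-acid composition | 20 | 20 |
| autocorrelation (8 scales × 90) | 720 | 8 × 50 |
| CTD (C/T/D) | 21 + 21 + 105 | 21 + 21 + 50 |
| conjoint triad | 343 | 50 |
| sequence-order (SOCN + QSO) | 30 + 50 | 30 + 50 |
| pseudo-AA composition | 50 | 50 |
| principal-property windows | 70 | 70 |
| **total** | | **762** |

The embedded property table holds published per-residue scales
(Kyte–Doolittle hydropathy, Hopp–Woods hydrophilicity, residue mass,
side-chain volume, Grantham polarity and composition, isoelectric point,
Chou–Fasman helix propensity). The five "principal property" scales are
derived in-package as the leading principal components of that table —
the construction used for proteochemometric z-scales — rather than
shipping a second, unverifiable constant table. The sequence-order and
pseudo-AA coupling terms use distances in the same standardized property
space.

**ProB** is similarity-derived: four panel-wide N×N matrices — global
sequence-alignment similarity (BLOSUM62, gap open 10 / extend 0.5,
normalized S(a,b)/√(S(a,a)·S(b,b)) and clipped to [0,1]) and Resnik GO
semantic similarity for each aspect (BP, MF, CC). Each protein's row in
each matrix is PCA-compressed to min(50, N−1) components, giving 4 × 50 =
200 descriptors on panels of ≥ 51 targets. Resnik term similarity is the
information content of the most informative common ancestor, normalized by
the maximum IC in the aspect; protein-level mixing is the best-match
average. IC is estimated from the panel's own annotation corpus — a
deterministic, download-free choice; with a larger external corpus the IC
values (not the machinery) would change. Proteins without annotations in
an aspect get similarity 0 to all others and 1 to themselves; an aspect
with no annotations at all degrades to the identity matrix with a warning.

Because the panel is a fixed, closed prediction universe — the same at
training and prediction time — fitting PCA (and the similarity matrices)
on the whole panel leaks nothing: protein-side features are constants of
the panel, not statistics of the training labels.

## Models and ensembles

Each scheme model is a gradient-boosted tree classifier (xgboost,
`binary:logistic`). Hyperparameters (eta, max depth, gamma, boosting
rounds) are selected by exhaustive grid search under internal stratified
10-fold CV, maximizing mean AUC, ties broken toward fewer rounds and then
shallower trees, followed by a refit on all training data. The default
deployment grid is eta ∈ {0.05, 0.1, 0.3}, depth ∈ {4, 6, 8}, gamma ∈
{0, 1}, rounds ∈ {100, 300}.

Ensembles fuse the six member scores per pair: **mean** (arithmetic
average; the default and recommended model), **maximum** (elementwise max;
sensitivity-heavy by construction, since its score dominates the mean
elementwise), and **stacked** (a logistic combiner over the six scores,
trained on out-of-fold member predictions from a 5-fold internal split so
the combiner never sees resubstitution scores).

All stochastic steps fan a single integer master seed into per-task
sub-seeds; training is single-threaded by default, which makes runs
bit-reproducible.

## Evaluation protocol

Two split modes at the pair level: **pair-split** stratifies records
jointly by target and label across 10 folds, so every sufficiently
populated target appears in training and test; targets with ≤ 5 records
are forced into training everywhere (they are too small to stratify and
would otherwise contribute unstable test estimates). **Compound-split**
partitions unique compounds into 10 parts and lets every record follow its
compound, so test compounds are never seen in training — the harder,
prospective scenario. The protocol repeats the whole CV with fresh folds
and reports mean ± sd across repeats.

Classification metrics use the confusion matrix at threshold 0.5 —
ACC = (TP+TN)/(TP+TN+FP+FN), SE = TP/(TP+FN), SP = TN/(TN+FP) — and AUC
as the exact Mann–Whitney rank statistic (concordant + ½ ties)/(P·N),
computed on the pooled out-of-fold predictions of each repeat.

Ranking quality uses **recall@k**: every test compound is ranked against
the full panel (ties broken by ascending target id, which is
deterministic and seed-free), and recall@k is the percentage of known
positive test pairs whose target ranks ≤ k. A compound-level variant (the
fraction of compounds with at least one known target in the top k) is
available via `level = "compound"`; the pair-level definition is the
default. The **enrichment fold**, (recall/100)/(k/N), expresses recall@k
relative to uniform random ranking; 1.0 is chance.

## The synthetic benchmark

`generate_benchmark()` produces a complete, download-free study: the goal
is data with the *statistical shape* the method assumes, not medicinal-
chemistry realism.

* **Compounds** are assembled from a ~50-fragment grammar (linkers with a
  splice slot, plus terminal groups), 2–4 fragments per molecule, all
  joins single bonds — valid by construction and deterministic under the
  seed.
* **Targets** come in families of 6: members share a mutated copy of a
  family founder sequence (12% substitutions) and a core of family GO
  terms from a generated toy ontology (3 aspects × 50 terms, random DAG),
  so both ProB similarity channels carry real family signal.
* **Pharmacophore keys.** Each target family is anchored on three
  signature fragments of the grammar; the family key is the set of ECFP4
  bits those fragment cores produce, and each member target adds the bits
  of one member-specific fragment. Compound–target compatibility is the
  Tanimoto overlap o between the compound's fingerprint and the key —
  normalizing by the union is what gives *selectivity* (a bit-rich
  compound is not compatible with everything). Keys built this way are
  attainable by construction: compounds that carry a family's chemotype
  really do match its key.
* **Ligand sampling.** Half of each target's measured ligands are drawn
  from that family's selective chemotypes (compounds whose best-matching
  family is this one), the other half from the whole library. Bioactivity
  databases are exactly this kind of actives-enriched sample; uniform
  sampling would instead make "positives" mostly marginal pairs that no
  ranker — not even one with oracle access to the planted keys — could
  place in the top ranks.
* **Activities**: for a sampled pair, log~10~ K~i~ = 2 − β·z + ε, where z
  is the compatibility o standardized over all sampled pairs and
  ε ~ N(0, 0.5²) — 0.5 log units is the order of inter-assay K~i~
  variability. Centring at 2 (= 100 nM) keeps both classes populated at
  any β; β = 0 removes all learnable signal, giving a built-in negative
  control. About 10% of pairs receive replicate measurements with small
  jitter (scaled to zero in the noise-free limit) to exercise the
  aggregation rule, and 15% of targets get ≤ 5 ligands to exercise the
  forced-training rule.
* **Ground truth** (`truth_table()`) is the noise-free planted label
  (z ≥ 0), independent of the Gaussian draw. The latent state
  (fingerprints, keys, per-target signature fragments) is kept on the
  benchmark object for diagnostics.

Defaults are 60 targets, 800 compounds, mean 20 ligands per target,
β = 1.5, seed 7. What passing tests on this benchmark do *not* show:
performance on real chemistry (fragment-grammar molecules have no
activity cliffs, scaffolds, or assay artifacts), behavior under extreme
class imbalance, and generalization across target classes absent from the
family structure.

## Numerical choices and degenerate inputs

* PCA uses a deterministic sign convention (largest-magnitude loading
  element positive); zero-variance columns are allowed; the component
  count respects the rank bound min(k, p, n−1). Fewer than 2 samples is
  fatal.
* Sequences shorter than a lag/λ requirement reduce the lag to length−1
  with a warning. Non-canonical residues (X/B/Z/U/O) are dropped for the
  composition-type descriptors; more than 5% of them in one sequence is
  fatal.
* Non-finite Mol2D values (possible in theory for pathological graphs)
  are replaced by 0 with a named warning.
* Single-class label vectors, non-finite features, and feature-width
  mismatches against the model manifest are fatal with located messages.
* Ranking ties are broken by ascending target id everywhere.

## Problem sizes for desk-scale runs

Evaluation runs default to a single hyperparameter configuration
(eta 0.1, depth 5, gamma 0, 60 rounds, `fast_grid()`) instead of the full
deployment grid: an exhaustive 36-cell search inside every outer fold of
a repeated 10-fold CV multiplies the training cost by ~360 while the
planted-signal benchmark is insensitive to tuning. The full grid remains
the default for `grid_search_train()` / `target_ensemble()` deployments
and any grid can be passed to `run_cv()`. The packaged benchmark
(60 targets × 800 compounds, ~1,000 pairs, 3 repeats) was chosen so a
complete evaluation runs on one CPU in minutes; repeats default to 5 (50
for publication-grade variance estimates, via `n_repeats`).

## Known limitations

* The panel is closed: ProB features are defined only for panel members,
  so new targets require refitting the panel blocks (this is inherent to
  similarity-matrix descriptors, and intended).
* OpenBabel's ECFP enumeration differs in detail from other toolkits'
  (identifier deduplication across iterations), so folded bit vectors are
  comparable within this package, not bit-for-bit across toolkits.
* Gasteiger charges and the coarse lipophilicity contributions are
  approximations; the charge and MOE-type descriptor families inherit
  their quality.
* IC from the panel's own annotation corpus compresses similarity scale
  on sparsely annotated panels.
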