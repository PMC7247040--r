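---
title: "Consensus connectivity-driven parcellation: model, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus connectivity-driven parcellation: model, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(conparc)
```

## The problem and the model

A dense structural connectome assigns a nonnegative weight to every pair of
cortical surface vertices; conceptually it discretizes the intensity
λ(x, y) of a symmetric Poisson point process of tracts over the union Ω of
two topologically spherical hemispheres. Any partition of the vertices into
regions E_1 … E_L implies a coarse connectome

ω(E_u, E_v) = Σ_{x ∈ E_u} Σ_{y ∈ E_v} W_{x,y},

the expected tract count between regions. `conparc` searches for a *group*
partition that (a) respects each subject's own connectivity topology,
(b) requires no label correspondence across subjects, and (c) chooses its
own number of regions.

Stage one clusters each subject by Newman modularity with the Louvain
multilevel heuristic, recursively: each parcel is re-clustered as an
independent graph (edges leaving it are dropped), three levels deep.
Subject-level hierarchies are therefore nested by construction. The
recursion is stopped for parcels holding fewer than `min_parcel_fraction`
(default 1 %) of all vertices, and for parcels whose induced subgraph has no
edges.

Stage two treats partitions as points in a metric space. With binary
membership matrices P (rows = vertices, columns = labels, zero-padded to a
common column count), the distance is

d(C_i, C_j) = min over column permutations π of ‖P_i − P_j π‖²_F,

and the consensus is the minimizer of Σ_i d(C*, C_i) — a (pseudo-)Karcher
mean. Exact minimization is NP-complete, so the hard-ensemble (HE)
algorithm greedily absorbs one subject at a time: align the next subject's
membership columns to the running average by an exact linear-assignment
solve, average with weights (t−1):1, and finally harden rows by argmax.
The (t−1):1 weights make the final soft matrix the unweighted mean of all
aligned memberships — the natural reading of successive averaging; the
update weights are otherwise underdetermined, so we fix this convention.

## Design choices worth knowing about

**Modularity convention.** We take m = Σ_{u,v} W_{u,v} over *ordered*
pairs, so the one-community partition scores exactly 0 and Q ∈ [−1, 1].
`modularity_score()` is implemented directly from the definition and is
used in tests to validate the delegated Louvain optimizer
(`igraph::cluster_louvain`, resolution 1); the optimizer is a heuristic,
the score is the contract.

**Assignment, never greedy matching.** The column permutation in the
distance, and in every HE absorption step, is solved exactly by a
Jonker–Volgenant shortest-augmenting-path assignment solver. Greedy
matching can miss the optimum; the test suite checks the solver against
brute-force enumeration of all permutations for L ≤ 6.

**Hardening ties.** When two columns of the running membership tie on a
row, the lower column index wins (`max.col(ties.method = "first")`);
deterministic and documented. Labels emptied by hardening are dropped
before canonicalization.

**Per-level ensembling.** Consensus is computed independently per hierarchy
level. Consequently HE (and CSPA) consensus levels are *not* guaranteed to
nest — only subject-level hierarchies are. `is_nested()` makes the check
explicit rather than silently enforcing it.

**CSPA input.** The co-occurrence graph S counts, for each vertex pair, the
subjects assigning them one label; we build S from the deepest individual
partitions (the least lossy choice) and cluster it unthresholded with the
same three-level scheme. CSPA is known to produce coarser, less faithful
top levels; the tests assert this qualitatively rather than hiding it.

**Piecewise-constant denominators.** The block approximation divides
ω(E_i, E_j) by |E_i||E_j| for i ≠ j but by |E_i|(|E_i|−1) on diagonal
blocks, i.e. by the number of off-diagonal vertex pairs actually in the
block. Region "size" is the vertex count. With these choices γ is the exact
conditional block mean on the support used by the KL step, which is what
makes "KL = 0 iff block-constant" and refinement monotonicity true; dividing
diagonal blocks by |E_i|² would break both. KL itself is computed on
off-diagonal unordered pairs, both distributions renormalized after
restriction, natural log, 0·log 0 = 0.

**AMI.** We use the max-normalized adjusted mutual information with the
exact hypergeometric (fixed-marginal permutation) expectation. MI is
computed as H(X) + H(Y) − H(X, Y), which is algebraically the usual double
sum but returns exactly 1.0 (in IEEE arithmetic) for relabel-equivalent
partitions — identity checks need no tolerance. When both partitions are
trivial the denominator vanishes; we return 1 for equivalent inputs and 0
otherwise. The expectation is validated against a Monte-Carlo permutation
oracle on small tables.

**Graph characteristics.** Coarse graphs are near-complete, so binary
clustering coefficient and path length degenerate; we use the Onnela
geometric-mean triangle intensity on weights rescaled by the maximum
(scale-invariant) and shortest paths with edge length 1/weight (so path
length scales inversely with intensity). Graphs with fewer than three
regions raise rather than returning a vacuous value.

**Sparsification.** `sparsify(w, q)` keeps the heaviest fraction q of
nonzero upper-triangle edges, per subject; ties at the threshold are all
kept, making the operation monotone in q. Zeros are not edges.

**Contiguity.** A parcel is contiguous when its vertices induce exactly one
connected component in the triangle-edge adjacency graph; no attempt is
made to detect handles or holes beyond connectedness.

## What the synthetic generator emulates — and what it does not

`cohort_spec()` fixes the study conditions: an order-3 icosphere pair
(642 vertices per hemisphere, 1,284 total) as the working scale, N = 20
subjects, a mirrored planted hierarchy of 8 super-regions × 3 subdivisions
grown as farthest-point Voronoi cells (hence contiguous and perfectly
symmetric), within/between Poisson edge intensities 8 / 0.5, 10 % label
noise (each affected vertex adopts a mesh-neighbour's labels, so perturbed
boundaries move rather than teleport), and mean-1 lognormal edge noise with
sdlog 0.1. Order 3 keeps the full pipeline in seconds-to-minutes on one
CPU; the order-5 mesh (10,242 vertices per hemisphere, the standard
resampled cortical resolution) is exercised by the mesh-combinatorics check
and the acceptance script.

Pairs in the same level-1 region but different level-2 blocks receive an
intermediate intensity, by default the geometric mean √(within·between).
A flat within/between dichotomy at the deepest level would make the level-1
structure invisible to any clustering method — there would be nothing
coarse to recover — so the mid tier is what makes the planted hierarchy a
hierarchy. It is a spec of the generator, not a tuned constant.

The generator reproduces the *structure* of the real problem (mirrored
spherical topology, nested block connectivity, subject-level boundary
jitter, Poisson-like counts) but not cortical geometry, tractography
artefacts (distance bias, gyral bias, false-positive bundles), or
between-subject differences in region *number*. Passing tests therefore
demonstrate correctness of the algorithms and sensible behaviour under
controlled perturbations — not performance claims on acquired diffusion
data.

## Numerical and degenerate-input policy

- Partitions are canonicalized to first-appearance order, labels 0 … L−1;
  equivalence is `identical()` after canonicalization; vertex ids are
  0-based on disk, 1-based in R.
- Connectome constructors enforce exact symmetry, nonnegativity and a zero
  diagonal (nonzero diagonals are dropped with a warning); loaders
  symmetrize single-triangle input by the elementwise maximum.
- `modularity_score` raises on edgeless graphs; coarsening conserves total
  mass to 1e−9 relative tolerance (tested); Louvain on a parcel with no
  internal edges is skipped and the parcel copied unchanged.
- Every random step derives its seed from a user-visible master seed via a
  fixed integer recurrence, so cohorts, parcellations and experiments are
  bit-reproducible; R's global RNG state is saved and restored around each
  seeded block.

## Harness conventions

Half-splits draw ⌊N/2⌋ subjects without replacement per replicate; the
order-permutation harness reruns HE under shuffled subject order; both
return the full vector of pairwise AMI values (n(n−1)/2 of them) rather
than a summary, so callers choose their own statistic. The classification
harness fits the consensus on one stratified half of the cohort, coarsens
only the held-out half with it (no per-subject re-parcellation), and runs
stratified 5-fold outer cross-validation with an inner
`glmnet::cv.glmnet` lasso path on the upper-triangle coarse edge weights;
features are standardized from training data only. Reported AUCs are
rank-based (Wilcoxon) on each outer fold.

## Known limitations

- HE is greedy and order-dependent: it attains the brute-force Karcher
  optimum on majority-concentrated cohorts (tested exhaustively at K = 6)
  but carries no global guarantee; the order-permutation harness exists to
  quantify exactly this.
- Consensus levels need not nest; treat C^I/C^II/C^III consensuses as three
  resolutions, not a tree.
- Graph-Voronoi cells are contiguous by construction only when shortest
  paths stay inside cells; exact distance ties on the highly symmetric
  icosphere are broken toward the lower seed index.
- The CSPA co-occurrence graph is dense (K² memory); at order-5 meshes use
  HE or the average-graph method instead.
- Optional neuroimaging surface formats (GIFTI, FreeSurfer annot) are not
  read; meshes travel as ascii PLY with a hemisphere sidecar, labels and
  edge lists as TSV, connectomes as Matrix Market.
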