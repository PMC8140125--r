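---
title: "Finding signature genes and key regulators in disease PPI networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Finding signature genes and key regulators in disease PPI networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(keyregnet)
```

## The analysis this package implements

Many complex diseases are studied by a now-standard integrative recipe:
collect case/control expression series, screen them for differentially
expressed genes (DEGs), map the DEGs onto a protein–protein interaction
(PPI) network, and interrogate that network for structure — scale-free
topology, hierarchical communities, and a small set of genes that hold the
organization together. `keyregnet` implements that recipe end to end as
composable, deterministic functions, together with synthetic-data generators
that plant known truth so each stage can be validated without any external
database.

The intended use is a disease with one or more comorbidities: the index
disease and each comorbidity are measured by *two* independent series each,
and robustness is enforced by a consensus rule rather than by
multiple-testing correction.

## Differential expression screen

For each gene, `differential_expression()` computes logFC =
mean(disease) − mean(control) on log2-scale data and a two-sided Welch
(unequal-variance) t-test p-value. Two deliberate conventions:

* **No multiple-testing adjustment.** The screen intentionally uses the
  nominal p-value so the DEG list stays large; robustness comes from the
  *consensus rule* instead: `consensus_degs()` keeps a gene only if it
  passes the cut-offs in **both** series of a disease **with the same
  direction of change**. Under the null, per-series false positives are
  independent, so the consensus false-positive rate is roughly the square of
  the single-series rate — the suite verifies a near-empty consensus on
  null simulations.
* **Boundary semantics.** `filter_degs()` keeps `p_value < p_max`
  (strict) and `|logFC| >= lfc_min` (inclusive), defaults 0.05 and 0.5.
  The opposite-direction screen (`opposite_direction_genes()`, e.g. a
  fetal-versus-adult contrast) uses the stricter default |logFC| ≥ 1.

The Welch test replaces moderated (empirical-Bayes) statistics used by
microarray suites such as limma: the downstream pipeline consumes only
(logFC, p) pairs, and with ≥ 5 samples per group the planted-truth recovery
(recall and precision ≥ 0.9 at |logFC| ∈ [1, 2], noise sd 0.5, 10+10
samples) is insensitive to the moderation. This is a documented divergence
from microarray practice, not an endorsement of unmoderated tests at tiny n.

## Topology and power-law characterization

`compute_centralities()` reports, per node: degree; local clustering
C = 2e_i/(k_i(k_i−1)) with C = 0 for degree < 2; unnormalized Freeman
betweenness with all shortest paths counted; closeness C_C(i) = n_i/Σd_ij
where n_i counts *reachable* other nodes (isolated nodes score 0, a star
centre scores exactly 1); and eigenvector centrality as the non-negative
principal eigenvector of the adjacency matrix of the largest connected
component, scaled to unit Euclidean norm (other components score 0). The
eigensolve is a dense symmetric decomposition — deterministic and exact,
appropriate for PPI-scale graphs (≲ a few thousand nodes); very large graphs
are out of scope.

`topology_curves()` averages each measure over nodes of equal degree
(arithmetic means, no logarithmic binning). Neighbourhood connectivity
C_N(k) is estimated as the mean over degree-k nodes of each node's mean
neighbour degree — the standard estimator of the conditional expectation
Σ_q q·P(q|k); a rising C_N(k) indicates assortative mixing.

`fit_power_law()` deliberately exposes **two** fitting routes side by side:

* `"mle-ks"` — the Clauset–Shalizi–Newman procedure on a raw degree sample:
  discrete power-law likelihood (Hurwitz-zeta normalization, computed by
  direct summation with an Euler–Maclaurin tail), exponent by maximum
  likelihood per candidate x_min, x_min chosen to minimize the KS distance
  of the fitted tail, optional semi-parametric bootstrap goodness-of-fit.
  Valid only for exponents > 1; shallower results are flagged
  `valid = FALSE`.
* `"loglog-ols"` — least squares through (log k, log value) of any
  degree-binned curve, any sign of slope.

The two routes answer different questions, and published PPI analyses often
print sub-1 "power-law exponents" for clustering or centrality curves; such
values can only come from the OLS route, since the MLE regime excludes them.
The package therefore never maps one route's exponent onto the other, and
`null_comparison()` reports OLS exponents for all six curves.

## Null models

Two size-matched nulls calibrate every structural claim
(`null_comparison()`):

* **Degree-preserving rewiring** (`rewire_preserving_degree()`): Markov-chain
  double-edge swaps, rejecting swaps creating self-loops or duplicate edges;
  default 10 attempted swaps per edge, a common mixing heuristic for this
  chain. The degree of every node is preserved exactly (the suite asserts
  bit-identical degree maps); graphs admitting no legal swap (stars,
  complete graphs) are returned unchanged with a warning.
* **Erdős–Rényi G(n, M)** (`gen_gnm()`): uniform over simple graphs with the
  observed node and edge counts. Its expected mean clustering is the edge
  density 2M/(n(n−1)); at n = 775, M = 20357 that is 0.0679 ≈ 0.068 with
  diameter 3 — the reference values recomputed by the acceptance suite.

## Recursive community decomposition

`lev_split()` performs one Newman leading-eigenvector step: on a connected
module, build B = A − kkᵀ/(2m) *from the module treated as a standalone
network*, split by the sign of the leading eigenvector, and declare the
module indivisible when the leading eigenvalue is ≤ 1e−12 or the split does
not increase modularity. Disconnected modules first split into their
components (sign-splitting can never merge components). Determinism is
enforced by a fixed orientation rule — the lexicographically first node with
a non-negligible entry gets a positive entry; zero entries join the
non-negative side — and lexicographic child ordering.

Two genuinely open design points, and the choices made:

* **Submodule matrices.** Newman's original recursion uses a generalized
  modularity matrix referencing the full network. The recursive procedure
  implemented here instead re-runs the split on each module's induced
  subgraph as a fresh network, which matches the described practice of
  detecting modules "from the main network, then from the sub-modules", is
  self-similar across levels, and keeps every level's split interpretable as
  plain modularity optimization of that module.
* **Exactness.** The one-step spectral split is a relaxation: on arbitrary
  small random graphs it matches the exhaustive modularity-optimal
  bipartition in only ~3/4 of cases (it is exact on cleanly separated
  two-community fixtures, which the suite asserts). A universal
  "agrees-with-brute-force" guarantee is therefore *not* claimed; the hard
  invariants are that any accepted split has strictly positive modularity
  gain, never exceeding the exhaustive optimum.

`decompose_network()` applies the step breadth-first until modules are
indivisible, smaller than 3 nodes, or at `max_levels` (default 10). Terminal
modules containing at least one triangle carry the **motif** flag — the
operational definition of "motif" here is a terminal, indivisible module
with a triangle, the smallest strongly cohesive unit.

### Level summaries, Hamiltonian energy

`level_summaries()` cuts the tree at each level (a node's module is its
deepest ancestor at or above the cut) and reports Newman–Girvan modularity
Q = Σ_c[e_c/m − (d_c/2m)²] against the full network, plus the
Constant-Potts-Model Hamiltonian energy H = −Σ_c[e_c − γ n_c²] with
resolution γ = 0.5 (an edge-density threshold: a community is "worth its
energy" when its internal density exceeds γ). At γ = 0.5, splitting a
community of sizes n₁, n₂ with cut c changes H by c − n₁n₂ ≤ 0, so **H is
non-increasing down the hierarchy** — a provable invariant the suite asserts
on every fixture. Q per level is computed against the full network (the
natural convention when levels are compared on one plot); the within-parent
alternative was rejected as it makes levels incommensurable.

### Tracing and key regulators

`trace_seed_genes()` follows each seed gene (a consensus DEG present in the
network) down its branch, recording at each level the regulating probability
P_x = y^[l]/E^[l]: the gene's edge count inside its level-l module over that
module's total edges. E^[l] is read module-locally (not as the whole level's
edge count): at level 0 the ratio is degree/E of the full network, and the
ratio then measures how much of its *local* module each gene anchors —
empirically P_x rises with depth on hierarchical fixtures. A module with
zero edges yields P_x = 0, flagged.

`key_regulators()` applies three conditions: the seed's branch reaches the
maximum depth attained by any seed-containing branch; its terminal module is
terminal *by indivisibility* (not by the size or level caps); and the gene
itself participates in a triangle of that module. Seeds that reach the
deepest level without a motif are explicitly not key regulators.

## Local-community-paradigm statistics

For every edge (x, y), CN = |S(x) ∩ S(y)| over first neighbours (excluding
x and y), and LCL = number of edges among those common neighbours, bounded
by CN(CN−1)/2. LCP-corr is the Pearson correlation of (CN, LCL) over edges
with CN > 1; it is *undefined* — reported as a state, not an error — when
fewer than two edges qualify or either variable is constant (complete graphs
and triangles are canonical undefined cases). Statistics are computed over
existing edges only ("interacting pairs"), not candidate non-edges as in
link prediction. `per_level_lcp()` averages module-level LCP-corr per
hierarchy level, excluding undefined *and* exactly-zero modules (both are
flagged distinctly in per-module output), without size weighting.

## Interologs

`check_interolog()` calls an interaction (a, b) conserved in a species when
*some* ortholog of a and *some* ortholog of b interact there — any-member
semantics over many-to-many ortholog maps, with the lexicographically first
witnessing pair recorded for reproducibility. An interolog is an edge
conserved in **all** supplied species (so adding a species can only shrink
the set), and `conserved_motifs()` enumerates the triangles of the conserved
subgraph. Ortholog maps and species networks are plain TSV inputs; ortholog
inference and database retrieval are out of scope.

## Synthetic data: what it does and does not emulate

* `gen_expression_pair()` emulates paired two-group series: per-gene
  baselines uniform on [4, 12] (typical log2 microarray intensities) drawn
  once and shared by both series; a fraction `frac_de` of genes shifted by a
  signed logFC with |logFC| ~ U[lfc_low, lfc_high], identical in both
  series; i.i.d. Gaussian noise. Defaults (2000 genes, 10+10 samples, 10%
  DEGs, |logFC| ∈ [1, 2], sd 0.5) describe a well-powered microarray
  comparison. It does **not** simulate probe-level structure, normalization
  artefacts, batch effects, or gene–gene correlation — so a green recovery
  test establishes the screen's logic, not robustness to those nuisances.
* `gen_hierarchical_planted()` is a hierarchical stochastic block model over
  a balanced tree; edge probability depends only on the lowest-common-
  ancestor depth of the pair, strictly decreasing toward the root (defaults
  0.9/0.15/0.01 over 2 levels, branching 2, leaf size 16 — separation strong
  enough that leaf recovery is essentially exact). Truth labels exist at
  every level, refining downward.
* `gen_hierarchical_deterministic()` is the classic deterministic
  hierarchical construction (clique replication toward a root hub), used
  where a *deterministic* scale-free, high-clustering fixture is needed.
* `sample_power_law_network()` draws i.i.d. power-law degrees (γ > 2,
  inverse-CDF on a truncated support whose tail mass is < 1e−9) and wires
  them by the configuration model, then simplifies; realized degrees can sit
  slightly below the sampled ones.
* Community recovery is scored by comparing the planted leaf labels with the
  decomposition **cut at the planted depth**. The decomposition itself
  continues below that depth (a 0.9-density block of 16 nodes still admits
  modularity-positive splits), so terminal-partition ARI is lower by
  construction; the cut-level comparison is the meaningful recovery measure.

No generator parameter is tuned to test outcomes; all defaults were fixed
from the stated screening conventions or, where unstated, once from typical
values in this literature.

## Numerical conventions and edge cases

* Seeds: every stochastic function takes an explicit `seed` and restores the
  caller's RNG state; equal seeds give bit-identical results.
* Eigensolves: dense `eigen(symmetric = TRUE)`; leading eigenvalue ≤ 1e−12
  means indivisible; eigenvector entries within 1e−10 of zero count as
  non-negative for the split.
* Degenerate DEG inputs: zero variance in both groups gives p = 1 (equal
  means) or the smallest representable positive p (unequal means), flagged
  `degenerate`.
* Ranking ties in `essential_candidates()` break lexicographically by node
  identifier, so top-n lists are reproducible.
* Graphs are simple and undirected throughout; parsers collapse duplicate
  and reversed edges and drop self-loops with a warning; a third edge-list
  column (e.g. a STRING confidence score) is parsed and ignored — confidence
  thresholding is the data supplier's job.
* Diameter and radius are computed on the largest connected component.

## Known limitations

* Welch statistics, not moderated statistics, at small sample sizes.
* Dense eigensolves bound practical network size (~10³–10⁴ nodes).
* The spectral split is not an exact modularity optimizer (see above); no
  alternative community algorithms (Louvain, Infomap) are provided.
* LCP is not extended to link-prediction scores (CH/CAR indices).
* Orthology is consumed, never inferred.
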