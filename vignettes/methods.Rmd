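---
title: "Methods: screening, network clustering and enrichment in netpharm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening, network clustering and enrichment in netpharm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netpharm)
```

`netpharm` implements the standard network-pharmacology workflow for a
multi-component herbal medicine against a disease: ADME screening of the
herb's chemical constituents, construction of the component–target (C-T)
network, confidence filtering of a protein–protein interaction (PPI)
network, intersection of herb and disease targets, dense-module detection,
pathway/GO over-representation analysis, and assembly of the merged
component–target–pathway (C-T-P) network. This vignette describes each
model, the parameters that matter, and the choices made where the design
was genuinely open.

## 1. ADME screening

Each component carries tabulated pharmacokinetic descriptors: molecular
weight MW (Da), octanol–water partition AlogP, hydrogen-bond donor and
acceptor counts, topological polar surface area (Å²), oral bioavailability
OB (%), Caco-2 monolayer permeability (log nm/s scale), a drug-likeness
score DL in [0, 1], and a binary gastrointestinal absorption class GI
(High/Low, from a WlogP/TPSA permeation model; consumed as an input column,
never computed from structure). The strict filter is the conjunction of

* OB ≥ 30 — inclusive, OB is a percentage;
* Caco-2 > −0.4 — strict, values at or below −0.4 are conventionally
  read as non-permeable;
* DL ≥ 0.18 — inclusive, the customary drug-likeness cut for herbal
  compounds;
* GI = High — compared case-insensitively;
* Lipinski's rule of five with at most one violation among MW ≤ 500,
  AlogP ≤ 5, donors ≤ 5, acceptors ≤ 10, rotatable bonds ≤ 10.

The inequality directions follow the forms in which these thresholds are
quoted in the screening literature; OB and DL admit their boundary value,
Caco-2 does not. Tolerating one Lipinski violation is the classical
reading of the rule and is what makes highly lipophilic triterpenes
(AlogP > 6) still count as rule-compliant. When the rotatable-bond column
is absent that sub-condition is skipped with a warning rather than treated
as a violation — an untabulated descriptor is missing data, not evidence
of failure.

The DL score itself is the continuous Tanimoto form
\[
T(A,B) = \frac{A\cdot B}{\lVert A\rVert^2 + \lVert B\rVert^2 - A\cdot B},
\]
where \(A\) is a compound's descriptor vector and \(B\) the average
descriptor vector of a reference drug library. `tanimoto_dl` implements
exactly this form: it is symmetric, equals 1 iff \(A=B\) (nonzero), and is
bounded in [0, 1] for non-negative vectors. The denominator notation
circulates in several typographically garbled variants; the implementation
uses the canonical one above, which is the form the drug-likeness
literature defines against a reference library average.

Screening is monotone by construction: relaxing any threshold can only
grow the strict-pass set. Components failing the filter may be *added
back* via a whitelist — configuration, not code — which models the common
practice of retaining constituents with strong independent pharmacological
evidence (e.g. hepatoprotective phenolic acids) despite poor predicted
pharmacokinetics. The report keeps `strict_pass` and
`retained_via_whitelist` separate so the provenance of every retained
component stays visible.

## 2. Component–target network

Associations arrive per source: curated (`identified`), and predicted by
ligand-based tools (`hitpick`, scored by precision; `sea`, scored by MaxTc,
the maximum Tanimoto similarity to a known ligand of the target).
Predictions are kept at precision ≥ 0.5 and MaxTc ≥ 0.5 (inclusive);
curated rows are never score-filtered. Deduplication is plain set union on
(component, target) pairs — first within, then implicitly across sources —
because per-source unique counts generally sum to more than the printed
union, so cross-source overlap removal is the only consistent reading.
Gene symbols are uppercased and trimmed; no identifier-mapping service is
called (offline reproducibility), with a static synonym table as the
configuration hook for known aliases.

The two headline ratios are `n_targets / n_components` (average targets
per component) and `n_edges / n_targets` (mean number of components
hitting a target). Full precision is kept internally; display rounds to
one decimal.

## 3. PPI filtering and target intersection

PPI edge tables follow the STRING export dialect (`node1`, `node2`,
`combined_score`). Scores come in two conventions: probabilities in
[0, 1], or integers up to 1000. Any value above 1 switches the whole table
to the 0–1000 reading (divided by 1000); a table mixing fractional values
in (0, 1) with values above 1 is rejected as ambiguous rather than
guessed at. The default cutoff 0.7 — "high confidence" — is applied
inclusively. Self-loops, duplicate undirected edges and nodes isolated by
the filter are dropped; the published workflows report network sizes
smaller than their input gene lists precisely because non-interacting
targets fall out. Filtering is monotone: a higher cutoff always yields a
subgraph of a lower one.

The herb–disease analysis intersects the two symbol sets and induces the
PPI subgraph on the overlap; Venn counts (herb-only, disease-only, both)
are returned alongside. Degree rankings break ties lexicographically so
hub lists are deterministic.

## 4. MCODE-style dense-module detection

`find_clusters` is a from-scratch implementation of seed-and-grow
molecular complex detection:

1. **Vertex weighting.** For each vertex, take the subgraph induced on its
   closed neighborhood, find that subgraph's maximum core number
   \(k_{max}\) (k-core decomposition by iterative minimum-degree peeling),
   and weight the vertex \(k_{max} \times\) the loopless density
   \(2E/(N(N-1))\) of the \(k_{max}\)-core. Dense, mutually connected
   neighborhoods weigh high; an isolated vertex weighs 0.
2. **Growth.** From the highest-weight unvisited seed, breadth-first
   admit unvisited neighbors with weight ≥ (1 − vwp) × seed weight.
   Visited vertices are never regrown, so clusters are node-disjoint.
3. **Post-processing.** Optional *fluff* (add boundary vertices whose
   closed-neighborhood density exceeds a threshold; off by default, and
   the only step that can make clusters overlap), optional *haircut*
   (iterative removal of degree < 2 members, i.e. the 2-core of the
   cluster), then the **k-core filter**: a cluster is reported only if it
   contains an internal k-core of order `k_core`. Raising `k_core`
   therefore never increases the number of clusters.
4. **Scoring.** `score = density × N = 2E/(N−1)`. The loopless density is
   used because it reproduces published cluster score tables exactly from
   their (nodes, edges) pairs — the loop-including variant does not. A
   clique of size N scores N, the maximum for its size.

Defaults `vwp = 0.2`, `haircut = TRUE`, `fluff = FALSE` are the
conventional plugin defaults; typical `k_core` choices are 5 on a large
disease PPI network and 2 on a small direct-interaction network. All ties
(equal weights, equal scores) break lexicographically on node name, so
output is identical across runs and vertex orderings. One deliberate
difference from the original plugin: every cluster reports its growth
seed. Published tables occasionally state that a cluster "has no seed";
the plugin's condition for withholding a seed is undocumented, so this
implementation always records the vertex the cluster grew from.

## 5. Over-representation analysis

For a query of \(n\) genes against a set of \(K\) annotated genes in a
universe of \(N\), the overlap \(X\) under the null is hypergeometric and
the reported p-value is the exact upper tail \(P(X \ge k)\) — one-sided,
since only over-representation is of interest. Adjustment is
Benjamini–Hochberg step-up; `m_total` lets a reported subset of a larger
family be adjusted against the full family size (ten published rows out of
146 tested pathways reproduce their printed adjusted column only with
`m_total = 146`).

Two choices deserve emphasis:

* **Background.** Published analyses rarely state their universe — the
  main reproducibility gap in this workflow. The default is the union of
  all collection genes; an explicit background file overrides it, and
  query genes outside the background are dropped with a warning.
* **Screening vs adjustment.** The p-cutoff (default 0.05) screens on the
  *raw* p-value, while adjusted values are reported alongside — matching
  the workflows that screen pathways at nominal p and print adjusted
  columns separately. Ranking is by raw p ascending, ties broken by larger
  overlap then set id; truncation to `top_n` applies per category
  (BP/CC/MF tags are bookkeeping on sets, not separate statistics).

## 6. Network assembly

The target–pathway network has one node per pathway and per unique member
gene of the enrichment output, one edge per (pathway, gene) pair;
slash-separated gene fields are trimmed, uppercased and passed through the
synonym table (the shipped table resolves the truncated token GRIN2 to
GRIN2B, which is the only reading under which the published unique-target
union is internally consistent; the reader reports when normalization
changes the union so the alternative reading stays visible). The C-T-P
network is the union of the two bipartite layers with shared targets fused
into single nodes; a name used with two different types is an error, since
silently fusing a component with a gene symbol would corrupt the topology.
GraphML export round-trips all attributes; SIF, which has no
node-attribute slot, preserves topology only; the TSV export writes a
companion node-table so types survive.

## 7. Synthetic data: what it does and does not emulate

The generators produce every pipeline input with known ground truth, as
pure functions of (parameters, seed) using R's default RNG (seeded locally
and restored, so they never disturb the caller's stream):

* `gen_components` draws descriptors uniformly from ranges spanning a
  realistic herbal property table (MW 150–500 Da, AlogP −1 to 7, OB
  10–90%, Caco-2 −1.5 to 1, DL 0–0.8) and *constructs* a chosen fraction
  of rows to pass all five criteria, forcing one randomly chosen criterion
  into its failing range for each remaining row. Labels are therefore
  exact, and margins around every threshold are wide enough that the
  2-decimal rounding of the table cannot flip a label.
* `gen_planted_graph` builds an Erdős–Rényi background
  \(G(n, p)\) plus vertex-disjoint planted cliques on fresh nodes.
  Cliques rather than merely dense blobs: ground truth is unambiguous and
  density 1 maximizes the cluster score. Planted-module tests use
  two 6-cliques over a 40-node background at p = 0.03.
* `gen_genesets` plants one set sharing a fixed overlap with the query
  while decoys are uniform draws from the background (exactly null).
* `gen_associations` (a convenience beyond the three core generators)
  mixes curated and scored predicted rows with deliberate cross-source
  duplicates to exercise deduplication.

What passing tests on these inputs shows: the algorithms implement their
definitions correctly — label recovery is exact, planted modules are
recovered, the planted set ranks first, false-discovery control holds
under the null. What they do not show: behavior on real data. Real PPI
networks are scale-free with overlapping, fuzzy-boundary complexes rather
than clean cliques in a uniform background; real descriptor tables have
correlated columns (MW with acceptor counts, AlogP with TPSA); real gene
sets overlap heavily and violate the independent-draw null. Quantities
that depend on specific database snapshots (exact network sizes, cluster
memberships, raw enrichment p-values of a given annotation release) are
out of scope by design and are exercised only at the level of shipped
summary-table fixtures.

## 8. Numerical and degenerate-input choices

* All tie-breaks (vertex weights, degree rankings, cluster ordering,
  enrichment ties) are lexicographic — output is reproducible bit-for-bit
  across runs and input orderings.
* `cluster_score` requires N ≥ 2; density of a singleton is defined as 0
  in the weighting step, and clusters reduced below 2 nodes by haircut are
  dropped.
* An empty herb–disease overlap is an empty network, not an error; an
  empty query after background intersection *is* an error, since every
  downstream quantity would be undefined.
* Hypergeometric inputs are validated (k ≤ min(K, n), K, n ≤ N);
  `bh_adjust` rejects p-values outside (0, 1] and family sizes smaller
  than the number of p-values.
* The BH family-size mechanism is validated against hand-computed
  step-ups and a published ten-row table whose printed adjusted column is
  reproduced to within 0.5% relative — the residual being the 3-significant
  -figure rounding of the printed raw p-values, so exact printed-precision
  agreement is not attainable from the printed inputs.

## 9. Pipeline and problem sizes

`run_pipeline` chains screen → C-T network → disease PPI (+ clustering) →
intersection (+ clustering) → enrichment → C-T-P assembly from a
YAML/JSON config, with flags-over-config precedence handled by the caller
merging lists. The manifest records package version, seed, parameters,
input MD5 checksums and per-stage results, so identical configs give
identical manifests modulo the timestamp.

The shipped test and acceptance workloads use desk-scale sizes chosen to
exercise every code path while keeping a full check run in seconds: planted
-module recovery over 20 seeded 52-node instances, an exhaustive
hypergeometric enumeration sweep for all universes N ≤ 12, and a 200-rep
null simulation for false-discovery control. These sizes are the package's
own test design; the algorithms themselves are written for networks of
10³–10⁴ nodes (the k-core peeling is quadratic in the worst case, which is
ample for PPI networks of that scale).

## Known limitations

* GI absorption is consumed as a given class; the underlying permeation
  model is not reimplemented.
* The enrichment universe default (union of collection genes) is a
  convention, not a ground truth; conclusions can shift with an explicit
  background.
* MCODE-style clustering is greedy; it recovers planted cliques reliably
  but offers no optimality guarantee on overlapping or fuzzy modules.
* Symbol normalization is table-driven; aliases absent from the synonym
  table pass through unchanged.
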