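---
title: "Graph-based phenotyping: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graph-based phenotyping: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenospread)
```

`phenospread` decides, per patient, whether a record as a whole supports a
phenotype, using only the output shape of an automated concept coder
(per-document CUI mentions with confidence scores 0–1000), a relation
knowledge base, and a single seed concept. This vignette documents the
model, every tunable that matters, and the choices made where the design
was genuinely open.

## The embedding model

Reflective random indexing approximates a concept–concept association
matrix without ever forming it. Its assumptions are worth stating:

* **Distributional signal.** Concepts related to the phenotype co-occur
  with it (or with its other correlates) across documents. The embedding
  is blind to the *kind* of relation — that is what the knowledge filter
  is for.
* **Near-orthogonality.** Random sparse ternary vectors of dimension
  `dim = 1000` with `nonzeros = 10` balanced ±1 entries are nearly
  orthogonal with high probability, so superposition approximately
  preserves the identity of contributing concepts. Both values are
  exposed; 1000 is the standard choice at which 100 random vectors have
  mean absolute pairwise cosine well under 0.05 (asserted in the test
  suite).
* **One reflective pass.** Elemental → document → concept. A single pass
  already captures second-order association (two concepts never sharing a
  document correlate through shared contexts); further passes progressively
  blur the space and are deliberately not implemented.

Weighting follows the standard log-entropy scheme from latent semantic
analysis, with natural-log local weight `log(1 + tf)` and global weight
`g_i = 1 + Σ_j p_ij log p_ij / log n ∈ [0, 1]`. A concept confined to one
document gets `g = 1`; a concept spread evenly over the corpus gets
`g = 0` and effectively vanishes — this is what keeps ubiquitous
vocabulary (vital signs, administrative phrases) from gluing every
document vector together. Within-document repeat mentions enter only
through `tf`; membership of a document in a concept's reflective sum is
binary. For a one-document corpus all weights are 1 by convention
(`log n` would be 0).

Determinism is a design requirement: elemental vectors are generated from
a hash of `(master_seed, cui)` through a locally seeded RNG whose state is
restored afterwards, so a vector store can be reconstructed bit-for-bit
from its sidecar metadata and the corpus, and two runs of the pipeline on
the same inputs produce byte-identical artifacts.

**Degenerate inputs.** A document whose every concept has zero global
weight yields the zero vector; it is kept (with a warning) rather than
rejected so that corpora with rare degenerate documents still process end
to end. Cosine against a zero vector is defined as 0. Non-zero stored
vectors are unit norm to within 1e-9.

## Graph growth

`build_bfs_graph()` grows the seed neighborhood level by level:
`branching = 6` neighbors per expanded concept, `max_depth = 3` levels,
giving the capacity series 6, 36, 216 and a hard node bound of 259. These
defaults mirror working-memory-sized neighborhoods; both are exposed.
Three subtleties are deliberate:

* The top-`branching` list is computed *before* excluding concepts already
  in the graph; an already-seen neighbor is skipped, not replaced by the
  next candidate. Combined with no-cross-edges (below) this reproduces the
  near-tree topology the method expects, at the cost that the expansion
  can saturate — in dense clusters some members rank just past position
  `branching` in every list and are never reached. The planted-recovery
  tests measure exactly this effect (mean recovery ≈ 0.9 of a 12-concept
  cluster under strong association).
* When a queried neighbor already exists in the graph, no edge is added by
  default; `cross_edges = TRUE` adds the edge between existing nodes
  without duplicating the node.
* `min_cosine = 0` excludes anti-correlated neighbors, which also
  guarantees the nonnegative edge weights that spreading activation
  requires.

Ties in neighbor ranking are broken by ascending CUI; frontier processing
order is insertion order. Both rules exist purely so that identical inputs
give identical graphs.

## Knowledge filtering

Any relation between two endpoint concepts — regardless of direction or
predicate type — validates an edge. Where both databases support a pair,
the thesaurus wins and the label is prefixed `UMLS:`; within a source the
lexicographically smallest predicate is chosen. Precedence and tie rules
are conventions for deterministic output, not semantic claims. Filtering
never removes nodes: concepts orphaned by edge removal stay in the graph
and are excluded from inference only by the seed-component restriction
(`active_subgraph()`), since activation cannot cross components.
Predicate-aware weighting (e.g. boosting TREATS/DIAGNOSES) is out of
scope.

## Spreading activation

The update rule is full synchronous redistribution: at each step every
node with at least one incident edge sends its entire activation to its
neighbors in proportion to edge weights; its new activation is the sum of
its inflows. Stated as "inflows minus what was spread away", this is
exactly a conservation law, and conservation to 1e-9 is a test invariant
alongside linearity in the initial state (the dynamics are a fixed linear
map). A `retain` parameter (default 0) generalizes to partial
redistribution while preserving conservation. Edges are undirected
channels; isolated nodes hold their activation indefinitely. The
implementation is edge-wise message passing; the test suite checks it
against an independently coded dense transition-matrix power on hundreds
of random graphs.

Three steps (`steps = 3`) is the default inference horizon: on a
neighborhood of depth 3 that is exactly enough for evidence at the rim to
reach the seed, while keeping the map far from its stationary limit (in
which the seed's identity would wash out).

**The decision threshold.** The binary call is
`seed_activation > threshold` with default `threshold = 0`: any evidence
reaching the seed counts. This maximizes recall and is the right default
when the surrounding corpus is quiet, but initial activations are *sums*
of confidences, so the activation scale grows with record length and
corpus noise; no fixed absolute threshold transfers across corpora. For
cohort-level use the package provides `choose_threshold()`: the exact 1-D
split minimizing within-class variance of the cohort's seed activations
(Otsu's criterion). It is unsupervised — gold labels are never consulted —
and deterministic, and on cohorts with a genuinely bimodal activation
distribution it lands in the gap between "record brushes the graph" and
"record loads the graph". When the distribution is unimodal (no signal),
the split is arbitrary; this is visible in the null-signal test, where
calls made this way have precision equal to prevalence. The threshold
remains the method's main free parameter and is the first thing to
examine on real data (`threshold_sweep()` scores a grid).

## The synthetic study generator

`simulation_config()` defaults define the package's reference study:
428 patients at prevalence 0.192 (the scale of a realistic chart-review
evaluation cohort), 3–8 documents per patient, a planted
cluster of 12 seed-associated concepts, 60 background concepts,
per-document mention probabilities 0.6 (seed given case), 0.8 (associated
given case), 0.05 (associated given control), 0.1 (background, everyone),
confidences uniform on [500, 1000], and a knowledge base supporting all
cluster pairs, alternating thesaurus/literature provenance. The cluster
size echoes the roughly dozen-node active graphs the method produces in
practice; mention probabilities were chosen once to give strong but not
deterministic association. Mentions are sampled per document so that
term frequencies have real variance for the log-entropy weighting;
`occult_seed_mentions()` then hides all direct seed mentions for a chosen
share of cases — the patients a direct-mention baseline must miss by
construction.

What the generator does **not** emulate: extraction errors beyond the
confidence mechanism, negated or family-history mentions (a documented
false-positive source for coder baselines on real notes — note that in the
generator controls *never* mention the seed, so baseline precision is
perfect by construction and the baseline's weakness is confined to
recall), temporal structure, and correlated background topics. Passing
tests therefore demonstrate that the pipeline recovers planted
distributional-plus-knowledge structure and that the inference mathematics
is exact; they do not certify performance on clinical text.

## Problem sizes and runtimes

The test suite runs the reference study end to end over 10 seeded
replicates (428 patients, dimension 1000) in well under two minutes on a
single core, plus ~200 randomized oracle-equivalence trials on graphs of
up to 50 nodes and brute-force checks on stores of up to 60 concepts.
`scripts/acceptance.R` repeats the replicate study and the printed-report
arithmetic from a single command-line seed. Exact nearest-neighbor scans
are used throughout: at desk scale (thousands of concepts) approximate
indexes are unnecessary.

## Known limitations

* Negation and family history are not modeled; on real notes the graph
  method inherits the coder's false positives.
* The expansion cap can miss genuinely associated concepts whose
  association ranks just past the branching factor everywhere (the
  documented saturation effect); domain knowledge can be injected by
  adding nodes manually before filtering.
* The decision threshold does not transfer across corpora; calibrate per
  cohort.
* Single seed per graph; multi-phenotype inference means multiple runs.
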