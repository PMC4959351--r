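---
title: "Computing relatedness networks over multi-ontology knowledge graphs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Computing relatedness networks over multi-ontology knowledge graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ontorelate)
```

## The problem

Biomedical knowledge is split across ontologies — diseases, symptoms, gene
product properties, chemicals — each internally well connected but only
sparsely linked to the others. A clinically interesting relationship
(a disease that mimics another because both present the same symptoms, or
two diseases sharing a molecular mechanism) often exists in no single
ontology: it only emerges when cross-ontology links are followed. This
package represents such a hybrid knowledge base as a directed, typed,
weighted graph and computes, around a chosen *anchor* concept, the set of
concepts related to it through bounded chains of within- and
cross-ontology links — a *relatedness network*.

## The model

A knowledge network is a directed graph `G = (V, E, C, S)`. Each concept
`v ∈ V` belongs to exactly one registered ontology (the membership map is
total), and each edge carries a relation type, a confidence `C(e) ∈ [0, 1]`
and a significance `S(e) ∈ [0, 1]`. An edge whose endpoints share an
ontology is an *intra*-relationship; otherwise it is an
*inter*-relationship. Edges from curated structured sources default to
confidence and significance 1.0; edges derived from a literature corpus
carry computed weights (below). Traversal is strictly forward along stored
edges — hierarchies that should be walkable in both directions are
materialised as two typed edge sets (parent-to-child and child-to-parent),
which is the only reading consistent with the anchor's own children being
the first expansion ring.

### The expansion recursion

Write `O[i, j, t]` for the set of concepts of ontology `t` collected after
`j` intra-relationship steps and `i` inter-relationship steps from the
anchor. Two neighbour operators act on concept sets: `intra(X)` is the set
of forward intra-neighbours of `X` within its ontology, and `inter_t(X)`
the set of forward inter-neighbours of `X` landing in ontology `t`.
Neither unions its input; the recursion does that explicitly:

* base: `O[0, 0, s] = intra({anchor})` for the anchor's ontology `s`,
  and `O[0, 0, t] = inter_t({anchor})` for every other ontology `t`;
* `i = j`: `O[i, j, t] = O[i-1, j, t] ∪ O[i, j-1, t]`;
* `i < j`: `O[i, j, t] = intra(O[i, j-1, t]) ∪ O[i, j-1, t]`;
* `i > j`: `O[i, j, t] = ⋃_{k ≠ t} inter_t(O[i-1, i-1, k]) ∪ O[i-1, j, t]`.

The anchor itself is excluded from every set. Cells are pure functions of
`(i, j, t)`, so the engine memoizes them; a deliberately uncached
re-implementation of the same identities serves as the test oracle, and
the two agree cell-for-cell on randomly generated networks.

Two limit behaviours pin the recursion down. With no inter edges,
`O[i, j, s]` is exactly the forward intra ball of depth `j + 1` around the
anchor (depth `j + 1`, not `j`, because the base cell is already the
one-hop ring), and every other ontology's set is empty. With no intra
edges, cells depend only on `i` and equal the concepts at the end of
forward inter walks of length at most `i + 1`. Both are verified against
independent breadth-first searches.

```{r}
net <- toy_disease_symptom_network()
expand_set(net, "D0", 1, 1, "D")
```

### The interesting set

Expansion mixes two kinds of findings: concepts any single-ontology
browser would reach, and concepts reachable only by crossing ontologies.
The pruning rule

`F(i) = O[i, i, t] − O[0, i, t]`

removes the intra-only reachable part, leaving concepts related to the
anchor exclusively through cross-ontology paths. On the worked example the
anchor (a disease labelled Lupus) reaches a disease labelled Rheumatoid
Arthritis only through two similar symptoms, and `F(2)` contains exactly
the four diseases with such symptom-mediated routes:

```{r}
interesting_set(net, "D0", 2, "D")
```

### Link masks

A mask entry `R(t, c, s)` attaches to a relation type: `t = 0` blocks the
type outright; `t = 1` follows an edge only when its confidence strictly
exceeds `c` *and* its significance strictly exceeds `s`. Strict comparison
is deliberate — an edge exactly at a threshold is dropped — so `R(1, 0, 0)`
passes any edge with positive weights and blocks zero-weight edges. A
wildcard entry (`all`/`rest`) covers types without their own entry; types
matching neither pass. Masks can be applied at traversal time or by
pruning the whole graph first; the two are equivalent (tested
property-wise), and the pruned-graph route is cheaper when many anchors
share one mask.

One property worth spelling out: tightening a mask shrinks every expansion
cell (the recursion is monotone in the edge set), but it does **not**
always shrink `F(i)`. `F` is a set difference; removing an intra edge can
take a concept out of the subtracted intra-only cell while a surviving
inter path keeps it in the diagonal, so `F` can gain members under a
stricter mask. This is not a defect — pruning direct links precisely in
order to surface indirect ones is a standard use of masks — but it means
`F`-sizes in a mask sweep need not be monotone in mask strictness. On our
random-network test bed roughly 1–2% of (graph, ontology) cases show such
growth between a loose and a tight all-type mask.

### Hub exclusion

Concepts linked to very many others (e.g. gene product properties required
by most processes) flood the expansion with uninformative candidates.
`exclude_hubs()` removes concepts whose degree (under a chosen edge class)
exceeds a user-set cut-off, together with their edges. There is no default
cut-off: it is a modelling decision that depends on the degree
distribution of the actual data.

## Corpus-derived edge weights

Cross-ontology edges extracted from a document corpus carry computed
weights. For a concept pair `(u, v)`:

* **confidence** is a pair-level TF-IDF: with `n(u, v)` the number of
  documents containing both concepts (which here equals the pair's
  document frequency, since a pair counts at most once per document) and
  `N` the corpus size, the raw weight is
  `w = n · (log((N+1)/(n+1)) + 1)`, normalised by the corpus-wide maximum
  so confidences lie in `(0, 1]` and the strongest pair scores exactly 1.
  The `+1` outside the logarithm keeps every weight strictly positive —
  including the single-document corpus, where the smoothed log term alone
  would vanish. TF-IDF has many variants; this one was chosen because it
  is the simplest that yields valid, self-normalising confidence values,
  and the choice matters less than its contract (range `(0, 1]`, maximum
  attained), which is what the tests pin down.
* **significance** is the mean impact factor of the supporting documents,
  normalised by the maximum such mean over all pairs. Mean-then-max-scale
  makes the scores bounded and invariant under rescaling all impact
  factors by a positive constant (changing journals' units should not
  change relative importance).

Ontology-derived edges keep the structured-source default of 1.0 for both
weights; the significance default is 1.0 by symmetry with the stated
confidence default (no number is conventional here, so the package makes
it configurable at the edge-table level).

## Evaluation harnesses

`misdiagnosis_candidates()` (the `F(steps)` set in the anchor's own
ontology), `intra_only_baseline()` (the forward intra ball — what a
single-ontology search would return), `recall_report()` against a
reference list, `disease_pair_candidates()`/`hit_ratio()` against a
confirmation list, `random_pair_baseline()` (uniform partner sampling,
seed-deterministic), and `mask_sweep()` (edge counts and mean candidate
counts per mask, as percentages of the unmasked run, which is 100% by
convention). Percentages are reported to one decimal and hit ratios to
two, matching how such tables are conventionally printed.

## Synthetic test beds

Because real disease/symptom/gene resources are large, versioned and
partly manually curated, the test suite runs on generated networks:

* `toy_disease_symptom_network()` — the fixed 14-concept worked example.
  Its edge list is the minimal directed graph satisfying all nine
  expansion identities documented above; each identity was verified by
  hand before the fixture was adopted as an oracle.
* `simulate_bmkn()` — random multi-ontology networks: each ontology a
  random rooted tree (edges directed root-to-leaf, mimicking
  parent-to-child hierarchy links) plus extra intra edges at rate 0.05
  and cross-ontology edges at rate 0.02 by default; weights either the
  structured default 1.0 or Uniform(0, 1). Property tests use 3
  ontologies of 8–16 concepts so that five expansion steps neither
  saturate the graph instantly nor leave it disconnected.
* `simulate_planted_bmkn()` — a two-ontology network (40 diseases, 30
  symptoms by default) where 4 planted diseases share a symptom with the
  anchor while sitting in a different branch of the disease hierarchy
  (forward intra distance greater than 3, so outside the intra-only
  ball). Background disease–symptom noise at rate 0.005 produces chance
  candidates. The planted list is the ground truth for recall
  comparisons: symptom-mediated expansion recovers essentially 100% of
  planted diseases, the intra-only baseline 0%, and random pairing about
  `n_planted / (n_diseases − 1)` ≈ 10%.
* `simulate_corpus()` — documents of 2–5 concepts sampled uniformly from
  a pool, designated pairs injected with probability `pair_bias`, impact
  factors LogNormal(meanlog 1, sdlog 0.5).

What these generators do *not* emulate: the heavy-tailed degree
distributions of real ontologies, cycles and multiple inheritance in
is-a hierarchies, correlated annotation noise, or realistic
disease–symptom co-morbidity structure. Green tests therefore demonstrate
that the inference machinery is correct and that the method's directional
advantage over intra-only and random baselines holds when cross-ontology
signal exists — not that any particular recall level will be achieved on
real resources.

## Numerical and design choices

* Set results are returned sorted; exports write sorted records, so equal
  structures serialize to identical bytes.
* Mask thresholds compare strictly (`>`); flag `t = 0` ignores both
  thresholds entirely.
* Typed mask entries take precedence over the wildcard; unmatched types
  pass.
* `diagonal_profile()` reports its fixpoint as the first step whose
  diagonal sets match the previous step's (an anchor with no edges is at
  a fixpoint from step 0).
* Degenerate inputs: an isolated anchor yields empty initial sets and an
  empty relatedness network; an empty reference list, an all-zero
  impact-factor corpus, and a corpus where no pair reaches `min_count`
  are errors, not silent zeros.
* Problem sizes in tests and the acceptance script (100 random graphs for
  the oracle comparison, cells up to index 4, 20 planted-network seeds)
  were chosen so the full check runs in about two minutes while keeping
  each property's case count in the hundreds.

## Limitations

Confidence and significance gate traversal but are never propagated or
multiplied along paths; the method ranks nothing within `F(i)`. Concept
identity is exact string equality — no cross-ontology alignment or CURIE
normalisation. The OBO reader covers the tags needed for hierarchy-style
ontologies (`id`, `name`, `is_a`, `relationship`, `is_obsolete`) and
ignores the rest. Real-world effectiveness depends entirely on the
density and quality of the inter-ontology links supplied.
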