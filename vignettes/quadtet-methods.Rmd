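---
title: "Tetrad and quadruplex topology classification: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tetrad and quadruplex topology classification: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quadtet)
```

This vignette documents the model behind `quadruplex_analysis()`, the
parameters that matter, the synthetic-data generators used throughout the
test suite, and the design choices made where the method leaves room.

## The pipeline

The analysis runs in five stages over an *annotation graph* — the ordered
residue list of one structure model plus its base pairs (with
Leontis–Westhof edge and cis/trans labels) and base-stacking contacts.

1. **Ingestion.** The graph comes from a DSSR-style JSON annotation, from
   the package's own annotation JSON dialect, or from atomic coordinates
   through the built-in geometric annotator.  When both an annotation and
   a structure file are supplied, the annotation wins and the coordinates
   are only checked for consistency.
2. **Tetrad finding.** Tetrads are vertex-disjoint 4-cycles in the
   base-pair graph.  In default mode every pair is traversable, which
   admits quartets held together by mixed pair chemistry; `strict = TRUE`
   restricts traversal to cis Watson–Crick/Hoogsteen pairs, the chemistry
   of a canonical G-tetrad.
3. **ONZ classification.** Each cycle is oriented — A is the 5′-most
   residue, and the walk direction follows A's Watson–Crick edge — and the
   5′→3′ arrangement of B, C, D decides one of the six classes O±, N±, Z±.
   For multimeric motifs the chain order is first optimized (below).
4. **Quadruplex assembly.** Tetrads whose residues stack (a one-to-one
   matching with at least `4 − stacking_mismatch` stacked residue pairs)
   are joined; connected components with ≥ 2 tetrads are quadruplexes,
   singletons are reported as lone tetrads.  Components are ordered along
   a stacking path from the tetrad holding the 5′-most residue, and the
   four tracts are built by chaining the per-step matchings.
5. **ONZM classification and output.** Letter (common, else M; R when any
   tetrad is unclassified), tract direction (p/a/h from the monotone
   index runs along the stack) and sign (+/−/*) combine into the class.
   Output includes the two-line dot-bracket and the arc diagram.

## Chain reordering for multimeric motifs

The 5′→3′ arrangement is well defined only for a committed strand order.
For motifs spanning several chains the package evaluates **all
permutations of the participating chains** (non-participating chains keep
their relative order and follow after) and commits the permutation that
maximizes, in order: the number of O-class tetrads, then the number of
N-class tetrads, then the lexicographically earliest chain order.  The
O-first objective reflects the strong dominance of O-type tetrads in
solved structures; the remaining two levels exist purely to make the
result deterministic — the method itself only demands O-maximization, so
any total tie-break is admissible and ours is the simplest reproducible
one.  Sign is deliberately not part of the objective.

Orientation and classification inside the permutation loop use a
precomputed integer-only path (the per-cycle Watson–Crick direction flags
do not depend on chain order), so the 8-chain worst case (40 320
permutations) completes in seconds.  Beyond 8 participating chains the
exhaustive search is refused and the input order kept, with a warning:
40 320 evaluations is the largest search we consider proportionate for a
single structure, and no deposited quadruplex we are aware of exceeds
eight strands.

With `no_reorder = TRUE` multimeric tetrads are left unclassified (their
arcs render grey); single-chain tetrads are classified either way.

## Tunable parameters

* `stacking_mismatch` (0, 1, 2; default 2) — how many of the four aligned
  residue pairs between consecutive tetrads may lack a stacking contact.
  0 enforces ideal geometry; the default tolerates the imperfect stacking
  common in experimental models.  The stacked-pair relation is monotone in
  this parameter, so raising it can only merge, never split, quadruplexes.
* `relaxed_stem` (default off) — additionally joins *sequentially
  neighbouring* tetrads regardless of stacking.  The method names this
  behaviour without defining the adjacency criterion; we define it as: the
  two tetrads share at least one chain and, on every shared chain, the gap
  between their index ranges contains no residue of a third tetrad.
* `strict` (default off) — see stage 2 above.
* Geometric annotator thresholds (all config-exposed):
  hydrogen-bond heavy-atom distance ≤ 3.5 Å with ≥ 2 polar contacts for a
  pair; ring-centroid distance ≤ 4.5 Å, inter-plane angle ≤ 30° and
  non-empty projected ring overlap for stacking.  These are conventional
  annotation values, chosen once; the upstream annotator a user supplies
  via JSON takes precedence over all of them.

## The geometric annotator

When only coordinates are available, pairs and stacks are derived
in-package.  A pair's edges are read off an edge–atom table (which polar
atoms belong to the Watson–Crick, Hoogsteen and sugar edge of each base),
each residue taking the edge with most participating contacts (ties
resolved W > H > S).  Orientation is cis when the two glycosidic bonds
point to the same side of the axis joining the glycosidic nitrogens,
projected into the mean base-pair plane.  Because base-pair hydrogen
bonds run within the base planes, candidate contacts whose inter-centroid
direction lies along the base normal, or whose planes are closer to
perpendicular than parallel, are rejected — without this filter the
atoms of two *stacked* bases (3.3 Å apart) would satisfy the distance
criterion and produce spurious pairs.  Ring overlap for stacking is a
convex-polygon test after projecting both rings onto their mean plane.

This annotator is a self-contained geometric implementation with its own
documented criteria; matching any external annotator's output on
arbitrary deposited structures is a best-effort goal, not an invariant —
the supported route for exact agreement with an external tool is its JSON
output.

## Determinism and numerical choices

* **Candidate cycles** are enumerated through common-neighbour pairs of
  each vertex pair and identified by a canonical diagonal key, so each
  4-cycle is considered exactly once.
* **Disjoint selection** among overlapping candidate cycles maximizes, in
  order: cardinality, the count of cis Watson–Crick/Hoogsteen pairs, the
  sorted vector of per-cycle minimum indices, then the sorted canonical
  keys.  The order is total, so the optimum is unique and the search
  (branch-and-bound over candidates in preference order) reproducible.
  Past 32 candidate cycles a greedy pass in the same preference order is
  used instead, with a warning; base-pair graphs of real structures stay
  far below that.
* **Orientation fall-backs.** When A's edges are symmetric or unknown
  (possible in default mode), the walk runs toward A's cycle neighbour
  with the smaller global index — this makes non-strict mode total and
  keeps orientation a pure function of the cycle.
* **Stack matching** is exact over all 4! assignments; ties take the
  lexicographically smallest permutation.  Steps joined only by relaxed
  sequential adjacency (no contacts at all) fall back to the assignment
  minimizing total index distance.
* **Non-monotone tracts** leave the direction undetermined: the
  quadruplex is reported with letter and sign but direction `?`, with a
  warning, rather than guessing.
* **Dot-bracket.** Each tetrad contributes (A,B) and (C,D) to line 1 and
  (B,C) and (D,A) to line 2 — a 4-cycle cannot sit on one line.  The
  split is a fixed convention of this package (any fixed split with a
  documented parse-back is unambiguous); bracket levels are assigned by
  greedy interval colouring in 5′ order over the alphabet `()`, `[]`,
  `{}`, `<>`, `Aa`–`Zz`, and chain breaks appear as `-` in all three
  lines.  Parsing the two lines recovers the encoded pair multiset
  exactly; this round trip is asserted throughout the test suite.
* **Rendering** writes SVG with fixed number formats and no timestamps:
  identical input gives byte-identical files.
* **Multi-model files** use model 1 unless `model =` says otherwise — the
  ensemble-versus-first question is open in the method; first-model is
  the common annotator default and keeps results deterministic.
* Whether a *default-mode* tetrad should require some minimum number of
  cis W/H pairs is likewise open; we accept any pair chemistry (the
  preference order still favours cycles richer in cis W/H pairs when
  candidates overlap) and expose `strict` for the conservative reading.

## The synthetic generators

Fixtures are generated at the annotation-graph level, so classification
logic is tested independently of geometry; a separate set of
rigid-geometry coordinate models (idealized planar bases placed by
deterministic optimization of hydrogen-bond distances) exercises the
geometric annotator.

* `make_tetrad_graph(onz, chains)` lays four residues out in the
  arrangement defining the requested class with the cycle pairs directed
  W→H, plus seeded unpaired spacers (which cannot affect the class).  For
  2 chains the split point between strands is chosen per class so that
  the reordering objective provably recovers the requested class — e.g.
  Z− splits 3 + 1 because the alternative order then yields Z+ (neither O
  nor N), letting the lexicographic tie-break pick the Z− order; the
  2 + 2 split used for O and N targets would instead hand N+ fixtures to
  Z−-producing orders or vice versa.  The file chain order is adversarial
  (the non-target order), so these fixtures genuinely exercise
  reordering.  With 4 chains (one residue per strand) *every* cycle
  admits an O-yielding permutation, so the post-reordering truth is
  always O with the requested sign (strand naming fixes the sign); the
  requested N/Z class is then realized only under the identity
  arrangement.  The generator returns all three ground truths (identity,
  reordered, no-reorder).
* `make_quadruplex_graph(letter, direction, sign, n_tetrads)` builds four
  tract blocks on one chain, realizes the letter by the cycle's routing
  across the blocks, the sign by the cycle direction, and the direction
  (p/a/h) by running 0, 2 or 1 tract blocks backwards; consecutive
  tetrads share 4/4 stacking contacts (reducible via
  `contacts_per_step`).  Defaults — three tetrads, 1–3-residue loops,
  guanine quartets — mirror the common deposited G4 architecture.
* `make_multimer_graph()` is a synthetic analogue of an eight-strand
  DNA/RNA hybrid assembly: two tetramolecular quadruplexes of five
  tetrads each, with per-tetrad signs, under an adversarial file chain
  order.

What the generators emulate is the *topology* of real motifs: pair edges,
cycle directions, stacking adjacency, strand partitions.  What they do
not emulate: experimental coordinate noise, non-planar or partially
resolved quartets, modified-base chemistry in the pair table, loops
long enough to pair internally, or annotator disagreement on borderline
contacts.  Passing the generator grid therefore certifies the
classification logic, not the geometric annotation of difficult
experimental structures — the coordinate fixtures cover the annotator's
criteria, but only under idealized geometry.

## Problem sizes in the test suite

The suite compares the tetrad finder against a brute-force
disjoint-4-cycle oracle on 200 seeded random graphs of 9–12 residues,
the stack matcher against exhaustive assignment enumeration on 200 random
4×4 contact matrices, runs the full 6 × {1, 2, 4} tetrad grid and the
36-combination quadruplex grid end to end, checks reordering
monotonicity on 100 seeded multimeric fixtures, and analyses the
eight-strand assembly once (40 320 permutations).  These sizes keep each
property's search space exhaustively checkable while the whole suite
runs in about a minute.

## Known limitations

* The N4-helix label is a heuristic: a component is flagged when two of
  its tetrads share no chain (independent quadruplexes stacked
  coaxially).  A single-chain coaxial stack of two quadruplex units is
  not flagged.  The label is reporting-only; classification always
  applies to the assembled component.
* Pentads, hexads and triads are out of scope, as are loop-type
  annotation, groove widths, and thermodynamic or sequence-based
  quadruplex prediction.
* Crystallographic symmetry mates are not generated; supply an annotation
  computed on the expanded assembly if the motif crosses the asymmetric
  unit.
* The whole-database census that motivates the O-first reordering
  objective is not reproducible offline; the package ships the synthetic
  analogues above instead.
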