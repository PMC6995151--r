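# quadtet

Identification and classification of tetrads and quadruplexes in nucleic
acid 3D structures.

## The problem

Quadruplexes are four-stranded nucleic-acid motifs found in telomeres,
promoters and many regulatory regions.  Their building block is the
**tetrad** (quartet): four nucleotides in one plane, each pairing with its
two neighbours — one contact along the Watson–Crick edge, one along the
Hoogsteen edge — so that the four base pairs close a 4-cycle.  Two or more
tetrads stacked ~3.3 Å apart form a quadruplex.  Most computational work
on these motifs targets canonical all-guanine G4s at the sequence or
tertiary-structure level; this package instead classifies tetrads and
quadruplexes by their **secondary-structure topology**, which covers
non-canonical chemistry and mixed-base quartets as well.

## The classification

Orient a tetrad so that residue **A** is its 5′-most member and the pairs
run (A,B), (B,C), (C,D), (D,A), the first residue of each pair binding
through its Watson–Crick edge and the second through its Hoogsteen edge.
The 5′→3′ arrangement of the four residues then decides the class:

| arrangement | class | | arrangement | class |
|---|---|---|---|---|
| 5′-A-B-C-D-3′ | **O+** | | 5′-A-D-C-B-3′ | **O−** |
| 5′-A-B-D-C-3′ | **N+** | | 5′-A-C-D-B-3′ | **N−** |
| 5′-A-C-B-D-3′ | **Z+** | | 5′-A-D-B-C-3′ | **Z−** |

The letters name the O-, N- or Z-shaped track the pairings trace in an arc
diagram; the sign records the cycle direction relative to the sequence.
The six permutations of B, C, D are exhaustive, so every oriented tetrad
receives exactly one label.

A quadruplex (a stack of ≥ 2 tetrads) receives an **ONZM** class: the
common tetrad letter (or **M** for mixed), the strand progression of its
four tracts — **p**arallel (all four tracts run the same way),
**a**ntiparallel (2 vs 2) or **h**ybrid (1 vs 3) — and a subtype sign:
`+` or `−` when all tetrads agree, `*` for a mixture.  Quadruplexes
containing unclassifiable tetrads fall into class **R**.

Because the classification follows the 5′→3′ direction, multimeric
(bi-/tetramolecular) motifs depend on the processing order of their
strands.  The package examines every permutation of the participating
chains and commits the one maximizing the number of O-class tetrads
(O-type tetrads dominate observed structures); with `no_reorder = TRUE`
the input order is kept and multimeric tetrads stay unclassified.

## Worked example

Inputs can be a PDB/mmCIF file, a DSSR-style JSON annotation, or an
annotation graph built in code.  The bundled generator creates graphs with
known ground truth — here an antiparallel stack of three O-tetrads with
mixed signs:

```r
library(quadtet)
fx <- make_quadruplex_graph("O", "a", "*", n_tetrads = 3)
qa <- quadruplex_analysis(fx$graph)
summary(qa)
#> Quadruplex analysis summary
#> ===========================
#> Residues: 18  pairs: 12  stacking contacts: 8
#> Committed chain order: A
#>
#> Tetrads (3):
#>   A.G1 A.G18 A.G11 A.G8 -> O-
#>   A.G2 A.G7 A.G12 A.G17 -> O+
#>   A.G3 A.G6 A.G13 A.G16 -> O+
#>
#> Quadruplexes (1):
#>   class Oa*: 3 tetrads [O- O+ O+]
#>
#> Dot-bracket:
#> GGGUUGGGUUGGGUUGGG
#> (((..))(..)((..)))
#> ([[..[[)..(]]..]])
```

Reading the output: the three tetrads are listed with their residues in
(A,B,C,D) orientation and ONZ class; the single quadruplex combines one
O− and two O+ tetrads on four tracts of which two run backwards, hence
class `Oa*`.  The two bracket lines below the sequence encode each
tetrad's 4-cycle — line 1 carries pairs (A,B) and (C,D), line 2 carries
(B,C) and (D,A); parsing both lines back recovers the pair set exactly.

`plot(qa)` draws the arc diagram (O is blue, N green, Z orange; dark for
`+`, light for `−`, grey for unclassified) and
`render_arc_svg(qa, "diagram.svg")` writes the same picture as
deterministic SVG.  `report_text()` / `report_json()` produce the full
reports.

A command-line wrapper is installed with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","quadtet.R",package="quadtet"))')" \
    --pdb structure.cif --stacking-mismatch 1 --complete-2d --output out/
```

with flags `--pdb`, `--dssr-json`, `--stacking-mismatch {0,1,2}`,
`--relaxed-stem-definition`, `--strict`, `--no-reorder`, `--complete-2d`,
`--output`, `--model`, `--config` (palette override).

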