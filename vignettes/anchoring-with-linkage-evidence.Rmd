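---
title: "Anchoring scaffolds with linkage-map, long-read, and BAC evidence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Anchoring scaffolds with linkage-map, long-read, and BAC evidence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(linkanchor)
```

## The procedure and its assumptions

`linkanchor` builds chromosome-scale pseudomolecules from an assembly
whose scaffolds are unordered, unoriented, and unassigned. The model of
the data is deliberately simple and mirrors how such evidence is actually
produced:

* **Markers.** A genetic map provides, for each marker, a linkage group
  and a centimorgan position. Marker sequences aligned to scaffolds
  (PAF) yield at most one placement per marker: alignments are filtered
  by mapping quality and identity, the single highest-scoring hit wins,
  and score ties drop the marker entirely. The tie-drop is the package's
  repeat defense — a marker that aligns equally well twice is precisely
  the kind of marker that creates false joins. The placement coordinate
  is the target-interval midpoint, which makes strand bookkeeping
  irrelevant for markers that are short relative to scaffolds.
* **Assignment** is by plurality: a scaffold joins the linkage group
  carrying the largest share of its markers if that share is at least
  `min_fraction` (0.6) and the scaffold carries at least `min_markers`
  (2). Both thresholds exist so that a single stray marker can never
  anchor a scaffold; both are exposed in `anchor_config()`.
* **Order and orientation.** Within a linkage group, scaffolds sort by
  the median cM of their on-group markers. Orientation is the sign of
  the Spearman rank correlation between scaffold coordinate and map
  position. Rank (rather than linear) correlation is used because the
  cM/bp relationship need not be uniform — recombination varies along a
  chromosome — while monotonicity is exactly what orientation needs.
  The underlying assumption is marker-map collinearity: within one
  scaffold, physical and genetic order agree up to noise.
* **Overhanging reads.** A long read supports a scaffold end when its
  alignment reaches within `max_end_dist` (500 bp) of the terminus and
  at least `min_overhang` (150 bp) of the read extends unaligned beyond
  it. A read with such terminal alignments on exactly two scaffolds is
  split-read evidence that the two ends are adjacent; reads implicating
  three or more scaffolds are treated as unreliable and discarded. Links
  need `min_reads` (3) distinct supporting reads. The end-distance
  tolerance absorbs ragged scaffold termini; the multi-read requirement
  absorbs chimeric reads.
* **Concordance.** All evidence lands in one graph whose nodes are
  scaffold *ends* (two per scaffold) and whose edges carry a source tag:
  `long_read`, `bac`, or `marker_adjacency` (the facing ends of
  map-consecutive scaffolds). Per scaffold pair, agreeing end-pairings
  from two or more sources are *concordant*, one source is
  *single-source*, and incompatible end-pairings are *conflicting*.
* **Authority.** Marker order is never overridden: end links only insert
  scaffolds that have no map position, each on the linked side of its
  partner, oriented so the linking end faces it, and only when the
  scaffold has exactly one non-conflicting long-read link to one placed
  scaffold. BAC links participate in concordance classification but
  never trigger insertion — in the kind of dataset this package targets,
  BAC end evidence proved much noisier than read overlaps, so it is
  used as a cross-check rather than a constructor.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `min_mapq` | 0 | Phred | marker alignment mapping-quality floor |
| `min_identity` | 0.9 | fraction | marker `n_match/aln_len` floor |
| `min_fraction` | 0.6 | fraction | LG plurality required for assignment |
| `min_markers` | 2 | count | markers required for assignment |
| `max_end_dist` | 500 | bp | alignment-to-terminus tolerance |
| `min_overhang` | 150 | bp | unaligned read extension past a terminus |
| `min_reads` | 3 | count | distinct reads per end link |
| `gap_length` | 100 | bp | N gap between joined scaffolds (NCBI convention for unknown gaps) |

`min_mapq` defaults to 0 because the simulator emits ideal alignments;
with real aligner output a floor of 30–40 is reasonable. Whether marker
alignments should be MAPQ-filtered before graph construction is genuinely
open — repetitive markers are already handled by the best-hit tie-drop —
so the knob exists rather than a hard-coded answer.

## Determinism

Equal inputs give byte-identical outputs regardless of row order: links
are canonicalized lexicographically, ordering ties fall back to
longer-scaffold-first then name, and a zero orientation score (typically
a single usable marker) is placed `+` and flagged rather than left to
chance. These rules are arbitrary where the evidence is genuinely silent,
but they are fixed and documented, which is what reproducibility needs.

## The synthetic data and what it does (not) show

The simulator emulates the study-like conditions the pipeline targets:
seven linkage groups of 200 kb at GC 0.36, markers every ~5 kb on a
linear 0.02 cM/kb map, fragmentation into ≥5 kb scaffolds with random
orientations and shuffled names, 10 kb reads centered on junctions (five
per junction plus background reads), and mate pairs with 100 ± 10 kb
inserts. Truth PAF alignments are emitted directly, so no aligner runs in
the tests; an externally produced PAF drops in identically. Map noise is
modeled as Gaussian cM jitter (sd 0.5 cM on a random 10% of markers).

Chromosome lengths are scaled down by roughly two orders of magnitude
from a real genome so the whole suite runs in minutes on one CPU; the
geometry that matters (markers per scaffold, junction coverage, insert
versus fragment size) is preserved. What passing tests show: the
bookkeeping — coordinate conventions, strand logic, canonicalization,
ordering, insertion geometry, stitching — is exact, and ordering is
robust to map jitter much larger than the marker spacing. What they do
not show: robustness to misalignment, chimeric scaffolds (no
misassembly breaking is attempted, by design), structural variation
between the mapped individual and the assembled one, or nonlinear
recombination landscapes. The simulator has no read-error model beyond
uniform substitutions and no diploidy; haplotype purging is accounted
for arithmetically (`purge_accounting()`), not simulated.

## Numerical choices

* Marker position `floor((tstart + tend)/2)`; intervals are 0-based
  half-open in PAF and 1-based inclusive in AGP, with exact converters
  between the two.
* Spearman correlation returning `NA` (zero rank variance) is treated as
  score 0, i.e. orientation unknown → `+` with a flag.
* k-mers are canonicalized against their reverse complement; k is odd by
  default (21) so no k-mer is its own reverse complement. The QV error
  model `E = 1 − (1 − a/t)^(1/k)` inverts the fact that one substitution
  corrupts up to k overlapping k-mers; with zero observed erroneous
  k-mers the QV is reported at a documented cap (99) and flagged rather
  than infinite.
* NG50 is reported as 0 with `ng50_defined = FALSE` when the assembly
  does not reach half the assumed genome size, instead of erroring
  mid-report.
* Half-mapped BAC pairs are a separate count, not forced into the three
  printed categories; this keeps the category sum equal to the pair
  total across assemblies of the same library.
* `summary_ratios()` takes an explicit rounding mode because published
  summary figures mix conventions (some ratios are rounded, some
  floored); hiding one default would silently misreproduce half of them.

## Known limitations

Conflicts between long-read links and marker order are resolved by
fiat in favor of the map; when overridden evidence exists it is visible
in the concordance report but nothing is re-ordered. Insertion handles
one marker-less scaffold per link chain — a chain of two unknown
scaffolds hanging off one placed scaffold stays unplaced. Gap lengths
are a convention (100 bp), not an estimate; no gap-size inference is
attempted from overhang lengths.

## Problem sizes used in the checks

The test suite and the acceptance script run the full pipeline on
7 × 200 kb fixtures (42 scaffolds, ~700 markers), 20 jittered ordering
replicates, a 200 kb / 21-mer QV recovery fixture at substitution rate
1e-4, 100-pair BAC libraries, and 1,000 random length lists for the
contiguity oracle — sizes chosen so each check exercises the full code
path while the suite stays interactive.
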