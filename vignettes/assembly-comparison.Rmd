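---
title: "Comparing assemblies from alignment blocks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing assemblies from alignment blocks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(blockmapr)
```

## The model: an assembly comparison as a set of blocks

`blockmapr` never aligns sequences. Its unit of analysis is the
*alignment block* produced by a reference-based evaluator: a maximal
stretch of similarity with 1-based inclusive coordinates on both axes —
`S1`–`E1` on a reference sequence and `S2`–`E2` on an assembly contig —
plus a percent identity and, in QUAST-style files, free-text comments at
the junctions between consecutive blocks of a contig ("translocation",
"indel: …", "local misassembly", …). The working assumption is that the
aligner has already resolved what matches what; everything the package
reports is interval algebra and bookkeeping over those blocks.

Reversed alignments arrive as `S2 > E2`. Internally every block stores
the *sorted* contig footprint `S3 = min(S2,E2) ≤ E3 = max(S2,E2)`
together with a single orientation flag `rev`. This keeps all length and
interval arithmetic uniform; orientation resurfaces only in the dotplot,
where a reversed block is drawn with negative slope. Two lengths matter:
`Length` (contig footprint, `E3 − S3 + 1`) and `LenOnChr` (reference
footprint); their difference and ratio (`LenDiff`, `LenExcess`) flag
blocks that gained or lost sequence relative to the reference.

### Related-block counters

For each block, the other blocks on the *same reference sequence* are
partitioned into six mutually exclusive relations of the reference
intervals: `same` (identical endpoints), `larger` (the other strictly
contains the test block), `alternatives` (strictly contained in it),
`ov_left` / `ov_right` (overhanging overlap on either side) and
`unrelated` (disjoint). Exclusivity and exhaustiveness are provable from
the definitions, and the tests verify both against a brute-force
six-predicate oracle on 10^5 random pairs; the counters of a block always
sum to the size of its population.

The counters are computed once, over all imported blocks, *before* any
filtering — a contained block stays contained no matter which subset is
displayed. The population is all blocks of the same reference sequence
regardless of contig; a `scope = "contig"` option restricts it to blocks
of one assembly contig for sensitivity analysis, since the narrower
reading is also defensible. The implementation counts containments with
`IRanges::findOverlaps(type = "within")` and rank queries rather than
pairwise loops; `ov_right` is obtained by subtraction from the population
size, which is safe exactly because the six relations partition it (the
property the oracle test pins down).

### The default filter

Downstream tables use blocks with `Length` strictly greater than 10 000
bases and `n_larger == 0`. The length bound removes alignment noise; the
containment bound removes redundant alternative placements while keeping
the largest representative. Both are user-settable (`--min-len`,
`--keep-larger`); counters are never recomputed on the subset.

### Contiguity and coverage statistics

`N_p`/`L_p` follow the standard definition: sort lengths descending,
take the smallest k whose prefix sum reaches p% of the total; `L_p = k`,
`N_p` is the k-th length. Chromosome coverage is the length of the union
of block reference intervals (`IRanges::reduce`), and gaps are the
maximal complement intervals in `[1, chromosome length]`, so
`covered + Σ gaps = length` is an identity, not an approximation.

Block statistics are tabulated per length category — "longer than t" for
a descending threshold ladder, or bands `(t_i, t_{i+1}]` that partition
the blocks when the lowest threshold is 0. The *genome fraction* of a
category is its share of the **total aligned length of all blocks**, not
of the reference length; this is forced by the convention that the
threshold-0 category prints fraction 1.00. A block is *repeated* when any
of its five overlap counters is positive (`n_unrelated` does not make a
block repeated); a containment-only variant is available via
`repeated_rule = "containment"` since the published wording does not
settle the point.

### Chromosome resolution and contig ordering

Which reference sequences are chromosomes is taken, in order of
precedence, from a user conversion file (declared order and lengths win),
from a stated count (top-n by length), or from a size heuristic: sort by
descending length, keep accepting while the next sequence is *strictly*
larger than 50% of the previously accepted one, stop at the first
failure. The strict boundary and the stop-at-first-failure scan are
deliberate readings of "larger than 50% of the previous one"; the
alternative (skip-and-continue) would make the accepted set depend on
excluded sequences.

Contigs are assigned to the chromosome carrying most of their aligned
bases (ties toward the smaller display index) and ordered by chromosome,
then by leftmost block start. On a collinear assembly this ordering puts
every bubble of the contig-vs-chromosome map on the main diagonal — a
property the tests check on gap-free, event-free scenarios.

## Tunable parameters

| parameter | default | unit | role |
|---|---|---|---|
| `min_length` | 10 000 | bases | default block filter (strictly greater) |
| `require_no_larger` | TRUE | – | drop contained blocks (`n_larger > 0`) |
| `thresholds` | 500k … 0 | bases | category ladder for block statistics |
| `keyword_map` | 3 entries | – | comment substrings → end flags |
| `scope` | "reference" | – | relation-counter population |
| `n_chromosomes` | – | count | explicit chromosome count |
| gradient anchors | 1→white, 0.5→yellow, 0.3→red, 0.15→blue, ≤0.05→black | – | integrity colour scale |

The keyword map defaults to exactly the three published flags
(`translocation`, `indel`, `local misassembly`, matched
case-insensitively as substrings); comments such as "relocation,
inconsistency = 12000" are preserved verbatim but set no flag, which is a
conscious choice — the evaluator vocabulary is open-ended, and a
misassigned flag is worse than an unflagged comment.

## Numerical choices

* **Rounding.** Display integers (average length, blocks per
  contig/reference) round half *away from zero* (`round_half_up`), not
  half-to-even; fractions use 2 decimals, identities and kb-scaled
  N-values 1 decimal. These conventions were calibrated against every
  internally checkable cell of the published category table, and the
  acceptance suite re-derives those cells exactly.
* **Ties.** First/last block of a contig: minimal `S3`, ties to the
  smaller `E3` (mirrored for the last block); contig assignment ties go
  to the smaller chromosome index; all orders use stable sorts, so
  results are permutation-invariant.
* **Degenerate inputs.** A row with `E1 < S1` is counted and skipped, not
  fatal (real evaluator output contains status lines); an empty length
  list yields `(N, L) = (0, 0)` with a warning; intervals beyond the
  chromosome end are clipped with a warning; a chromosome without blocks
  produces a zero row and one full-length gap; integrity is clipped at 1
  when a contig length had to be estimated from block coordinates (such
  rows are flagged `length_estimated`).
* **Junction comments** attach to both flanking alignment rows (right
  comment of the previous, left comment of the next), to a single
  neighbour at file boundaries. This mirrors the fact that a misassembly
  annotation describes the junction, i.e. both block ends.

## Visualisation data layers

Every plot is built from a pure, JSON-serializable data layer; renderers
(ggplot2 → SVG/PNG, or SVG embedded in a self-contained HTML page with a
small pan/zoom script) never alter it. The bubble map aggregates filtered
blocks per (contig, chromosome) cell: total aligned length drives bubble
*area* (linear), and the integrity level — largest block at the cell over
contig length — drives a white→yellow→red→blue→black gradient whose
anchors are configuration, since only the colour ordering is fixed by
convention. Two connector rules coexist deliberately: contig lanes
connect consecutive blocks of a contig that are not contiguous *on the
reference* (that is what an interruption means in a track view), while
the dotplot draws its dotted connector on a discontinuity on *either*
axis, because a contig-side insertion is exactly the "jump between
parallel diagonals" the dotplot exists to show.

## The scenario simulator

`simulate_scenario()` works at the block level — it emits alignment
*files*, never sequences — because the tool under test consumes
alignments, and block-level simulation keeps every expected value exact.
Contigs tile the non-gap portion of each chromosome; events inject the
corresponding structure: an inversion reverses contig coordinates, an
indel splits a block into two reference-adjacent parts offset on the
contig (junction comment "indel"), a translocation merges contigs across
a chromosome boundary (comment "translocation"), a duplication adds a
block strictly contained in a host block, and the gap fraction leaves
reference intervals uncovered. Identities are Gaussian noise clipped to
[80, 100]. The same configuration and seed give byte-identical files.

Defaults describe a small but structured comparison: five chromosomes of
500 kb decaying by 15% (so the 50% guessing rule accepts all five),
20 kb contigs, 5% gap fraction, 5% inversions, 10% indels, 25%
translocation probability per chromosome junction, 3% duplications,
identity 99 ± 0.5%. These rates are in the range a practitioner sees in
a decent short-read assembly of a small genome; they exercise every
annotation path without making any single event dominate.

`expected_tables()` is the independent oracle: it recomputes coverage
per base, counters by explicit pairwise predicates and event flags from
the generator's own labels, sharing no code with the annotate/stats
modules. What passing means — and does not mean: the simulator emulates
the *block structure* of real evaluator output, not its full messiness.
Real QUAST files contain ambiguous placements, fragmented misassembly
vocabularies, unaligned contigs and coordinate quirks the generator does
not model; exact recovery on simulated scenarios validates the interval
algebra and the parsing contracts, not the evaluator itself.

## Problem sizes used by the test suite

The suite checks the classifier oracle on 10^5 random pairs, the N/L and
coverage oracles on 10^3 random instances each (chromosomes up to 10 kb
for the per-base oracle), exact ground-truth recovery on 100 seeded
scenarios of 2–6 chromosomes (≈40–120 blocks each), and one end-to-end
command-line run over 25 chromosomes and >100 000 blocks through import,
all seven tables, all nine plot types and a level-4 report, verifying
that report tables are byte-identical to standalone `calc` output. These
sizes were chosen to exercise the asymptotics (the relation counters and
parsers are all O(n log n) or better per reference sequence) while
keeping the default test run in minutes on one core.

## Known limitations

* Misassembly information comes *only* from evaluator comments; nothing
  is inferred from coordinates, so files without comments yield no end
  flags.
* SAM/PAF ingestion is out of scope; only QUAST-style TSV and nucmer
  `show-coords` tab output are parsed.
* Reference sequences not assembled into chromosomes appear only in the
  excluded-sequence listing and contig-level tables.
* The QUAST summary report is echoed for display, never recomputed, so
  its metrics (e.g. reference-based misassembly counts) are not
  validated by this package.
* Very fragmented assemblies (millions of blocks) will render slowly in
  the HTML plots even though the tables remain fast; the data layers can
  be exported and plotted with other tools.
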