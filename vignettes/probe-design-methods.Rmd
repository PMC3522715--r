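---
title: "Methods: genome-wide similarity classification and FISH probe design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genome-wide similarity classification and FISH probe design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fishprobes)
```

## The problem

A FISH probe is only useful if its hybridization pattern is predictable.
For a query locus, every base falls into one of three classes with respect
to the rest of the genome: unique, globally similar (copies elsewhere in
the genome), or locally repetitive (extra copies, but all inside the query
locus itself). Unique stretches yield conventional single-copy probes.
Globally similar stretches are unusable. Locally repetitive stretches
support a probe class of their own: an amplicon on one repeat copy
hybridizes to every family member inside the locus and nowhere else,
giving a bright, still locus-specific signal. `fishprobes` implements this
classification and both probe-design arms, plus primer design and
reporting.

## Alignment and the bit-score threshold

Similarity is defined by thresholded local alignments of the query against
the unmasked genome. Hits can be supplied as standard 12-column tabular
alignment output, or computed by the built-in aligner: exact
`word_size`-mer seeding (default 16) on both strands, ungapped X-drop
extension along the diagonal (default X = 20, trimmed back to the
maximum-score extent), and a final anchoring step that retracts each hit
end to its outermost run of `word_size` exact matches. Anchoring keeps hit
boundaries from drifting past a repeat's edge on chance matches in the
flanks; the retraction is at most a boundary-collar effect (below). The
scoring scheme is megablast-like (+1/−2) with the published ungapped
Karlin–Altschul parameters for that matrix (λ = 1.28, K = 0.46), so raw
scores convert to bits as (λS − ln K)/ln 2. Hits below `min_bits`
(default 200, user-adjustable) are discarded — at +1/−2 this corresponds
to exact matches shorter than about 109 bp, which are unlikely to produce
efficient probe hybridization. The threshold is inclusive: a hit at
exactly 200.0 bits is kept.

Gapped alignments from external aligners are accepted and used with a
linear interpolation of the query→subject mapping; the built-in aligner
itself is ungapped, which is what makes its hits exactly recomputable and
lets a brute-force scan serve as its oracle.

## Per-base classification

The query's own genomic copy (the *self locus*) is taken from declared
coordinates when the FASTA header carries them (`chrom:start-end`,
1-based inclusive), otherwise from the highest-scoring near-identity hit
(identity ≥ 0.99 covering ≥ 95% of the query). For each query position,
every covering hit maps it to a genomic point; points on the same subject
within `word_size` bases count as one locus, the self locus always counts
once, and the label is then: one locus → UNIQUE; extra loci all fully
inside the self interval → SIMILAR_LOCAL; any extra locus outside, or
straddling the locus border → SIMILAR_GLOBAL. Border-straddling loci are
deliberately counted as external: a probe binding such a site would leak
signal outside the locus. Minus-strand hits count exactly like
plus-strand ones. The computation sweeps the hit-boundary segmentation of
the query and evaluates each segment at its midpoint, which is exact for
ungapped hits.

Seeded alignment cannot resolve repeat boundaries more finely than the
seed length, so all oracle comparisons exclude a *boundary collar* of
`word_size` bases around each truth-label change. Within a collar, a
position may legitimately differ between the pipeline and a per-position
exact-multiplicity count; outside the collars the test suite requires
100% agreement on substitution-free genomes.

## Blocks, repeat families, and probe targets

* **Unique blocks**: maximal UNIQUE runs strictly exceeding
  `min_unique_len` (default 4000 bp — a 4000 bp block is excluded,
  4001 bp included).
* **Similar blocks**: SIMILAR runs merged across gaps of at most
  `max_gap` other-label bases (default 500 bp: smaller than any amplicon,
  larger than typical alignment fraying at repeat edges).
* **Repeat families**: non-self hits mapping entirely inside the self
  locus are translated to query coordinates; intervals joined by an
  alignment or by ≥ 1 bp overlap form families (connected components, so
  copies never directly aligned still share a family transitively).
  Member intervals are trimmed to SIMILAR_LOCAL bases.

Single-copy targets tile each unique block left-to-right with consecutive
amplicons within `[amplicon_min, amplicon_max]` (defaults 1–10 kb,
bracketing long-PCR practice), maximising covered bases; a remainder
shorter than `amplicon_min` stays uncovered at the right edge. The tile
lengths realise the integer-partition optimum (longest first), which the
test suite verifies against direct enumeration.

Repetitive candidate windows slide across each similar block (start
positions and the length grid both stepped by `amplicon_min`/2, plus the
full block length so narrow blocks can be used whole). A window must be
at least 90% SIMILAR_LOCAL and contain no SIMILAR_GLOBAL base at all —
global contamination would break locus specificity, so it is banned
outright rather than thresholded. A window's predicted binding sites are
its own interval plus all members of any family overlapping it by at
least `amplicon_min`/2. Selection is greedy maximum coverage on the union
of binding sites, subject to chosen amplicons not overlapping, stopping
when the best marginal gain drops below `min_gain` (default 500 bp).
Greedy was chosen over exhaustive search for determinism and the
(1 − 1/e) guarantee; on instances whose candidates bind disjoint site
sets it is exact, and the suite compares it against exhaustive subset
enumeration on ≤ 15 candidates. Ties break toward the smaller start, then
the shorter window.

## Restriction screening

Probe templates are destined for cloning with ClaI linkers, so amplicons
must not contain the recognition site `ATCGAT` (palindromic; any IUPAC
site and its reverse complement can be configured). In `verify` mode,
occurrences are only reported. In `enforce` mode (default), every unique
block is cut through the middle of each occurrence and re-tiled — which
shifts, splits, or drops amplicons exactly as space allows (a split
through the site destroys both halves of the recognition sequence without
losing template) — and an affected repetitive window is re-derived inside
the site-free pieces of any similar block, preferring the candidate with
the largest binding gain and, among equals, the longer window. After
enforcement, every emitted amplicon scans clean; the suite asserts zero
occurrences across all fixtures.

## Primer pairs

Each probe target receives one primer pair from the built-in engine.
Candidate 5′ ends lie within `primer_search_margin` (200 bp) of the two
target edges, *inside* the target, so the PCR product — the physical
probe — is always a substring of the restriction-screened interval. The
product length must lie within the configured amplicon limits and within
2 × margin of the target length. Candidates are screened on hard bounds
(length 18–27 nt, Tm 57–63 °C, GC 0.2–0.8, homopolymer runs ≤ 4,
self-complementarity ≤ 8) and scored as |len − 20| + |Tm − 60|; the
chosen pair minimises the summed penalty plus the pair's Tm difference,
with ΔTm ≤ 3 °C and cross-complementarity ≤ 8 as hard constraints, ties
toward the smaller product and then the leftmost forward primer. If no
admissible pair exists the target is re-tiled: repetitive targets fall
back to alternative site-free candidate windows; a target with no
feasible window is dropped and logged. Melting temperatures use unified
nearest-neighbour thermodynamics with duplex initiation terms, the
0.368 (N−1) ln[Na⁺] entropy salt correction, and Tm = ΔH/(ΔS +
R ln(C/4)) at 50 mM monovalent salt and 50 nM primer; the values are
cross-checked in the tests against an independent implementation of the
same published table. Complementarity is scored as the best contiguous
segment of any antiparallel register at +1 per Watson–Crick pair and −1
per mismatch — a raw pair count maximised over registers would exceed any
useful threshold for almost every random primer, so the segment score is
what makes the default threshold of 8 meaningful. Both primers are then
extended 5′ with the lowercase `atcgat` ClaI linker for clone screening;
Tm is computed on the core only, since the linker is unpaired in early
PCR cycles. The engine is pluggable: any implementation honouring the
same contract (product inside the screened target, within the product
range) can stand behind `design_pair()`, and the built-in engine's choice
is verified against exhaustive enumeration at reduced search margins.

The reported probe target is shrunk to the designed product, so the
emitted target, the screened interval, and the amplicon coincide; binding
sites and cumulative binding are recomputed for the final interval.

## Synthetic genomes and oracles

`genome_spec()` describes a genome as ordered segments (unique,
local-repeat copy, global-repeat copy) with per-copy substitution
divergence; `generate_genome()` derives all copies of a family from one
master sequence and emits the genome, the query (the locus substring),
per-base truth labels, and the family intervals. Divergence is
substitutions only — no indels — so truth stays well-defined per base and
the oracles remain exact. The default `ig_like_spec()` geometry (~55 kb:
5/6/8 kb unique blocks, a three-copy 1.5 kb local family at 2%
divergence, a 1 kb global family with one copy inside and two outside)
mimics a locus with long unique flanks around a locally repetitive core.
Repeat-family masters are drawn free of the default forbidden site: a
site shared by every copy of a family would make the family un-probeable
by construction and the fixture would no longer exercise the repetitive
design arm; unique segments keep whatever sites they contain, and a
divergence substitution can still create a site in one copy, so
restriction enforcement is exercised on both arms.

Three independent oracles validate the pipeline: `brute_force_mask()`
(exhaustive window-multiplicity classification — exact for
substitution-free genomes, which is why oracle comparisons use
divergence-0 specs), `in_silico_hybridize()` (full diagonal scan of a
probe against both genome strands for windows ≥ 100 bp at ≥ 85%
identity, echoing the 100–300 base fragments of a labelled probe), and
`brute_force_select()` (exhaustive subset enumeration of the selection
objective).

What passing these tests shows — and what it does not: the synthetic
genomes have uniform base composition, clean repeat boundaries, and no
indels, segmental duplications, or low-complexity sequence. Real genomes
will produce frayed alignment edges, gapped hits, and repeat families
with complex substructure; the classification logic is the same, but
boundary behaviour will be coarser than the word-size collar measured
here, and external megablast-style hits are the recommended input for
production use.

## Numerical and interface choices

* Intervals are 0-based half-open internally and in BED; reports print
  1-based inclusive coordinates (Ensembl style). BED12 target records
  span the union of binding sites with the amplicon as thickStart/End and
  the binding sites as blocks.
* All randomness lives in the simulator and flows through a single seed;
  the design pipeline itself is fully deterministic, and identical
  seed + configuration reproduce every output byte for byte (tabular
  hits print floats losslessly with `%.17g`).
* Degenerate inputs: an all-N genome aligns to nothing (the query is then
  entirely UNIQUE); a query absent from the genome build fails self-locus
  detection with a clear error; blocks shorter than `amplicon_min` and
  targets without feasible primers are dropped and logged, never silently
  discarded — the run report lists every dropped item with its reason.
* Test problem sizes are desk-scale by design: 20–55 kb genomes for the
  seeded validation sweeps, ≤ 15 candidates for exhaustive selection,
  reduced margins for exhaustive primer enumeration. These sizes keep
  every oracle exact and the full validation reproducible in minutes on
  one CPU.

## Known limitations

* The internal aligner is ungapped; indel-containing repeats need an
  external aligner's tabular output.
* Gapped external hits use a linear query→subject interpolation when
  mapping positions, which is approximate inside long gaps.
* A base whose only extra copies partially overlap the locus border is
  classified globally similar by design; other conventions are defensible
  and the rule is isolated in the classifier.
* The primer engine models primer thermodynamics, not secondary-structure
  folding or multiplex cross-compatibility.
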