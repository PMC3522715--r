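# fishprobes

Design of single-copy **and locus-specific repetitive** FISH probes from a
genome-wide similarity screen.

Fluorescence in-situ hybridization (FISH) probes must bind their intended
locus and nothing else. For a query region, `fishprobes` classifies every
base against the whole genome into three classes:

* **unique** — no similarity to any other genomic site (white in the track
  figure);
* **globally similar** — at least one additional copy elsewhere in the
  genome (gray);
* **locally repetitive** — additional copies exist but all of them lie
  inside the query's own locus (cyan).

Single-copy probes are tiled over contiguous unique stretches exceeding
4 kb. The locally repetitive class — useless for conventional single-copy
design — is turned into an asset: a repetitive probe placed on one repeat
copy hybridizes to every copy of its family inside the locus and nowhere
else, so the probe targets are chosen to maximise the **cumulative length
of their binding sites** (greedy maximum coverage, with the classic
1 − 1/e guarantee and an exhaustive oracle for small instances). Every
amplicon is screened for the ClaI site `ATCGAT` (configurable), and a PCR
primer pair with a lowercase 5′ `atcgat` linker is designed for each probe
template by a built-in nearest-neighbour/penalty engine.

The classification is driven by local alignments thresholded at a minimum
**bit score** (200 by default): either parsed from standard 12-column
tabular output of an external aligner, or computed by the package's own
seeded, ungapped X-drop aligner, which doubles as the desk-scale test
oracle. A deterministic synthetic-genome simulator with planted repeat
structure (and exact per-base truth labels) backs the test suite.

## Worked example

```r
library(fishprobes)

sim    <- generate_genome(ig_like_spec(seed = 1))   # ~55 kb synthetic genome
design <- fish_design(sim$query, genome = sim$genome)
design
#> <fish_design> locus (28,700 bp) at min_bits = 200
#>   mask: 23,225 unique / 1,001 globally similar / 4,474 locally repetitive bp
#>   8 single-copy + 1 repetitive probes; 21,079 bp of probe binding 24,306 bp of sequence
#>   9 primer pairs designed; 9 item(s) logged
```

The fixture plants a three-copy 1.5 kb repeat family confined to a 28.7 kb
locus, one repeat family shared with the rest of the genome, and long
unique blocks. The design recovers that structure: 23,225 bp classified
unique, the within-locus family cyan, the shared family gray. Eight
single-copy amplicons (A–H) tile the unique blocks; a single repetitive
amplicon (x) of 1,247 bp covers one repeat copy but binds 4,474 bp of
sequence — the whole family — which is why the probe set's total binding
(24.3 kb) exceeds its physical length (21.1 kb).

```r
dplyr::select(tidy(design), -binding)
#> # A tibble: 9 × 5
#>   kind        label start   end cumulative_binding
#> 1 single_copy A        47  1860               1813
#> 2 single_copy B      1978  4031               2053
#> 3 repetitive  x      5193  6440               4474
#> # …

tidy(design, "primers")[1:2, c("label", "fwd_seq", "product_len")]
#>   label fwd_seq                      product_len
#> 1 A     atcgatCAGCTTGGGTACGCCAGGCC          1813
#> 2 B     atcgatTCAGGCCACGACCCGCTATACA        2053
```

`glance(design)` gives the one-row summary, `autoplot(design)` draws the
white/gray/cyan similarity track with the probes above it, and
`write_results(design, "out/")` exports BED tracks (BED12 with binding
sites as blocks), the amplicon FASTA, the primer TSV, the commented
effective configuration, and a plain-text report (1-based inclusive
coordinates, Ensembl style).

A thin command-line front end is installed with the package:

```sh
cli=$(Rscript -e 'cat(system.file("cli/fishprobes", package = "fishprobes"))')
Rscript "$cli" simulate --seed 1 --out-dir sim
Rscript "$cli" run --query sim/query.fasta --genome sim/genome.fasta --out-dir out
```

Real genomes and precomputed alignments enter through `read_fasta()` and
`parse_tabular_hits()` (`fish_design(query, hits = ...)`); a
`chrom:start-end` FASTA header declares the query's genomic origin.

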