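# pairsuite

Contact-pair extraction and quality control for chromosome conformation
capture (Hi-C / 3C+) sequencing data, in R.

3C+ protocols record the spatial proximity of genomic loci as chimeric DNA
molecules: fragments that were close in the nucleus are ligated, sequenced
in paired-end mode, and aligned locally to the reference, so a single read
pair can carry several alignments. `pairsuite` turns such name-grouped SAM
alignments into deduplicated, quality-controlled lists of genomic **contact
pairs** in the [4DN `.pairs`](https://github.com/4dn-dcic/pairix) text
format, the interchange format between aligners and contact-matrix binning
tools.

The toolchain covers:

* **parse** — extract contacts from chimeric alignments: chains segments
  along each read, collapses readthrough duplicates, *rescues* single
  ligations sequenced as three alignments, classifies sides
  (unique/multi/unmapped), and expands multi-junction *walks* under six
  policies (`mask`, `all`, `5unique`, `5any`, `3unique`, `3any`);
* **flip / sort / merge** — canonical upper-triangular orientation, fully
  deterministic genomic sorting, exact k-way merging of sorted inputs;
* **dedup** — PCR/optical duplicate removal by fixed-radius neighbour
  search (`|Δpos| ≤ r` on both sides, transitive closure), chunked with
  carry-over so results are independent of chunk size, plus **library
  complexity** estimation from the with-replacement sampling model
  `U = C·(1 − e^(−T/C))`;
* **stats / scaling** — pair-type and cis/trans tallies, strand-oriented
  contact-frequency decay `P(s)` in geometric bins, and the **orientation
  convergence distance** that separates ligation by-products from genuine
  contacts; YAML or grep-able TSV output;
* **restrict / phase / filterbycov** — restriction-fragment annotation and
  by-product classification (dangling ends, self-circles, mirror pairs),
  haplotype phasing from suboptimal alignment scores on a combined diploid
  reference, and single-cell coverage filtering;
* **select / sample** — safe predicate-based splitting and seeded random
  subsampling;
* **simulate** — a synthetic 3C+ library generator with complete ground
  truth (pairs, duplicate groups, walks, by-products, haplotypes) that
  writes aligner-style SAM, used throughout the test suite.

## Worked example

Simulate a 20,000-molecule Hi-C library with 30 % PCR duplication, then run
the minimal pipeline (parse → sort → dedup → stats):

```r
library(pairsuite)

cfg <- sim_config(seed = 42,
                  chromosomes = c(chr1 = 1000000L, chr2 = 1000000L),
                  n_molecules = 20000, duplication_rate = 0.3)
lib <- simulate_library(cfg)

res <- parse_pairs(lib$sam, lib$genome$chromsizes, parse_config())
srt <- sort_pairs(res$pairs, res$header)
dd  <- dedup_pairs(srt, res$header, max_mismatch = 3)

dd$stats$complexity
#> library complexity: T = 26022 , U = 20000 , C = 47165

compute_stats(rbind(dd$unique, dd$duplicates, dd$unmapped), res$header)
#> <pairs_stats> total: 26022  mapped: 26022  dups: 6022  cis: 15506  trans: 4494
```

26,022 read pairs survive parsing; dedup removes 6,022 duplicates, exactly
recovering the 20,000 distinct molecules. The complexity estimate (C ≈
47,000) exceeds the simulated pool because this library duplicates
molecules by a Poisson PCR model rather than the uniform resampling the
estimator assumes — on resampled draws the estimator is accurate to well
under 1 % (see the tests). The first records of the deduplicated table:

```
SIM0014030_0  chr1  109  chr1  899372  +  -  UU
SIM0000196_0  chr1  146  chr1  754486  +  -  UU
```

The same pipeline is available from the shell via the installed
`exec/pairsuite` script:

```sh
pairsuite parse -c sim.chrom.sizes sim.sam \
  | pairsuite sort \
  | pairsuite dedup -o nodups.pairs --output-stats dedup.yml
pairsuite stats -o library.stats nodups.pairs
grep "summary/dist_freq_convergence/convergence_dist" library.stats | cut -f2
```

Every command appends its exact argument vector to the `#command:`
provenance trail of the output header.

## Documentation

The methods vignette (`vignettes/pairsuite-methods.Rmd`) describes the
parsing model, the walk policies and reporting frames, the deduplication
and complexity model, the convergence-distance rule, what the simulator
does and does not emulate, and the package's numerical choices. Function
documentation is in the roxygen comments of `R/`.
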