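---
title: "Extracting Hi-C contact pairs: models and methods in pairsuite"
author: "pairsuite authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting Hi-C contact pairs: models and methods in pairsuite}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pairsuite)
```

# The problem

A 3C+ (Hi-C, Micro-C, ...) library is a collection of chimeric DNA
molecules: chromatin is cross-linked, digested, and re-ligated so that
fragments close in the nucleus become covalent neighbours. After paired-end
sequencing and *local* alignment (each mate aligned independently, split
segments reported as supplementary records), the evidence for one molecule
is a name-grouped bundle of alignments. `pairsuite` converts these bundles
into contact pairs — rows of a `.pairs` table with the read id, two genomic
sides `(chrom, pos, strand)` and a two-character pair type — and takes them
through sorting, deduplication and quality control.

The reported position of a side is always the **5' end of the chosen
alignment on the reference** (strand-dependent). This choice is independent
of where the ligation junction falls inside the read and is stable when the
same fragment is observed again through readthrough.

# Parsing chimeric bundles

## Segment chains

For each read side, mapped non-secondary alignments are ordered by their
position along the read (clips count toward read coordinates, so the span
is clip-aware and reported in the original read orientation). Two rules
make the chain deterministic:

* **Overlapping read spans** (two alignments claiming the same read bases)
  keep the higher-mapq alignment, then the longer one, then the 5'-most.
* **Unaligned gaps** longer than `max_inter_align_gap` (default 20 bp)
  become explicit *null segments*: they represent a fragment of the
  molecule that could not be placed. A leading gap gets a null segment too
  — an unmappable 5' fragment changes what the `5any` policy should report.
  A trailing unaligned tail does *not*: 3' tails are most often adapter or
  low-quality sequence, and treating them as phantom fragments would turn
  ordinary pairs into walks. This asymmetry is a deliberate design choice.

Sides are classed per segment: `U` (unique) when `mapq >= min_mapq`
(default 1), `M` (multi-mapped) below it, `N` for null segments. The
pair-type code concatenates the two side classes after orientation
(`N < M < mapped` when a side is not uniquely mapped; genomic order
otherwise), yielding the familiar `UU`, `NU`, `MU`, ... codes, with `R`
marking a rescued side, `W` masked walks and `D` duplicates.

## Readthrough collapse and reporting frames

When the sequenced molecule is shorter than the summed read lengths, both
mates read through the same fragments and the 3' portions of the two chains
duplicate each other. The two chains are assembled into a single
molecule-ordered chain (side 1 as read, then side 2 reversed), and the
longest suffix of side 1 that genomically coincides with the leading
segments of the reversed side-2 chain — same chromosome, opposite SAM
strands, reference spans overlapping by at least 1 bp — is merged, keeping
the side-1 copy on ties.

Every merged segment carries two *reporting frames*: the molecule read
forward (side 1's direction) and backward (side 2's direction). When a pair
`(left, right)` is emitted from the molecule chain, `left` is reported in
the forward frame and `right` in the backward frame, each preferring the
actual coordinates observed by the corresponding mate when both exist. This
makes every emitted junction look exactly like a standalone Hi-C pair (the
two sides "read into" the junction from opposite ends), and makes walks,
readthrough molecules and plain two-alignment pairs mutually consistent:
a molecule with a single junction produces the identical record no matter
which code path or walk policy handled it.

## Rescue

A single ligation is often sequenced as *three* alignments: one mate covers
the junction (5' segment "red", 3' segment "green"), the other mate is
entirely within one fragment ("blue"). If green and blue are two reads of
the same fragment — same chromosome, opposite SAM strands, 5' ends within
`max_molecule_size` (default 750 bp, the typical sequenced molecule size) —
the molecule is a single ligation and the pair (red, blue) is emitted with
the rescued side typed `R`. All three segments must be unique; otherwise,
or when the geometry fails, the molecule is treated as a walk.

## Walk policies

Molecules with two or more junctions ("walks") are reported per
`walk_policy`:

* `mask`: one `WW` record with null coordinates — the molecule is counted
  but not interpreted;
* `all`: one record per adjacent segment pair of the molecule chain, with a
  `walk_pair_index` column carrying the junction ordinal (records of one
  read share its id);
* `5unique` / `3unique`: the 5'-most (3'-most) *unique* segment of each
  read side, reported side-wise; a side without a unique segment becomes a
  null side;
* `5any` / `3any`: the 5'-most (3'-most) segment of each side regardless of
  class, so an unmappable 5' fragment yields a null-unique pair. When one
  side is entirely unmapped and the other holds at least two segments, the
  `*any` policies take both segments from the mapped side (in molecule
  order); the `*unique` policies never pair two segments of one side. The
  behaviour for this one-sided case is underdetermined by the policy names
  alone; this package fixes it as described.

Defaults (`min_mapq = 1`, `max_molecule_size = 750`,
`max_inter_align_gap = 20`, policy `5unique`) are configurable; they were
chosen so that the canonical chimeric-read scenarios behave as documented
and match common practice for short-read Hi-C.

# Sorting and merging

Pairs are first **flipped** so the genomically lower side (chromosome rank
from the chromsizes file, then position) comes first; pairs with a
non-unique side order by class instead, clustering `N*`/`M*` codes.
Flipping swaps chromosomes, positions, strands, pair-type characters and
all per-side extra columns consistently, and is idempotent.

Sorting uses the total key `(rank1, rank2, pos1, pos2, strand1, strand2,
serialized record)` — the final whole-line tie-break makes the order fully
deterministic, so independently produced sorted files are byte-comparable.
The null chromosome `!` ranks last, which pushes unmapped classes to the
end of the file. Merging verifies that all inputs share the chromosome
order and are sorted, and produces output identical to sorting the
concatenation; provenance entries are concatenated in input order.
Sorting is in-memory: the package targets library scales where a pairs
table comfortably fits in RAM (tens of millions of records).

# Duplicate removal and library complexity

PCR and optical duplicates are pairs whose two sides map to (nearly) the
same positions. Two candidate records are neighbours when chromosomes,
strands, and any requested extra columns match and both position
differences are at most `max_mismatch`; duplicate clusters are the
connected components of this relation (transitive closure), computed with a
sorted sliding window over `pos1` — equivalent to a fixed-radius
neighbour search, and checked against a brute-force all-pairs oracle in the
tests. The default radius of 3 bp absorbs the ±1 bp trimming jitter typical
of protocols that amplify before sonication while keeping genuinely
distinct molecules apart; `max_mismatch = 0` is exact matching. Only
records uniquely mapped on both sides (`U`/`R` classes) are candidates;
everything else passes through untouched. Within a cluster the first
record in sort order is kept; the rest are re-typed `DD`.

Input is processed in chunks to bound memory. After each chunk, every
cluster that still has a member within `max_mismatch` of the chunk's
trailing `(chrom1, chrom2, pos1)` key is carried over in full, and a
record's final status is only fixed once its whole cluster has left the
window. Because an edge can only connect records within the radius on
`pos1`, no cross-chunk cluster can be missed, and the output is provably
identical for every chunk size — an invariant the tests exercise down to
`chunk_size = 1`.

Duplicate counts give a library complexity estimate under the standard
model that each read is drawn with replacement from a pool of `C` distinct
molecules, so the expected number of distinct observed molecules after `T`
reads is `U = C(1 − e^{−T/C})`. The estimate inverts this by bracketed
root finding (bracket doubled from `U`, relative tolerance 1e−6 or
better); `U = T` yields the undefined sentinel (`NA`) since the data carry
no evidence of saturation, and `U ≪ T` collapses onto `C ≈ U`. Note the
model assumes uniform resampling: libraries whose duplication is, e.g.,
per-molecule Poisson will be estimated as more complex than their molecule
count, which is the correct answer to the question the model asks.

# Statistics and scaling

`compute_stats()` tallies totals by mapping category, the pair-type
histogram, cis/trans counts and cis counts at separations ≥ 1, 2, 4, 10,
20 and 40 kb (a ladder bracketing the range where by-products live),
per-chromosome-pair counts, the oriented scaling, the convergence distance
and the complexity estimate. Output is a nested mapping, serialized as
YAML or as a flattened `path<TAB>value` table whose `/`-joined key paths
(e.g. `summary/dist_freq_convergence/convergence_dist`) are convenient for
`grep | cut` shell pipelines; both forms round-trip.

**Scaling.** Cis pairs are binned by separation `s = pos2 − pos1` into
geometric bins (default 8 per decade from 10 bp to the longest
chromosome), counted separately for the four strand orientations, and
normalised by bin width. Trans pairs are summarised as an average trans
frequency: the trans count divided by the number of inter-chromosomal
locus pairs `Σ_{i<j} L_i L_j`.

**Orientation convergence distance.** Unligated dangling ends inflate
convergent (`+-`) pairs at short range, self-circles inflate divergent
(`-+`) pairs, and mirror artefacts the same-strand orientations; genuine
contacts are orientation-symmetric. A bin is "similar" when the relative
spread `(max − min)/mean` of its four orientation densities is at most
`rel_tol` (default 0.25), judged only in bins with at least `min_count`
(default 100) pairs — raw counts are multinomially noisy, and a stricter
tolerance would never converge on realistic depths. The convergence
distance is the upper edge of the right-most dissimilar bin: contacts
above it can be interpreted without by-product concern. If no judged bin
is dissimilar the first bin edge is returned; if all are, the curve never
converges (`NA`). The tolerance pair is a declared package decision, and
both knobs are exposed.

# Protocol tools

**Restriction.** `digest_genome()` places fragment boundaries at position 1
and at the first base of every recognition-site match on either strand
(IUPAC codes honoured, palindromes counted once); enzyme-specific cut
offsets within the site would shift all boundaries equally and are left at
0. Annotation locates each side's fragment by binary search and appends
0-based fragment ordinals and bounds; by-product classification then calls
same-fragment pairs `dangling_end` (`+-`), `self_circle` (`-+`) or
`mirror` (same strand), and different-fragment pairs `valid`.

**Phasing.** Reads are assumed mapped against a concatenated diploid
reference whose chromosomes carry haplotype suffixes (`name#0`/`name#1` by
default, separator and suffixes configurable), with suboptimal alignments
reported (column `XB`, entries `chrom,pos,strand,score`). A side resolves
to its best alignment's haplotype unless a suboptimal alignment ties within
`score_tie_margin` (default 0 — only exact ties are ambiguous, appropriate
for deterministic scoring): a tie on the homologous chromosome means the
read covers no distinguishing variant (unresolved, `.`), a tie anywhere
else is a true multi-mapper (`!`), and multi takes precedence when both
occur. A side that ties both within and across base chromosomes is thus
conservatively called multi. Both homologs are treated identically, so
phasing introduces no haplotype bias beyond the variant annotation itself.
After phasing, chromosome names are rewritten to their base form and pairs
re-flipped against the base chromosome order.

**Coverage filtering.** For single-cell libraries, coverage is the number
of pair *sides* per fixed-width bin (default 1000 bp, both sides of every
mapped record counted); records with at least one side in a bin whose
coverage strictly exceeds `max_coverage` are removed in a second pass, so
the result is independent of record order. The threshold has no universal
default and must be set per dataset (copy number × expected per-allele
contacts).

# Selection and sampling

Filter expressions are parsed into an AST and checked against a restricted
grammar — column names, literals, comparisons, `+ - * / abs`, boolean
connectives (with `and`/`or`/`not`/`True`/`False` accepted), `%in%`/`c`,
and `grepl` — then evaluated in an environment containing nothing else, so
no arbitrary code can run on untrusted expressions; programmatic callers
may instead pass a predicate function for full generality. Sampling is
seeded and leaves the caller's RNG state untouched: fraction mode takes an
independent Bernoulli decision per record; count mode draws a uniform
without-replacement index set (implemented with an in-memory draw; the
contract is the distribution and seed determinism, not the streaming
mechanics), preserving input order.

# The simulator

`simulate_library()` emulates the molecule classes the parser must handle,
with complete ground truth, so every stage is testable hermetically:

* single-ligation **contacts** (cis with probability `cis_fraction`,
  default 0.7, separations drawn from `P(s) ∝ s^{−1}` between 500 bp and
  half the chromosome — typical of conventional Hi-C; trans otherwise),
  fragment lengths Normal(250, 50) bp truncated to [50, 2000] as for
  sonicated libraries, 100 bp reads;
* multi-junction **walks** (2–3 junctions) built from short fragments
  (40–70 bp) so reads span the junctions, exercising supplementary-record
  chains and readthrough collapse;
* **by-products**: dangling ends (one fragment read convergently),
  self-circles (divergently), mirror pairs (both reads identical); with a
  `restriction_site` configured their fragments coincide with restriction
  fragments of the simulated genome, so by-product classification can be
  validated against planted labels;
* **PCR duplicates**: per molecule, extra copies are Poisson with mean
  `duplication_rate`, each side independently jittered ±1 bp with
  probability 0.5 — trimming variation, the reason fuzzy matching exists.
  The truth table records each copy's actual coordinates, so the expected
  deduplicated output is computable exactly;
* **diploid mode**: two haplotype copies per chromosome differing at
  Bernoulli(`snv_rate`) positions; each alignment carries an `XB` entry
  for the homologous position whose score is penalised by 4 per covered
  variant, which is what an aligner reports when the read does (not)
  overlap a distinguishing SNV.

Alignments are written directly as a perfect local aligner would — exact
reference spans, soft-clipped CIGARs in SAM orientation, split segments as
supplementary records, mates aligned independently; SEQ/QUAL are omitted
(`*`), since the toolchain operates on coordinates. The simulator does
*not* model sequencing errors, base qualities, indels between haplotypes,
chimeric mapping artefacts or non-uniform genome composition; passing
tests therefore demonstrate the correctness of the extraction logic on
ideal alignments, not robustness to aligner noise on real genomes.

Test problem sizes are the package's own choices: the end-to-end recovery
check uses 10^5 molecules on a 2×2 Mb genome (50 % duplication, 5 % walks,
5 % by-products); convergence recovery uses 20 replicates of 10^5 planted
cis pairs; dedup oracle equivalence uses 50 random instances up to
n = 2000 on a 10 kb genome with radii 0–5; complexity recovery resamples
5×10^4 reads from a 2×10^4-molecule pool. The 2 Mb chromosomes keep
coincidental coordinate collisions (false duplicates) well below the 0.1 %
tolerance while keeping runtimes in seconds to minutes.

# Known limitations

* Tables are processed in memory; external-memory sorting and streaming
  I/O beyond gzip are out of scope, as are pairix/tabix indexing and
  binary columnar storage.
* BAM input is not decoded; convert with `samtools view` first.
* Secondary alignments (flag 0x100) are dropped entirely: chimeric
  segments travel as supplementary records, and the suboptimal-placement
  information phasing needs is taken from `XB`-style tags rather than
  secondary records.
* Multi-contact (Pore-C-style) molecules beyond the walk policies, and
  ligation-site trimming, are not supported.
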