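---
title: "Methods: curation of UCE target-capture data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: curation of UCE target-capture data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ucecurate)
```

This vignette documents the models, parameter choices and numerical
conventions behind each stage of the package. It is the package's own
account of its science; every number shown here is computed by the code at
build time or asserted by the test suite.

## The curation problem

UCE target capture enriches genomic libraries for ultraconserved loci using
a kit of synthetic baits ("probes", named `locus_pN` where `N` indexes the
tile within a locus). Datasets assembled with two different kits cannot be
combined naively: the kits target overlapping locus sets under different
names, recovered loci differ wildly in taxon occupancy, some loci capture
paralogs, and useful off-target ("bycatch") markers such as 28S rDNA and
mitochondrial genes hide in the assemblies. This package implements the
curation computations that bridge raw capture assemblies and an
analysis-ready supermatrix.

## Probe-set blending

**Model.** Two kits, "spider" and "arachnid", are merged so each underlying
locus is represented once. Homology between probes of the two kits is not
documented, so it is inferred operationally: capture contigs from a diverse
taxon panel are matched against both kits, and a contig matching a probe of
each kit is taken as a witness of homology between those probes. Arachnid
probes with at least one homology edge are deleted; the rest are appended
to the spider kit. Spider probes are never removed, and the report obeys
|blended| = |spider| + |arachnid| − |removed|.

**Matcher.** The built-in matcher is a k-mer-seeded, gap-free extension
aligner: exact `seed_word_len`-mers (default 11, the classic nucleotide
search word size) seed diagonals; on each seeded diagonal the
highest-scoring contiguous segment under match +1 / mismatch −2 is the
reported HSP; both strands are searched. Two numerical choices matter:

- *End anchoring.* The best-scoring segment can drag its boundary a few
  bases into unrelated flanking sequence whenever a short lucky match run
  outweighs an interior mismatch. HSP ends are therefore trimmed to the
  outermost runs of ≥ `seed_word_len` consecutive matches, so reported
  boundaries always sit on an exact seed-length match. The chance of a
  spurious 11-base exact run in random flank is 4⁻¹¹ per position,
  negligible at the scales involved.
- *Reporting thresholds.* Defaults `min_identity = 0.80` and
  `min_hit_len = 50` bp. These stand in for the unreported settings of the
  external matcher that the original workflow used; the package also
  imports externally produced 12-column tabular hit files verbatim when
  bit-exact parity with lastz/BLAST output is wanted.

**Granularity.** Removal defaults to per-probe (exactly the matched
arachnid probes are dropped), the literal reading of the rule. A per-locus
mode (drop every probe of any arachnid locus with a matched probe) is
provided because downstream duplicate removal operates per locus; the
locus-level removal set always contains the probe-level one, and this
monotonicity is asserted in the tests. A single witness contig suffices for
an edge — the removal rule keys on *any* hint of homology — so no
minimum-witness threshold exists.

## Locus filtering

**Occupancy.** A locus fails iff it has fewer than `min_taxa` (default 6)
taxa total or fewer than `min_ingroup` (default 3) ingroup taxa. The
comparator is strict ("fewer than"), so the boundary — exactly 6 taxa with
exactly 3 ingroups — passes.

**Long-branch paralogy screen.** Applied only to occupancy passers. The
statistic is the ratio of the longest to the second-longest edge length in
the locus gene tree, with all edges (terminal and internal, root edge
included if present) participating and the tree used exactly as parsed —
no re-rooting, since the original screen filtered whatever its gene-tree
program emitted. A locus fails iff the ratio meets the threshold (default
5). The comparator is *inclusive* (ratio = 5.0 fails): the rule is stated
as "at least 5× longer", and the exclusive alternative is exposed via
`filter_params(inclusive = FALSE)` for users who prefer the other reading.
Zero-length edges participate in the ranking; when the second-longest edge
is zero the ratio is `Inf` and the locus fails — a degenerate tree with a
single long edge is precisely the paralogy signature being screened.

Loci that pass occupancy but carry no gene tree are retained with a logged
warning rather than silently dropped; a missing tree is a bookkeeping
problem, not evidence of paralogy.

## Bycatch mining

**Thresholds.** A hit is retained iff its e-value is strictly below
`evalue_max` (default 10⁻¹⁰) and its aligned (HSP) length strictly exceeds
`min_len` (default 200 bp). The length threshold applies to the match, not
the whole contig: it is the matched gene region being retained. Hits at
exactly the thresholds are rejected, and this boundary behaviour is pinned
by tests.

**E-values.** The built-in engine attaches Karlin–Altschul e-values for
ungapped DNA matches: with raw score $S$ under +1/−2 scoring,
$E = K m n e^{-\lambda S}$ with $\lambda = 1.28$, $K = 0.46$ (the classic
ungapped nucleotide values), $m$ the query length and $n$ the total
database length, and bit score $(\lambda S - \ln K)/\ln 2$. These constants
are documented rather than tuned; the import path is the route to bit-exact
agreement with an external search engine.

**Stitching.** When several contigs of one taxon match disjoint parts of
one gene, their segments are orientation-normalised to the query strand,
laid out by query coordinate, and combined into one sequence spanning from
the first hit's query start to the last hit's query end. Unmatched interior
spans are filled with `N`; where query spans overlap, the higher-bitscore
hit's residues win; identical spans with equal bit scores are resolved
deterministically by contig id (smallest id wins), with a logged message.
Per-sequence curation trims — e.g. deleting a terminal stretch of one
suspect bycatch sequence — are expressed as explicit config entries, never
inferred automatically.

## Supermatrix assembly

**Rotation.** Whole mitochondrial genomes assemble with arbitrary starting
points on the circle. `rotate_to_anchor()` locates a conserved 16S anchor
on either strand of the doubled genome (mismatch-tolerant matching at an
identity floor of 0.8, best = fewest mismatches, ties to the leftmost
start) and cuts the circle so the anchor starts at position 1. The output
is always a cyclic permutation of the input or of its reverse complement,
preserves length and base content, and the operation is idempotent — all
three properties are asserted over random genomes.

**Legacy-parity trimming.** Long bycatch sequences dwarf the short legacy
Sanger sequences for the same markers; to put both on near-equal footing,
alignment ends are trimmed until at least `k_legacy` (default 3) legacy
rows are represented. "Represented" is read *column-wise*: within each
segment, columns are removed from each end up to the first column at which
≥ `k_legacy` legacy rows carry a non-gap character. This is the only
reading that yields a deterministic column cut; a whole-sequence reading
("until 3 legacy sequences survive entirely") would be order-dependent.
Interior columns and rows are never removed, the operation is idempotent,
and segment boundaries (e.g. the mtDNA regions before 16S–ND1, between
16S–ND1 and COI, and after COI) are trimmed independently.

**Manual trims.** Alignment-wide column deletions and per-sequence gap
replacements are config entries in the original 1-based coordinates;
per-sequence trims (coordinate-preserving) apply before column removals.
As an arithmetic check carried by the tests: trimming 1,593 leading and
9,793 trailing columns from an 18,646-column alignment leaves 7,260
columns.

**Concatenation and datasets.** Blocks concatenate over the union of their
taxa, absent cells filled with `?` (PHYLIP/NEXUS convention) or `-`
(FASTA). The partition table follows block order, is 1-based inclusive and
tiles the matrix, so every block can be spliced back out exactly.
`assemble_datasets()` emits the four standard datasets: #1 UCE loci
concatenated (analysed unpartitioned), #2 28S+mtDNA with two named
partitions, #3 the legacy-parity-trimmed version of #2, and #4 = #1 ⊕ #3
(unpartitioned, so no partition file is written for it).

## The synthetic-data generator

The generator emulates the *structure* of a real capture study so that
every stage has a recoverable planted truth:

- `gen_probesets()` builds shared loci from a common ancestral region tiled
  by probes, the arachnid copies mutated at rate `divergence`
  (substitution-only). Paired probes are guaranteed detectable by the
  default matcher up to divergence ≈ 0.15; the test sweeps run at 0.05.
- `gen_contigs()` plants each locus region and each off-target gene
  fragment on its own contig between random flanks, on a random strand,
  recording coordinates. Gene fragments partition the gene contiguously so
  noise-free stitching must reproduce the gene exactly.
- `gen_locus_set()` plants exact filter outcomes: occupancy failures
  violate one of the two occupancy rules; long-branch trees have their
  ratio forced into `[ratio_hi, 2·ratio_hi]` by rescaling one edge, passers
  into `(1, ratio_lo]`. The acceptance-scale design — 1,837 loci over 31
  taxa (22 ingroup) with 511 occupancy failures and 13 long-branch
  failures — mirrors the accounting of the study this workflow supports
  and runs in a few seconds.
- `gen_mito()` cyclically shifts a canonical random genome carrying three
  disjoint gene intervals; the anchor is the start of the 16S interval.
- `gen_mixed_alignment()` makes legacy rows gap-padded windows of the long
  consensus, with the window-start range constrained narrower than the
  window length so all windows mutually overlap. Under that constraint the
  column-scan trim boundary coincides exactly with the order statistics of
  the planted windows (k-th smallest start, k-th largest end), which is
  what the trimming tests assert on 50 random fixtures.

What the generator does **not** emulate: read-level artefacts (quality,
adapters, chimeras), assembly errors, indel variation (noise is
substitution-only by design so planted coordinates stay exact), base
composition and repeat structure of real genomes, and alignment uncertainty
(synthetic "alignments" are constructed, not estimated). Passing tests
therefore demonstrate the correctness of the curation logic under its
stated rules, not robustness to upstream noise sources; with real data the
import paths (hit tables, externally aligned blocks) carry those burdens.

## Problem sizes and determinism

Test and demo sizes are chosen to exercise every code path at desk scale:
the homology sweep uses kits of 4 shared + 2 + 2 loci (2 probes per locus,
120 bp) over 100 seeds; trimming equivalence uses 50 fixtures of 8 long +
5 legacy rows; rotation properties use 100 random genomes of 300–800 bp;
the filter worked example runs at full scale (1,837 loci) since it is
cheap. Every generator takes one integer seed, restores the caller's RNG
state, and is byte-deterministic: identical seeds give identical outputs,
which the pipeline manifest verifies via md5 digests of every output file.

## Known limitations

- The built-in matcher is gap-free; indel-containing homologs are reported
  as multiple HSPs rather than one gapped alignment. For real kits, import
  externally produced hit tables.
- Karlin–Altschul constants are fixed, not estimated from composition, so
  built-in e-values are comparable within a run but not bit-identical to
  BLAST's.
- Alignment itself (and re-alignment of rotated mitochondrial segments) is
  delegated to external tools; the package only splits, dispatches and
  reassembles.
- The blend of the real 15,015-probe and 14,799-probe kits (25,689 blended,
  hence 4,125 removed) requires the proprietary kit FASTA files and a
  many-taxon contig panel; the package reproduces the rule and its
  arithmetic, and verifies the inference on synthetic kits where the truth
  is known.
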