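# ucecurate

Curation tools for ultraconserved-element (UCE) target-capture datasets in
phylogenomics, built around the data-preparation steps that sit between raw
capture assemblies and a concatenated supermatrix ready for maximum-likelihood
analysis:

- **Probe-set blending.** Two bait kits (a spider-specific kit of 15,015
  probes and an older pan-arachnid kit of 14,799) target overlapping but
  non-identical locus sets, and the kits do not document which probes are
  homologous. Capture contigs from a diverse taxon panel are matched against
  both kits; any contig matching a probe from each kit witnesses homology
  between those probes. Arachnid probes with at least one homology edge are
  dropped (duplicate homologs depress recovery because contigs matching two
  probes are discarded downstream as problematic) and the remainder are
  appended to the spider kit, yielding a blended kit in which
  |blended| = |spider| + |arachnid| − |removed|.
- **Two-stage locus filtering.** Loci with fewer than 6 taxa total or fewer
  than 3 ingroup taxa are deleted (occupancy filter); among the survivors,
  loci whose gene tree has a longest branch at least 5× the second-longest
  edge are deleted (a long-branch signature of paralog capture or
  misassembly). The cascade report accounts for every input locus:
  n_input = n_fail_occupancy + n_fail_long_branch + n_retained.
- **Bycatch mining.** Although no bait targets them, 28S rDNA and the
  mitochondrial 16S–ND1 and COI regions are recoverable from capture
  assemblies. Each taxon's contigs form a searchable database queried with
  reference gene sequences; hits are retained iff e-value < 10⁻¹⁰ and
  aligned length > 200 bp (both strict), and multi-contig matches to one
  gene are stitched into a single sequence ordered by query coordinate,
  with interior gaps filled with `N` and overlaps resolved by bit score.
- **Supermatrix assembly.** Circular mitochondrial genomes are rotated so
  they all begin at a conserved 16S anchor; long bycatch sequences are
  trimmed to near-parity with short legacy Sanger sequences (columns are cut
  from each segment end until ≥3 legacy rows are represented at the boundary
  column); hand-curation decisions are applied as explicit config entries;
  and alignment blocks are concatenated into four analysis datasets with
  1-based, tiling partition tables (RAxML and NEXUS dialects).

A synthetic-data generator plants ground truth for every stage — probe
homology pairs, per-locus filter labels, gene fragment coordinates and
strands, rotation offsets, trim boundaries — so the whole pipeline is
testable end-to-end without any external downloads.

## Worked example

```r
library(ucecurate)

# two probe kits with 8 shared loci (2 probes each) and 4 kit-unique loci apiece
ps <- gen_probesets(n_shared = 8, n_spider_only = 4, n_arachnid_only = 4,
                    probes_per_locus = 2, divergence = 0.05, seed = 11)
gc <- gen_contigs(c("panelA", "panelB"), ps$truth, noise_rate = 0, seed = 12)
contigs <- unlist(unname(gc$contigs))

hits_s <- match_probes_to_contigs(contigs, ps$spider)
hits_a <- match_probes_to_contigs(contigs, ps$arachnid)
graph  <- infer_probe_homology(hits_s, hits_a)
graph
#> <homology_graph> 32 edges, 16 spider probes, 16 arachnid probes

blend <- blend_probesets(ps$spider, ps$arachnid, graph)
blend$report
#> <blend_report> spider 24 + arachnid 24 - removed 16 (granularity probe) = blended 32
```

All 16 arachnid probes from the 8 shared loci are recognised as homologous
to spider probes and removed; the 8 probes from arachnid-unique loci are
kept, so the blended kit covers each locus exactly once
(24 + 24 − 16 = 32).

```r
ls  <- gen_locus_set(200, n_taxa = 31, n_ingroup = 22, n_fail_occupancy = 60,
                     n_fail_long_branch = 8, seed = 13)
res <- filter_cascade(ls$loci, filter_params(ingroup_taxa = ls$truth$ingroup_taxa))
res$report
#> <filter_report> input 200 loci; 60 failed occupancy; 8 failed long-branch; 132 retained
```

The per-locus decision table (`res$report$decisions`) records, for each
locus, its taxon and ingroup counts, its branch ratio where a tree was
consulted, and which rule (if any) removed it.

A complete synthetic workspace and a five-stage run
(blend → capture → filter → mine → assemble) are available via:

```r
cfg <- make_demo_workspace("demo_ws", seed = 42)
manifest <- run_pipeline(cfg)
manifest$stages
```

or from the shell with the thin wrapper
`Rscript inst/scripts/uce-curate.R demo --workspace demo_ws` followed by
`Rscript inst/scripts/uce-curate.R run --config demo_ws/config.json`.

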