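Package: ucecurate
Title: Curation of Ultraconserved-Element Target-Capture Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for curating ultraconserved-element (UCE) target-capture
    datasets for phylogenomics: blending two bait kits by inferring probe
    homology from shared contig matches, two-stage locus filtering (taxon and
    ingroup occupancy, then a gene-tree longest/second-longest branch-ratio
    paralogy screen), mining of off-target ("bycatch") loci such as 28S and
    mitochondrial genes from capture assemblies with contig stitching,
    rotation of circular mitochondrial genomes to a shared anchor, trimming
    of long bycatch sequences to parity with short legacy Sanger sequences,
    and supermatrix assembly with partition tables. A synthetic-data
    generator plants ground truth for every stage so the whole pipeline is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
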