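Package: domestiscan
Title: Windowed Selection Scans, Conserved Noncoding Element Discovery and
    Lineage-Specific Substitution Scanning for Domestication Genomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparative and population genomics of domestication.
    Computes windowed nucleotide diversity, Weir-Cockerham FST, per-sample
    heterozygosity, inbreeding coefficients, runs of homozygosity and linkage
    disequilibrium decay from VCF genotypes; calls putative selective-sweep
    regions from joint FST and pi ln-ratio thresholds with a Monte Carlo test
    for the significance of region-set overlaps; identifies conserved
    noncoding elements from focal-referenced multi-species alignments and
    classifies focal-lineage lost and divergent elements with nearest-gene
    assignment and hypergeometric enrichment; and scans reciprocal-best-hit
    one-to-one ortholog sets for focal-lineage-specific amino-acid
    substitutions with conserved flanks. A synthetic-data module generates
    every input format (VCF, MAF, GFF3, FASTA proteomes, population maps)
    with planted ground truth so all stages can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    ape,
    vcfR,
    Biostrings,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
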