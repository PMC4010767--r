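Package: slickmap
Title: Multi-Evidence Fine-Mapping of a Dominant Coat Phenotype from SNP
    Genotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to localize a dominantly inherited phenotype (the
    short, sleek "slick" coat of tropically adapted cattle is the
    motivating case) from dense SNP genotypes by combining several
    independent lines of evidence: kinship-corrected mixed-model
    case/control association with adaptive permutation, EM-based
    linkage-disequilibrium estimation with Gabriel-rule haplotype-block
    detection and per-pattern haplotype association, runs-of-homozygosity
    frequency scanning at multiple run-length thresholds, standardized
    integrated haplotype scores (|iHS|) with windowed averaging, and
    sliding-window identity-by-state consensus haplotype mapping. Evidence
    tracks are integrated into a consensus locus by interval intersection.
    A seeded forward-in-time multi-breed simulator with a planted dominant
    causal haplotype (Balding-Nichols breed divergence, Haldane
    recombination, backcross lineages) makes every stage testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    vcfR,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
biocViews: GenomeWideAssociation, SNP, Genetics, PopulationGenetics
RoxygenNote: 7.3.3
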