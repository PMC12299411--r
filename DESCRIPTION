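Package: popdivscan
Title: Additive-Dominance and Selective-Sweep Scans for Two-Population
    Genetic Divergence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects between-population genetic divergence from SNP genotype
    data with two complementary scans. The first uses the leading principal
    component of a genomic relationship matrix as a surrogate phenotype and
    decomposes per-SNP effects into additive and dominance components by
    nested-model ANOVA under a linear mixed model (an EigenGWAS-style scan
    with additive-dominance orthogonalization). The second combines
    z-normalized per-site Weir-Cockerham F_ST with the log2 ratio of
    nucleotide diversity to flag loci in the joint top tails. Includes VCF
    input/output and quality control, REML variance-component estimation
    under additive plus dominance kinships, set-level comparison of scan
    results, interval-based gene annotation, genotype-phenotype ANOVA
    validation with compact letter displays, and a Balding-Nichols
    two-population simulator with planted divergent and
    heterozygote-excess loci.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vcfR,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    car,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
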