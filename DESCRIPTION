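Package: hapdiver
Title: Haplotype Diversity Analysis for Amplicon Resequencing Panels
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing nucleotide diversity of a single amplicon
    resequenced across a germplasm panel, built around the barley cytokinin
    dehydrogenase gene HvCKX2.1 as the worked system. Calls biallelic SNPs
    from a multiple sequence alignment under a binomial per-base error model
    with two confidence tiers, assigns SNP haplotypes with compatibility
    resolution of partial (missing-data) haplotypes, maps SNPs onto codons by
    brute-force gene-model fitting and arbitrates between alternative
    initiation codons, collapses haplotypes into protein variants, builds
    median-joining haplotype networks, computes a binomial sampling-bias null
    for haplotype absence and chi-squared haplotype-by-phenotype tests, and
    summarises haplotype climate envelopes (monthly precipitation means,
    PCA with 95 percent confidence ellipses). A synthetic-data generator
    produces alignment, population and climate tables with known ground truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    igraph
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
biocViews: Genetics, SNP, VariantDetection, Network, PopulationGenetics
RoxygenNote: 7.3.3
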