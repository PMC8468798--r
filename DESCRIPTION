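Package: coalstep
Title: Stepwise Coalescent Demography and Divergence from ddRAD-Seq
    Site-Frequency Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for reconstructing effective population size through time
    from reduced-representation (ddRAD-seq) genotype data. Implements VCF
    genotype filtering (per-allele depth, site quality, presence, exact
    Hardy-Weinberg screening), genetic sexing of ZW-system birds from
    Z-to-autosome coverage and heterozygosity ratios, nucleotide diversity
    and AMOVA-based Phi-ST divergence statistics, folded and masked site
    frequency spectra, a stepwise time-interval model of effective
    population size fitted by Poisson composite likelihood, two-population
    model selection (isolation with migration, split with migration,
    neutral no divergence), conversion of coalescent-scaled parameters to
    individuals and years, and a coalescent simulator providing ground
    truth for every stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    vcfR,
    ape,
    jsonlite,
    yaml,
    pracma,
    MASS
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
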