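Package: wgiscore
Title: Whole-Genome Instability Scoring from Shallow Whole-Genome Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Copy-number based assessment of homologous recombination
    deficiency (HRD) from shallow whole-genome sequencing (sWGS) of FFPE
    tumour samples. Counts properly-paired reads into fixed genomic windows,
    applies GC-decile normalisation and a within-segment noise index,
    performs penalized optimal-partitioning segmentation with a noise- and
    tumour-fraction-adaptive minimal CNA cutoff, calls large-scale genomic
    alterations (LGAs) and converts them into a whole-genome instability
    (wGI) score. Includes a simplified grid-search tumour-fraction/ploidy
    estimator, in-silico tumour-fraction dilution by binomial count
    thinning, BRCA1/2 variant-status filtering, the combined HRD call,
    diagnostic concordance statistics (PPA/NPA/OPA), cohort summaries, and
    a synthetic-data generator with independent brute-force truth oracles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    Rsamtools,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
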