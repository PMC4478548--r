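Package: polymap
Title: SNP Array Genotype Clustering and F2 Linkage Mapping for
    Allotetraploid Crops
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A desk-scale pipeline for Infinium-style SNP genotyping
    arrays in allotetraploid crops such as cotton: candidate-SNP
    filtering and array content selection, per-marker one-dimensional
    Gaussian-mixture cluster fitting on polar intensity coordinates,
    automated genotype calling with call-frequency and cluster-pattern
    classification (including homeologous "homeo-SNP" markers),
    replicate-similarity and minor-allele-frequency summaries, F2
    linkage-map construction (EM recombination fractions, LOD grouping,
    SARF ordering, Kosambi distances, map cleaning, framework
    reordering), crossover and recombination-bin statistics,
    segregation-distortion tests, and genetic-map versus
    reference-genome synteny analysis with translocation detection.
    Includes a synthetic-data generator that emulates the intensity
    cluster patterns, null-allele call deficits, inbred-panel MAF
    spectra, and F2 populations the analyses assume, so the whole
    pipeline is testable without array data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
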