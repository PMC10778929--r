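Package: cubscape
Title: Intragenic Codon Usage Bias and Local mRNA Folding Landscapes
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Domain-resolved codon usage bias analysis for gene families:
    effective number of codons (Wright's Nc and a pseudocounted Ncw
    variant), Codon Adaptation Index with an expected-CAI (eCAI) null from
    GC-calibrated random synonymous sequences, GC3 and GC content with
    whole-gene percent-difference normalization, sliding-window local
    folding energy deltas (deltaLFE) against synonymous-codon permutation
    nulls with x-intercept and translational ramp detection, synonymous /
    missense variant classification, and a synthetic multi-species homolog
    generator with region-wise codon-bias profiles for end-to-end testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    Rcpp,
    yaml,
    jsonlite,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    seqinr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'AllClasses.R'
    'methods.R'
    'seqio.R'
    'codon-metrics.R'
    'mfold.R'
    'variants.R'
    'synthetic-data.R'
    'pipeline.R'
    'RcppExports.R'
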