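Package: cremap
Title: Mapping Carbon Catabolite Regulator Targets from Two-Channel Expression Arrays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for genome-wide mapping of the target
    range of a carbon catabolite repressor (CreA/CRE1) from two-channel
    microarray chemostat experiments. Implements dye-swap aware pretreatment
    (flag and saturation filtering, background thresholding from 'not found'
    features, global intensity-dependent lowess normalization, probe-to-transcript
    aggregation), empirical-Bayes moderated t-statistics with Benjamini-Hochberg
    control and a log2 magnitude filter, a template-matching / CAST /
    hierarchical cluster-assignment cascade, degenerate IUPAC motif and dyad
    (paired-motif) promoter scanning with genome-normalized enrichment and
    random-control de novo motif discovery, and hypergeometric functional
    category enrichment. A synthetic-data generator with planted ground truth
    makes every stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    BiocGenerics,
    Biostrings,
    IRanges,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    limma,
    mclust
Config/testthat/edition: 3
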