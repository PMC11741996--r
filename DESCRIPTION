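Package: mhcRepertoire
Title: Functional Clustering of MHC Class I Alleles by In Silico Peptide
    Binding Repertoires
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An in silico pipeline for comparing major histocompatibility
    complex (MHC) class I molecules by the viral peptide repertoires they
    are predicted to bind. Digests per-virus proteomes into overlapping
    peptides, scores allele-peptide binding through a pluggable backend
    (a synthetic anchor-motif model is included), self-calibrates
    percentile ranks against a reference peptide pool, calls binders at a
    rank threshold, clusters alleles by the Jaccard similarity of their
    per-virus binder repertoires (UPGMA with virus-subsampled bootstrap
    support and extended majority-rule consensus), computes epitope
    density statistics with group comparisons, and screens for
    sweep-candidate viruses. Synthetic data generators with planted
    family and supertype structure make every stage testable end to end
    without external databases or predictors.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    optparse
Config/testthat/edition: 3
biocViews: Software, SequenceAnalysis, Clustering, Immunology
RoxygenNote: 7.3.3
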