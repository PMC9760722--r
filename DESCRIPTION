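Package: gliprio
Title: Prioritization of Gene-by-Lifestyle Interaction Loci from Summary-Level Multi-Omics Evidence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Summary-statistics pipeline for prioritizing gene-by-lifestyle
    interaction (GLI) loci. Provides a synthetic-cohort generator under the
    linear GLI model, ordinary least squares cohort fitting, inverse-variance
    fixed-effect meta-analysis within and across ancestry groups (with 1df
    interaction and 2df joint tests, Cochran's Q heterogeneity and MAF
    filters), interaction-significance variant screening, 500 kb locus window
    construction around gene exon spans and CpG sites, a multi-omics evidence
    cascade joining differential methylation, eQTM, eQTL and differential
    expression evidence to candidate genes, and reporting utilities that
    summarize tiered locus tables.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    methods,
    GenomicRanges,
    IRanges,
    GenomeInfoDb,
    S4Vectors,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
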