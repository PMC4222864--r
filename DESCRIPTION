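Package: retroprobe
Title: Re-Annotation and Expression Analysis of Retroelement-Reporting Microarray Probes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies microarray probes that report sense transcription of
    endogenous retroelements (LTR elements, LINEs, SINEs) by localizing probe
    sequences on a genome, testing strict containment within repeat-masked
    intervals in the chemistry-appropriate orientation, and attaching
    nearest-gene context. Applies enhanced filtering to isolate probes
    reporting single-integration, intergenic elements, and provides the
    downstream expression statistics: normal-exponential background
    correction, quantile normalization, one-step Tukey biweight probeset
    summarization, blocked ANOVA probe selection, probe-versus-probeset
    concordance testing, and nearest-gene co-regulation regression. Includes a
    deterministic synthetic-data generator producing genomes, repeat and gene
    annotations, platform manifests and expression matrices with known ground
    truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    BiocGenerics,
    limma,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
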