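Package: gstmine
Title: Gene-Family Mining, Annotation and Expression Profiling for De
    Novo Transcriptome Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tested, reusable pipeline for mining gene families (such as
    the glutathione S-transferase superfamily) from de novo transcriptome
    assemblies.  Provides translated homology search of nucleotide contigs
    with protein queries, six-frame ORF extraction with full-length/partial
    completeness classification, reciprocal best-hit annotation against a
    labeled reference panel, domain vetting by position-specific scoring
    matrices, wildcard motif scanning with substitution calls,
    identity/similarity percentages with a region-of-overlap rule for
    partial proteins, cross-assembly ortholog/paralog correspondence, and
    RPKM developmental expression summaries.  Includes a ground-truthed
    synthetic transcriptome generator that plants gene families with
    controlled divergence structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
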