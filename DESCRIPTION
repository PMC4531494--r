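Package: ClonoScope
Title: Clonality and Diversity Analysis of Immune Repertoires from
    Annotated AIRR-Seq Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for characterising immunoglobulin (IG) and T-cell
    receptor (TR) repertoires from per-read V(D)J annotation tables of
    the kind produced by high-throughput alignment portals. Provides
    descriptive functionality statistics, configurable clonotype
    counting (CDR1/CDR2/CDR3 amino acid, CDR3 nucleotide, whole read,
    or V-(D)-J gene combination), rarefaction-based diversity curves
    with a saturation-plus-read-error model fitted by an elitist
    evolution strategy, V-(D)-J gene/allele combination spectra mapped
    onto a germline reference, exact-match multiplex-PCR primer
    efficiency reports, multi-sample clonotype comparison and
    longitudinal tracking, FASTA split/merge preprocessing for portals
    with submission size limits, and a seeded synthetic-repertoire
    generator with full ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'utils.R'
    'AllGenerics.R'
    'AllClasses.R'
    'io-summary.R'
    'io-fasta.R'
    'genecall.R'
    'spectrum.R'
    'simulate.R'
    'repertoire.R'
    'compare.R'
    'primer-match.R'
    'diversity.R'
    'es.R'
    'io-primers.R'
    'cli.R'
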