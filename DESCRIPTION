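Package: bessurvey
Title: BAC-End Sequence Genome Survey Toolkit
Version: 0.1.0
Authors@R: person("BES", "Survey Maintainers", email = "bessurvey@example.org",
                  role = c("aut", "cre"))
Description: Tools for genome surveys built on BAC-end sequences (BES):
    FASTA quality control and end pairing, GC content, perfect
    microsatellite (SSR) mining with motif canonicalization by rotation
    and reverse complement, repeat-annotation accounting and masking,
    gene-content extrapolation from BLAST hits, clone-library coverage
    statistics under the Poisson model, and classification of paired-end
    alignments into microsynteny categories. Includes a synthetic
    genome/library generator with complete truth labels so every stage is
    verifiable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    IRanges,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
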