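Package: asodesign
Title: Allele-Specific Antisense Oligonucleotide Design from RNA
    Secondary-Structure Accessibility
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for designing antisense oligonucleotides (ASOs) that
    discriminate a mutant, exon-skipped transcript from its wild-type
    counterpart. Builds exon-skipped transcript models and the novel
    exon-exon junction, predicts or imports RNA secondary-structure
    ensembles and summarises them as per-nucleotide single-strandedness
    (ss-count) profiles, maps differential accessibility between alleles,
    enumerates junction-straddling gapmer candidates, converts them to
    accessibility-guided mixmers, scans single-nucleotide mismatch
    variants, and annotates every design with GC content, melting
    temperature, DNA-run architecture, off-target hits and
    accessibility-corrected binding scores. Includes the dose-response
    analytics (2^-ddCt fold changes, four-parameter-logistic IC50 fits,
    selectivity indices) used to rank designs, plus seeded synthetic-data
    generators so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
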