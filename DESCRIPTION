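Package: hemescan
Title: Sequence-Based Detection of Transient Heme-Binding Motifs in Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scans protein sequences for candidate transient heme-coordination
    sites (Cys, His, Tyr), extracts the 9-mer motif window around each site,
    computes its net charge, detects cysteine-proline (CP) dipeptides and
    ancillary coordination sites, and assigns each motif to one of eight
    heme-binding-motif (HBM) classes. Candidate sites can be filtered by
    predicted or user-supplied solvent accessibility. Also provides a local
    PROSITE-syntax consensus-pattern matcher, a rule engine that maps UV/Vis,
    resonance-Raman and cwEPR readouts to heme-iron coordination-state calls,
    and a seeded simulator of combinatorial X4(C/H/Y)X4 nonapeptide libraries
    for fixtures and calibration checks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    seqinr,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
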