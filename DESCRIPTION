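Package: mirexapt
Title: Evolutionary Analysis of Intronic MicroRNA Precursors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for deciding whether a candidate hairpin in a host-gene
    intron is a processable microRNA precursor and for tracing its evolutionary
    history across species. Provides secondary-structure prediction under
    configurable energy models with an exhaustive enumeration oracle,
    stem-loop decomposition and annotation against structural and energetic
    criteria (folding energy, paired bases on the main stem, defects in the
    mature arms), homolog location in intron sequences with conservation and
    CpG-island summaries, small-RNA arm-dominance quantification, host/miRNA
    co-expression inference for intragenic promoter activity, promoter
    candidate calling from CAGE, DNase and H3K4me3 tracks, seed-match target
    scoring with GO over-representation, and a deterministic synthetic-data
    generator so every stage is testable with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    stats,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
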