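Package: cgrwalk
Title: Reconstruction and Characterization of Complex Genomic Rearrangements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing complex genomic rearrangements (CGRs) from
    breakpoint-junction calls and copy-number segments: a breakpoint-graph
    model that assembles derivative-chromosome walks (linear or ring) from
    segment dosage and novel adjacencies, a parser and emitter for ISCN-like
    seq[...] g.[...] derivative nomenclature, junction microarchitecture
    classification (microhomology, blunt joins, templated and nontemplated
    insertions) with replicative-mechanism heuristics, trio-based parental
    origin phasing of the rearranged homolog, a minimal read-depth
    copy-number caller, and a synthetic-data generator that emits toy
    references, derivative chromosomes, trio SNV genotypes and binned depth
    profiles with known truth. Bundles the breakpoint tables and derivative
    descriptions of three chromosome 21 rearrangement cases as worked
    examples.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    methods,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
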