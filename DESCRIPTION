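Package: retromorf
Title: Detection of MoRFs and Retro-MoRF Binding Site Candidates in
    Disordered Protein Regions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Screens protein sequences for molecular recognition features
    (MoRFs): short, structure-prone, hydrophobic-rich segments that appear
    as "dips" in a per-residue disorder profile inside otherwise disordered
    regions. Candidate fragments are aligned against a protein database in
    normal and reversed (retro) orientation with a Smith-Waterman local
    aligner, chance similarity is assessed with seeded empirical
    shuffle-based E-values, and each hit is classified with three criteria:
    sequence identity above 60 percent, conserved hydrophobic/charge
    pattern, and a disordered or disorder-flanked context on the target.
    Includes a transparent scale-based disorder profiler, polyproline-II
    (SH3 class I/II) motif finders, helical hydrophobic-moment annotation,
    and a seeded generator of synthetic benchmarks with planted motifs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
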