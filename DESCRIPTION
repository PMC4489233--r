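Package: topoconsensus
Title: Consensus Prediction of Membrane Protein Topology from Multiple Predictors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Combines per-residue topology predictions from several
    membrane-protein topology predictors into a single consensus topology.
    Predictions over the four-letter alphabet S (signal peptide), M
    (membrane helix), i (inside loop) and o (outside loop) are stacked
    into a per-residue voting profile, and the grammar-valid label path
    with the highest geometric-mean profile score is recovered with a
    Viterbi-style dynamic program.  Also provides a sliding-window free
    energy of membrane insertion track over a pluggable hydrophobicity
    scale, benchmark evaluation of predicted against reference topologies
    (segment-overlap correctness, error taxonomy, class confusion
    matrices), seeded synthetic data generation for end-to-end testing,
    and readers and writers for FASTA and tabular topology formats.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
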