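Package: phylorecomb
Title: Detection and Statistics of Gene-Conversion Exchange Among Bacterial
    Phylogroups
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying homologous recombination among bacterial
    phylogroups from grouped multiple-sequence alignments. Detects candidate
    gene-conversion tracts between strain pairs from runs of agreement at
    polymorphic sites with a column-permutation significance test, enumerates
    exchange events at three stringency tiers (all fragments; identical-border
    duplicates merged; at most one event per segment and group pair), tests for
    non-random between-group exchange against a proportional-opportunity null
    via multinomial Monte-Carlo simulation of the Pearson chi-square score, and
    compares inter- versus intra-group exchange frequency. Includes
    neighbor-joining phylogenies (Kimura two-parameter distances, complete
    deletion, bootstrap) with group-level topology congruence classification,
    and a synthetic-panel generator that plants conversion tracts with known
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    ape,
    jsonlite,
    Biostrings,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
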