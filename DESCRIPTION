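Package: unicityr
Title: Peptide Unicity Mapping and Proteomics Evidence Integration for
    Curated Proteomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for integrating mass-spectrometry proteomics evidence
    into an expertly curated proteome. Builds an isoform-, variant- and
    processing-aware table of theoretical tryptic peptides (a "unicity"
    table) to decide whether an observed peptide identifies a single
    protein unambiguously; filters peptide-spectrum matches by Mascot
    score, posterior error probability and PTM localization score
    (Ascore); enforces biological-relevance rules such as the exclusion
    of phosphorylation sites inside transmembrane regions; and merges
    accepted sites into canonical-coordinate annotations carrying the
    ECO:0000244 evidence code. Includes a synthetic-fixture generator
    with planted ground truth so the whole pipeline is testable without
    external data, and a command-line entry point for end-to-end runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
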