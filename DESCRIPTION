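Package: allerscreen
Title: Allergen Database Screening, Record Triage and Curated Release Tools
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Toolkit for sequence-based allergenicity screening against a
    curated allergen database, following FAO/WHO and Codex Alimentarius
    guidance. Implements exact Smith-Waterman local alignment with affine
    gaps, full-length database search with Karlin-Altschul E-values, the
    80-amino-acid sliding-window identity rule (hit when identity exceeds
    35 percent over at least 80 aligned columns), and exact 8-mer peptide
    matching via a k-mer index. Also provides a configurable keyword rule
    engine for triaging annotated protein records into allergen candidates,
    entry validation against peer-review inclusion criteria, versioned
    database releases with diffs and transparency exports, deterministic
    synthetic fixtures for testing, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    Biostrings,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
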