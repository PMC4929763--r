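Package: crispex
Title: CRISPR/Cas9 Target Design with Genome-Wide Specificity and
    Restriction-Site Screening
Version: 0.1.0
Authors@R:
    person("crispex", "maintainers", email = "crispex@example.org",
           role = c("aut", "cre"))
Description: Enumerates 23-nt CRISPR/Cas9 candidate targets (20-nt
    protospacer plus 3-nt PAM) in query sequences on both strands, filters
    them for genome-wide specificity against a user-supplied background
    genome with a two-level mismatch/seed-uniqueness test, annotates
    restriction-enzyme recognition sites overlapping the predicted Cas9
    cleavage position for PCR-digest mutant screening, and writes
    per-target CSV reports with per-gene summary statistics. Includes a
    brute-force off-target search oracle and a synthetic-genome generator
    with planted target structures for fully offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
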