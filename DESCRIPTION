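Package: biopepsim
Title: Bioactive Peptide Profiling and In Silico Proteolysis of Protein Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Profiles protein sequences against a dictionary of known
    bioactive peptides (ACE-inhibitory, DPP-IV-inhibitory, antioxidant and
    related activity classes), reporting per-activity occurrence counts and
    occurrence frequencies A = a/N. Simulates enzymatic hydrolysis with a
    declarative protease cleavage-rule engine (P1/P1' specificity sets with
    exception pairs), supporting single and combined enzyme action, missed
    cleavages, and exact-match release of active fragments. Includes the
    supporting proteomics arithmetic (monoisotopic peptide masses,
    charge-state m/z, b/y fragment-ion ladders, sequence coverage) and
    seeded generators for synthetic proteins with planted motifs and known
    cleavage sites, so every stage is testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
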