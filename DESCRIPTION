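Package: bamanno
Title: Biotransformation-Based Annotation of MS/MS Suspect Spectra
Version: 0.1.0
Authors@R:
    person("bamanno", "developers", email = "bamanno@example.org",
           role = c("aut", "cre"))
Description: Annotates unknown MS/MS query spectra by biotransformation-based
    annotation (BAM): a spectrally similar annotated "anchor" molecule is found
    through molecular networking with modified cosine similarity, biotransformation
    rules whose mass delta matches the observed precursor mass difference are
    applied to the anchor to enumerate candidate "suspect" structures, and the
    candidates are ranked by the site-of-metabolism likelihood of the atom each
    rule was applied to. Includes PROXIMAL2-style rule extraction from
    reactant-product structure pairs via maximum common substructure alignment,
    a mass-delta indexed rule table, average-rank tie handling, evaluation
    metrics (recall, rank-at-k), a seeded synthetic benchmark generator, and a
    command-line interface. Chemistry primitives are computed through a bundled
    RDKit bridge (requires a Python 3 interpreter with RDKit on the PATH).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
SystemRequirements: Python (>= 3.8) with RDKit
Imports:
    igraph,
    jsonlite,
    optparse,
    stats,
    tools,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
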