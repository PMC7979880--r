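Package: derivnet
Title: Expansion of Biosynthetic Pathways to Natural Product Derivatives
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rule-based expansion of the biochemical vicinity of a heterologous
    biosynthetic pathway. Generalized bidirectional enzymatic reaction rules are
    applied iteratively to pathway metabolites to build a generation-indexed
    reaction network restricted to catalogued compounds; candidate derivatives
    are trimmed to a benzylisoquinoline elemental scaffold, ranked by literature
    popularity (citations plus patents), connected to pathway intermediates by
    constrained linear pathway enumeration, and matched to enzyme candidates by
    reactive-site-centred reaction fingerprints scored against a reference
    reaction database. Ships a self-contained noscapine pathway fixture (17
    metabolites, 17 reactions, 11 rule classes) so the complete workflow runs
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    igraph,
    jsonlite,
    yaml,
    optparse,
    utils,
    stats
Suggests:
    testthat (>= 3.0.0),
    xml2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
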