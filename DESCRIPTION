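Package: cfig
Title: Critical Functional Ingredient Group Selection by Quantitative
    Network Pharmacology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative network pharmacology of multi-ingredient
    herbal preparations. Builds weighted disease gene regulatory networks from
    literature-evidence tables, filters candidate ingredients by ADME criteria
    (Caco-2 permeability and drug-likeness), constructs ingredient-target
    bipartite networks, scores nodes with a betweenness-derived importance
    measure (Nim) combined with a community-proximity factor, extracts the
    functional response space of key response proteins, validates it by
    hypergeometric enrichment coverage against un-optimized effective targets,
    and selects the critical functional ingredients group by greedy
    marginal-coverage (ICP) ranking. Includes a synthetic-study generator with
    planted critical ingredients so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
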