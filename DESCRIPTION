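Package: sbotagger
Title: Automated Systems Biology Ontology Term Assignment for SBML
    Metabolic Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Assigns Systems Biology Ontology (SBO) terms to the entities of
    constraint-based metabolic models in SBML Level 3 (with the
    flux-balance-constraints extension). Reactions are triaged into
    pseudo-reactions (exchange, demand, sink, biomass), transport reactions
    and biochemical reactions; transport reactions are sub-classified by
    mechanism (passive, ATP- or PEP-driven active transport, symport,
    antiport); biochemical reactions are resolved to precise terms through an
    Enzyme Commission (EC) number mapping store and the SBO is-a hierarchy.
    Metabolites, genes and enzymatic modifiers receive appropriate terms, the
    annotated model is written back to SBML, and a coverage report summarises
    term specificity. Includes a deterministic fixture generator for
    miniature BiGG-style models and an optional client for back-filling EC
    numbers from the BiGG Models web API.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    xml2
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
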