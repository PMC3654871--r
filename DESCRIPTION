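Package: meshopr
Title: Literature Over-Representation Profiles for Drug-Disease Association Ranking
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds quantitative term-enrichment profiles (MeSH
    over-representation profiles) for drugs and diseases from an annotated
    literature corpus, scores candidate drug-disease associations with a
    panel of profile-similarity metrics, removes literature-annotation bias
    with an empirical peer-window significance correction, and validates
    rankings by temporal-split and reference-collection ROC analysis. A
    synthetic corpus generator with planted drug-disease links makes the
    whole pipeline testable without access to MEDLINE.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
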