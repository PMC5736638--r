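Package: infosig
Title: Prioritization of Informative Gene Signatures and Their Redundancy Network
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Scores gene signatures for overdispersion and coordination by
    principal component analysis restricted to the signature genes, with
    empirical null distributions built from random gene sets of equal size
    and Benjamini-Hochberg correction per dataset. Signatures that are
    simultaneously overdispersed and coordinated in at least two expression
    datasets are classified informative. The package also quantifies
    cross-dataset conservation of signature eigengenes, compositional
    (Jaccard) versus functional (metasample-correlation) redundancy between
    signature pairs, builds the weighted signature redundancy network with
    exports to GraphML, SIF and JSON, performs two-group differential
    activity analysis, and generates synthetic multi-dataset expression
    compendia with planted modules for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    igraph,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
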