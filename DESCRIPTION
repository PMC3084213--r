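Package: cincat
Title: Integration and Cross-Species Analysis of Chromosome Instability Gene Screens
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for building a confidence-scored catalogue of chromosome
    instability (CIN) genes from heterogeneous marker-loss screens in budding
    yeast (CTF, ALF, GCR, BiM, LOH), testing Gene Ontology term
    over-representation against a screened-gene background with an exact
    hypergeometric tail and Bonferroni control, projecting the catalogue onto
    human candidate gene lists by orthology and by membership in strongly
    enriched terms, cross-referencing candidates with somatic-mutation gene
    tables via a two-proportion z-test, and clustering genetic-interaction
    (SGA) profiles by average linkage on correlation distance. A seeded
    synthetic-data generator with planted ground truth makes every stage
    testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
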