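Package: pedunite
Title: Merge, Edit and Reconcile Pedigrees Collected from Multiple Informants
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for unifying family pedigrees collected independently from
    several informants of the same extended family. Provides an in-memory
    pedigree model with sublineage (descendant subtree) extraction and
    structural validation; readers and writers for a tab-delimited
    configuration/pedigree/metadata file trio plus LINKAGE PED and Graphviz
    DOT export; field-level provenance tracking so every attribute value can
    be traced to its source file or manual edit; three merge algorithms
    (replacement, combination, addition) with duplicate elimination and
    destination-precedence conflict resolution; individual-level comparison,
    reconciliation and editing; a synthetic-pedigree simulator that emulates
    multi-informant collection with controlled omissions and discordances;
    and a batch command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
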