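Package: korefnet
Title: Reference Pathway Networks for Non-Model Organisms from EST Homology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Annotates expressed sequence tags (ESTs) of non-model organisms
    with KEGG Orthology (KO) groups by thresholded best-hit selection over
    BLAST tabular output against annotated model organisms, parses KGML
    pathway maps into graph objects, projects KO-annotated queries onto the
    maps to build highlighted reference pathway and regulatory networks
    (SIF, GraphML, TSV and annotated KGML exports), computes pathway
    coverage statistics, and scores annotation accuracy with a
    leave-one-organism-out benchmark. Includes a seeded synthetic-world
    generator (gene families, EST fragments, hit tables, KGML maps) so the
    whole pipeline is testable without external databases.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
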