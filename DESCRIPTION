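Package: mcrkit
Title: Module Completion Ratios and Functional Classification of Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Evaluates the functional potential (functionome) of genomes
    annotated with KEGG Orthology (KO) identifiers. Parses Boolean module
    definitions in the KEGG DEFINITION dialect, computes module completion
    ratios (MCRs) and complete-set abundances for genome KO profiles,
    and performs the downstream functional-classification stage:
    constant-module filtering, Euclidean complete-linkage clustering with
    Newick export, and principal component analysis with module-loading
    diagnostics. Includes a seeded synthetic-data generator producing
    phenotype-structured genome cohorts, transcribed worked-example
    fixtures for four archaeal genomes, flat-file and TSV readers and
    writers, and a command-line pipeline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    jsonlite
Config/testthat/edition: 3
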