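Package: rmavoid
Title: Restriction-Modification Target Avoidance in Bacterial Genomes and Plasmids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects Type II restriction-modification (R-M) systems in annotated
    proteomes by protein similarity to a target-annotated enzyme reference,
    builds a taxonomic dictionary of recognition targets across species, scores
    statistical avoidance of target words with a maximal Markov-model
    exceptionality Z-score, and relates avoidance to pangenome component,
    plasmid size, and plasmid host range. Ships seeded synthetic-data
    generators that emulate every input the pipeline consumes, with planted
    ground truth for recovery tests.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
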