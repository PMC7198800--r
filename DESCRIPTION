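Package: nitrofill
Title: Ensemble Gapfilling and Proteomic Statistics for Bacterial
    Nitrogen Substrate Utilization
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how bacterial strains utilize diverse
    nitrogen substrates. Implements flux balance analysis on toy-scale
    stoichiometric networks, positive and negative gapfilling against a
    universal reaction database, ensemble network reconstruction with
    weighted growth and flux prediction, phenotype-microarray growth-curve
    scoring (logistic fits, carrying-capacity growth calls, quartile
    intensity matrices), masked model-vs-experiment evaluation with random
    baselines, and label-free proteomics statistics (differential
    abundance, KEGG-ortholog matching, combined pathway p-values, and a
    PII-correlation screen). A synthetic-data module generates metabolic
    universes, plate-reader kinetics and LFQ matrices with known ground
    truth for recovery-style testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    minpack.lm,
    stats,
    tools,
    utils,
    withr,
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
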