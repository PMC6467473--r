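Package: capacitrack
Title: Transcriptome Trajectory Analysis of Pluripotent Stem Cell Capacitation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for characterizing the transcriptional
    progression of naive pluripotent stem cells toward formative/primed
    pluripotency (capacitation). Provides highly-variable-gene detection by
    regression of the squared coefficient of variation against mean
    expression, soft clustering of temporal expression dynamics by fuzzy
    c-means with elbow-method cluster-number selection, semantic labelling of
    temporal cluster archetypes, cross-dataset and cross-species cluster
    correspondence through one-to-one orthologs, hypergeometric gene-set
    enrichment, simplex-constrained least-squares (quadratic programming)
    decomposition of samples into embryonic epiblast stage fractions, and
    sample-level PCA/correlation trajectory summaries. A synthetic-data
    generator with planted ground truth makes every stage testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    e1071,
    pracma
Config/testthat/edition: 3
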