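Package: methscape
Title: DNA Methylation Landscape Analysis for Drug-Metabolizing Enzyme Gene Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for Illumina 450K-style beta-value matrices over
    curated gene panels of drug-metabolizing enzymes (DMEs). Computes per-CpG
    box statistics and the beta_R inter-individual variability statistic with a
    control-gene-derived threshold, tests per-CpG methylation-expression rank
    correlations, calls tumor promoter hypermethylation and integrates it with
    demethylating-agent expression responses, classifies genes into
    methylation-landscape types (highly variable, tumor-suppressor-like,
    housekeeping-like), and performs shared-locus first-exon methylation
    analysis of splicing isoforms with an exact one-sample Wilcoxon signed-rank
    test. Includes a seeded synthetic-cohort generator with planted ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
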