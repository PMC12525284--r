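Package: embryogs
Title: Embryo Genomic Selection with Biopsy-Scale Genotyping, Imputation and GBLUP
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis pipeline for preimplantation genomic
    selection in sheep. Generates a pedigreed cohort with a 50K-style SNP
    panel and polygenic growth traits, corrupts embryo-biopsy genotypes with
    a cell-number-dependent whole-genome-amplification dropout/error model,
    and runs the downstream evaluation: PLINK-style marker and sample QC
    (including the Hardy-Weinberg exact test), genotype concordance and
    method-of-moments identity-by-descent, reference-panel imputation with a
    diploid Li-Stephens hidden Markov model, VanRaden genomic relationships,
    and GBLUP breeding values with prediction-error-variance reliabilities,
    culminating in the embryo-versus-lamb GEBV concordance analysis.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    tools,
    utils,
    vcfR,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
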