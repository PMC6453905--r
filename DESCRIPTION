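Package: surfmine
Title: Surfaceome Mining of Thymocyte RNA-Seq Expression Profiles
Version: 0.1.0
Authors@R:
    person("Open", "Contributor", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Mines bulk RNA-seq abundance estimates for candidate cell-surface
    biomarkers of leukemia-initiating cells. Reads per-sample transcript
    abundance tables (target_id/length/eff_length/est_counts/tpm), aggregates
    transcripts to genes, restricts the expression matrix to a curated
    surfaceome catalogue, bins genes into four TPM expression classes, applies
    a threshold-based fold-change screen per thymocyte DN stage, partitions
    the stage-wise hit sets into Venn regions, ranks candidate markers, and
    provides sample-structure diagnostics (log-transformed PCA with sorted
    loadings, sample-sample correlation). Ships a seeded synthetic-data
    generator emulating the 2-genotype x 4-stage x replicate study design with
    planted marker genes, plus recovery scoring and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
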