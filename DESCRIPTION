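Package: flagmot
Title: Inference of Bacterial Flagellar Motility from Genomes and Metagenomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to infer the capacity for flagellar motility at two scales.
    At the genome scale, a panel of flagellar-assembly gene families is selected
    from labelled gene presence/absence data by dual prevalence criteria and a
    gradient-boosted tree classifier is tuned, trained and evaluated on the
    binary gene features. At the community scale, a flagellar motility index is
    computed from shotgun metagenomic reads as the ratio of the median
    gene-length-corrected reads-per-kilobase (RPK) of flagellar genes to that of
    120 single-copy marker genes, and converted to a percent of flagellated
    bacteria through a linear standard curve calibrated on mock metagenomes.
    Includes a mock-metagenome simulator (synthetic genomes, uniform read
    sampling, naive translated-search annotation), calibration-curve fitting,
    and trait-ecology statistics (phylogenetic D for binary traits, taxonomic
    rank conservation, gene-category enrichment between trait classes), plus a
    command-line interface over all steps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    data.table,
    jsonlite,
    lhs,
    S4Vectors,
    stats,
    tools,
    utils,
    xgboost,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
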