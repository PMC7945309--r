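Package: gbsfoil
Title: De Novo GBS Locus Assembly, Filtering, and Exhaustive Five-Taxon
    D-Statistic Introgression Scans
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A reusable pipeline from demultiplexed genotyping-by-sequencing
    (GBS) short reads to introgression inference. Implements two-step de novo
    locus assembly (reference-locus clustering from representative individuals
    followed by best-hit assignment of all individuals), hypervariability and
    missing-data filtering, construction of individual-, population- and
    taxon-level working datasets with SNP and concatenated-sequence
    representations and locus-level bootstrapping, and an exhaustive
    five-taxon D-statistic (DFOIL; Pease and Hahn 2015
    <doi:10.1093/sysbio/syv023>) scan constrained by an ultrametric guide
    tree, with pair-level aggregation of significant tests. A synthetic-data
    module generates GBS read sets with known species trees, introgression
    events, missingness and paralogy so that every stage is testable end to
    end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    ape,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
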