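Package: islescan
Title: Admixture Scans, Runs of Homozygosity and Selection Tests for
    Recently Admixed Cohorts
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for dissecting the genomes of recently admixed
    populations: genotype quality control and LD pruning, a PLINK-style
    sliding-window caller for runs of homozygosity, local-ancestry
    dosage handling with block segmentation and length statistics, a
    genome-wide Z-score scan for local-ancestry deviations with a
    diversity follow-up, weighted two-locus admixture-LD dating of the
    admixture event, windowed Tajima's D / Hudson FST / PBS selection
    statistics, and an ms-dialect coalescent engine that builds neutral
    null distributions for them. A seeded synthetic-cohort generator
    produces three-way admixed genomes with known truth for
    parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    vcfR,
    jsonlite,
    yaml,
    GenomicRanges,
    IRanges
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
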