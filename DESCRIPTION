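Package: thalcefa
Title: Thalassemia Genotype Calling from Multiplex PCR Capillary
    Electrophoresis Fragment Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Calls diploid alpha- and beta-thalassemia genotypes from
    multi-dye capillary-electrophoresis fragment data. Copy-number
    configurations of the alpha-globin cluster (the -a3.7, -a4.2,
    anti-3.7 and anti-4.2 triplication and HKaa rearrangements) are
    classified from alpha1/alpha2 and Y1/Y2 peak-height ratios, and
    deletion and non-deletion alleles are resolved from mutation,
    wild-type-control and breakpoint peaks in the FAM, VIC and NED
    channels. Includes size-standard calibration, peak detection and
    target binding for raw traces, a rule-based diploid genotype
    assembler with explicit ambiguity and QC handling, and a synthetic
    electropherogram simulator with truth labels so the whole pipeline
    is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
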