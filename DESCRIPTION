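Package: msapr
Title: Methylation-Sensitive Amplified Polymorphism (MSAP) Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Scores dual-enzyme (HpaII/MspI) band-presence matrices from
    methylation-sensitive amplified polymorphism assays into per-locus
    cytosine methylation states (non-, hemi-, fully methylated,
    uninformative), profiles relative methylation levels per sample and
    compares sample groups, quantifies methylation breadth across tissues
    with a tau specificity index, counts tissue-specific and shared
    methylated loci, tallies state transitions along developmental stage
    paths, and relates methylation state classes to transcript levels.
    Includes a seed-deterministic synthetic-data generator that emulates
    the biochemistry of the two isoschizomers for validation of the whole
    pipeline against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
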