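Package: ylineage
Title: Diachronic Y-STR Haplotype Analysis, Pairwise TMRCA Estimation and
    Paternal-Line Continuity Testing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for diachronic Y-chromosome short tandem repeat (Y-STR)
    studies that compare ancient and modern males from the same community.
    Implements Yfiler and Yfiler Plus panel handling with the DYS389b
    nomenclature conversion and multi-copy locus splitting, forensic
    diversity indexes (per-locus gene diversity, haplotype diversity, match
    probability, discrimination capacity) with compatibility clustering of
    partial profiles, per-pair locus difference vectors under the infinite
    allele and stepwise mutation models, a Bayesian estimator of the time to
    the most recent common paternal ancestor for a pair of haplotypes with a
    geometric coalescence-time prior, chronological-window continuity
    verdicts, two-population AMOVA FST/RST with permutation tests, and a
    forward genealogy simulator for locus-specific stepwise mutation with
    ancient-DNA style locus dropout.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
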