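Package: okseqr
Title: Okazaki-Fragment and Ribonucleotide Sequencing Analysis of
    Replication Origin Firing and Fork Progression
Version: 0.9.0
Authors@R: person("okseqr", "developers", role = c("aut", "cre"),
    email = "okseqr@example.org")
Description: Analysis of strand-specific nascent-strand sequencing data from
    budding yeast. Computes per-origin productive-firing efficiency (the
    origin efficiency metric, OEM) from Okazaki-fragment reads, origin-anchored
    strand-bias and delta-bias profiles, normalized meta-coverage and
    fork-progression readouts around early-firing origins, coverage-based
    timepoint matching between conditions, and restriction-site normalized
    ribonucleotide (HydEn-seq) summaries for polymerase-usage inference.
    Includes a stochastic S-phase simulator with per-origin firing competence,
    truncated-normal firing times, constant-speed bidirectional forks and
    passive replication, which generates Okazaki-fragment, ribonucleotide and
    restriction-site reads with known ground truth, plus an independent
    analytic oracle for expected OEM, so every statistic is verified by
    parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
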