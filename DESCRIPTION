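Package: admixscan
Title: Case-Only Admixture Mapping by Excess Local Ancestry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Case-only admixture mapping for recently admixed cohorts such as
    African Americans. Simulates admixed case cohorts with Markov ancestry-tract
    structure, Balding-Nichols reference panels and disease ascertainment at a
    risk locus; applies a genotype quality-control cascade (sample call rate,
    heterozygosity outliers, SNP call rate, panel concordance); scans local
    European ancestry for case-only excess relative to each individual's global
    ancestry with one-sided Z tests in both ancestry directions; sets
    genome-wide significance thresholds from the eigenvalue-based effective
    number of independent tests; calls candidate regions with peak and
    mean-excess summaries; and maps observed excess ancestry to ancestry
    relative risks under additive or multiplicative case-ascertainment models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
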