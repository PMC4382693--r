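Package: laikit
Title: Local-Ancestry Pipelines for Recently Admixed Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying recently admixed diploid cohorts with three
    continental ancestries (Native-American, European, African): a
    hybrid-isolation cohort simulator with ground-truth ancestry tracts,
    array-style SNP and sample quality control, a haplotype admixture hidden
    Markov model for local-ancestry calling, base-weighted global ancestry
    with region-weighted population estimates and demographic-zone
    comparisons, time-since-admixture inference from ancestry-switch counts,
    concordance analysis between call sets, reference-panel-size and
    SNP-density sensitivity sweeps, and Hudson FST with permutation tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
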