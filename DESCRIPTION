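Package: cfMRD
Title: Multi-Modal Cell-Free DNA Analysis for Longitudinal Relapse Monitoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Longitudinal liquid-biopsy analysis of plasma cell-free DNA for
    minimal residual disease monitoring. Implements a negative-binomial
    mixture methylation caller for cfMeDIP-seq window counts, healthy-panel
    z-score statistics over the cfDNA genome and fragmentome (copy number,
    fragment size, fragment ratio profiles, targeted loci, site-centered
    coverage), a tumor-specific hypermethylation signature builder with a
    cross-comparison vote rule, and a mixed-effect logistic model that
    integrates the per-sample metrics with patient-grouped cross-validation
    and cohort-baseline normalization. Ships a synthetic-cohort generator
    that emulates the statistical structure of a uveal melanoma monitoring
    study (fragment-length mixtures, CNV-bearing binned counts at stated
    tumor fractions, generative cfMeDIP mixtures, methylation arrays with
    planted hypermethylation, and longitudinal metric trajectories with
    relapse labels) so every component is testable against known ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    lme4,
    data.table,
    IRanges,
    S4Vectors,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    limma,
    withr
Config/testthat/edition: 3
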