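Package: idhres
Title: Longitudinal Multi-Omics Analysis of IDH-Inhibitor Resistance in AML
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested, reusable pipeline for studying clinical resistance to
    mutant-IDH1/2 inhibitors in acute myeloid leukemia from longitudinal
    multi-omics data. Implements somatic variant filtering with a four-tier
    hierarchical confidence classification of putative drivers, longitudinal
    variant-allele-frequency analytics (cancer cell fractions, relative
    mutation timing, IDH-mutation clearance calls, relapse
    acquisition/selection events, single-cell clone-independence tests),
    promoter-methylation consensus k-means clustering with differential
    methylation testing, LSC17 leukemia-stemness scoring with a minimal
    preranked enrichment statistic, response-association statistics (Fisher
    odds ratios, ROC/AUROC, multivariable logistic regression, starburst
    methylation-expression integration, log-rank survival comparison), and a
    rule-based classifier of per-patient genetic/epigenetic evolution
    patterns at relapse. A seeded synthetic-cohort generator with a
    recoverable ground truth makes the full pipeline testable end to end
    without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
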