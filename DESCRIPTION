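Package: painmiR
Title: miRNA Dysregulation Screening and Behavioural Analysis for
    Cancer-Pain Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tested, reusable pipeline for discovering and validating
    cancer-pain-associated miRNA signatures in sensory ganglia. Provides
    quantile normalization and a replicate-consistency dysregulation
    screen for miRNA expression arrays, delta-delta-Ct relative
    quantification of qPCR data, consensus aggregation of miRNA-target
    predictions with housekeeping-normalized expression-response
    filtering and reciprocal-regulation scoring, and reduction of von
    Frey withdrawal data to stimulus-response curves, interpolated
    mechanical thresholds and area-under-curve summaries. A synthetic
    data module generates every pipeline input with planted, recorded
    ground truth so all stages are testable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    limma,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
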