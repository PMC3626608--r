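Package: ffpeqc
Title: Quality Assessment of Expression Arrays from Degraded (FFPE) Samples
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Per-array quality metrics for expression matrices from degraded
    samples such as formalin-fixed paraffin-embedded (FFPE) tissue. Implements
    the normalization-stress statistic (Stress) and the leave-one-out
    standardized deviation statistic (dfArray), together with the comparison
    metrics RLE, NUSE and the distance-to-average-array outlier rule;
    two-stage remove-and-renormalize quality workflows; a synthetic
    FFPE-degradation data generator with ground-truth labels; and an
    evaluation of the variance inflation and bias incurred by retaining
    poor-quality arrays during normalization.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    limma,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
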