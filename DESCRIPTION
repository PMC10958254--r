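Package: qoctga
Title: Quantitative OCT Analysis of Geographic Atrophy Progression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: En-face quantification of geographic atrophy (GA) from per-B-scan
    OCT segmentation masks of the three constituent features of retinal
    atrophy (RPE loss, photoreceptor degeneration and hypertransmission).
    Derives composite feature maps (RORA, photoreceptor degeneration in
    isolation, intact macula), fovea-centred ETDRS subfield areas and
    per-cent occupancy, lesion focality and perimeter morphometrics,
    longitudinal square-root-area trial endpoints with mixed-effects least
    squares means, and baseline predictors of 12-month GA growth with
    bootstrap R-squared. Includes a synthetic-cohort simulator that renders
    multifocal lesions whose square-root area grows linearly in time, with
    known ground truth for validation of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    grDevices,
    igraph,
    jsonlite,
    lme4,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    emmeans,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
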