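Package: cdrhythms
Title: Circadian Rhythm and Alter-Specificity Analysis of Call-Detail Records
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates circadian rhythms of outgoing telephone-call activity
    from call-detail records (CDRs), quantifies their persistence across
    successive observation periods with square-root Jensen-Shannon and
    Euclidean distances, and measures alter-specificity (whether particular
    contacts are called at particular times of day) through origin, reference
    and relative entropies under a time-shuffling permutation null model.
    Includes a configurable synthetic CDR generator emulating an older-adult
    study population, preprocessing filters (outgoing-only selection, common
    observation window, active-ego retention), top-2 alter call fractions,
    entropy/top-2 correlation, call-duration profiles by social category, and
    an end-to-end pipeline with reproducible seeding.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
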