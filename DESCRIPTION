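Package: paleoneuro
Title: Quantitative Paleoneurology of Endocast Measurements
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the classical quantitative analysis of mammalian
    cranial endocasts: encephalization quotients under the theoretical
    two-thirds brain-body allometry, neocorticalization percentages and
    their trend through geologic time, minimum convex polygons delimiting
    class-level brain-body grades, cortical surface-to-volume scaling, and
    within-species variation statistics. Ships verbatim transcriptions of a
    published endocast measurement table (158 recoverable specimen rows of
    fossil and living mammals plus an eight-specimen intra-species series)
    as plain-text fixtures, together with a deterministic synthetic-data
    generator for parameter-recovery and property-based testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports: stats, grDevices, jsonlite
Suggests: testthat (>= 3.0.0), withr, graphics
Config/testthat/edition: 3
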