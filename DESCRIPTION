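Package: altiniche
Title: Altitudinal Gradients of Species Richness and Niche Specialization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing how species richness and niche
    specialization change along altitudinal gradients in presence-only
    occurrence data. Occurrence records are binned into 100-m vertical
    intervals per biogeographic region, richness is adjusted for interval
    area as D = S/log10(A + 1), per-species niche breadth is obtained from
    an Outlying Mean Index decomposition of a standardized environmental
    matrix (inertia = marginality + tolerance + residual tolerance), and a
    species specialization index SSI = 1 - T/Tmax is derived from the
    tolerance percentages. Altitude-response trends are fitted by
    significance-driven polynomial degree selection (cubic, then quadratic,
    then linear). A virtual-species simulator with Gaussian altitudinal
    niches provides landscapes and occurrence data with known ground truth,
    and a pipeline driver runs the whole analysis end to end with a
    reproducible manifest.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
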