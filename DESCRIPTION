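Package: funhab
Title: Functional Habitat Connectivity and Butterfly Flight Time Budgets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools linking habitat fragmentation to insect movement behaviour.
    Turns binary habitat rasters into matrix-edge-core maps, signed edge
    distances, extended-forest-edge functional habitat and gap-crossing
    functional-connectivity maps with temporal summaries; aggregates point
    occurrences on hexagonal grids and ranks candidate sampling cells; computes
    quadrat-level Shannon evenness of host-plant surveys and the habitat-contrast
    abundance model; and fits negative-binomial mixed time-budget models to
    flight-arena trial logs, with exposure offsets, linear contrasts, marginal
    means and AIC selection. Seeded synthetic-data generators emulate every
    input so the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    igraph,
    glmmTMB,
    lme4,
    lmerTest,
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    emmeans,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
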