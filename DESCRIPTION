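Package: herdlab
Title: Headless Multi-Agent Herding Simulator and Behavioral Time-Series Pipeline
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A headless reimplementation of a collaborative search-and-corral
    ("desert herding") task in which three player avatars locate, corral, and
    contain Brownian-driven target agents inside a central containment area,
    together with the measurement pipeline used to study division of labor
    and behavioral structure in such tasks: construction of 5 Hz
    movement-fluctuation series (displacement angle and head-orientation
    change), detrended fluctuation analysis (DFA) with a geometric window
    schedule, alpha-shape search-area polygons and proportion of overlapping
    search area, and censored log-logistic accelerated failure time (AFT)
    modeling of trial duration. Scripted player policies emulate the task's
    visibility, information (HUD vs. compass), and target-number
    manipulations so the entire pipeline can be exercised without human data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deldir,
    polyclip,
    jsonlite,
    data.table,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    survival,
    optparse
Config/testthat/edition: 3
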