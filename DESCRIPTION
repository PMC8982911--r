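Package: coviam
Title: System Dynamics Simulation of Pandemic Impacts on Sustainable
    Development Goals
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A generic stock-flow system-dynamics engine (declarative model
    specification, closed expression grammar, piecewise-linear lookups,
    explicit Euler integration over calendar years) together with causal-loop
    analysis (signed influence digraphs, elementary feedback-loop enumeration,
    polarity classification and loop-inventory audits), an Egypt model
    instance quantifying COVID-19 impacts on SDG 1 (poverty), SDG 2 (food
    insecurity), SDG 8 (GDP growth) and SDG 13 (greenhouse-gas emissions),
    time-dependent shock and policy scenarios, trajectory-anchor calibration
    by derivative-free bounded search, and a run-comparison reporting layer
    with a command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
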