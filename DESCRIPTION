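Package: coastsim
Title: Agent-Based Simulation of Emerging Coastal-Tourism Vulnerability
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: An agent-based model of a coastal tourism destination in which
    hotel, beach, dive, boat and nearshore operators allocate scarce resources
    between maintenance, the tourism product, the environment and savings while
    pollution diffuses over a coded coastal grid, sudden events deposit
    environmental degradation, and sea-level rise erodes low-lying land.
    Operators can respond to environmental threats collaboratively or
    individually; the success of past collaborations is remembered on directed
    links that modulate future willingness to act. The package provides the
    full scheduler with seeded reproducibility and time-series output, a
    synthetic map generator, and an experiment harness for variance-based
    (Sobol) global sensitivity analysis with Saltelli sampling and for
    scenario discovery via Latin hypercube sampling and the Patient Rule
    Induction Method (PRIM).
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    lhs,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
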