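Package: olsim
Title: Agent-Based Simulation of Opinion-Leader Emergence on Nursing Units
Version: 0.1.0
Authors@R: person("Olsim", "Maintainers", email = "maintainers@olsim.example.org",
    role = c("aut", "cre"))
Description: Deterministic-seedable agent-based model of opinion dynamics on
    a simulated patient care unit. Nurse agents hold probability-scaled
    beliefs and revise them under credibility weighting when new evidence
    is announced; uncertain agents seek advice from visible, credible
    colleagues, and agents repeatedly sought out for advice emerge as
    opinion leaders. Includes a full-factorial parameter sweep with
    replication, an individual-agent time-series experiment, advice-network
    edge-list export, and a statistical verification harness (descriptive
    aggregation, directional regression sign checks, and a logistic model
    of advisor availability).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
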