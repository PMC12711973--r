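Package: orsched
Title: Two-Phase Stochastic Scheduling of Elective Surgeries in Shared
    Operating Rooms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for scheduling inpatient and outpatient elective
    surgeries in shared operating room blocks under uncertain surgery
    durations, emergency arrivals, and no-shows.  Implements a two-phase
    stochastic optimization framework: a chance-constrained integer
    programming model for the advance (assignment) stage with Monte
    Carlo-approximated chance constraints, and a two-stage stochastic
    mixed-integer program for the allocation (sequencing and timing)
    stage solved by sample average approximation (SAA), N-fold SAA, or a
    biased random-key genetic algorithm with a joint sequencing-and-slack
    encoding.  Includes a synthetic instance generator calibrated on
    published lognormal procedure-duration mixtures, a vectorized
    discrete-event evaluator of weekly schedules under Bernoulli or
    Poisson emergency arrivals, and multi-objective cost reporting.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
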