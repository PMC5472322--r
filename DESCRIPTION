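Package: anaerocap
Title: Anaerobic Capacity from Breath-by-Breath Gas Exchange Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates anaerobic capacity from cycling gas-exchange and blood
    lactate data by four methods: the maximal accumulated oxygen deficit (MAOD)
    with submaximal VO2-power extrapolation and a 10% body-store correction; the
    alternative MAOD summing the fast component of excess post-exercise oxygen
    consumption (biexponential off-kinetics fit) with a blood-lactate O2
    equivalent; W' from three two-parameter critical-power models selected by the
    standard error of W'; and anaerobic work derived from gross efficiency and
    metabolic power. Includes gas-exchange utilities (resampling, windowed
    averages, trapezoidal O2 integration, isotime), automated gas exchange
    threshold detection by two-segment v-slope regression, paired and
    repeated-measures comparisons, and a synthetic physiology generator for a
    two-condition crossover so every stage is testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    pracma,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
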