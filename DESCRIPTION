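Package: eldergame
Title: Four-Party Evolutionary Game of "Internet + Community Elderly Care" Regulation
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Models the regulation of "Internet + Community Elderly Care"
    services as an asymmetric four-population evolutionary game between
    elderly-care service providers, service information platforms, the
    government, and elderly consumers. Implements the pure-strategy payoff
    matrix and expected-utility layer, the replicator-dynamics vector field,
    Lyapunov first-method stability classification of the sixteen corner
    equilibria (including detection of unconditionally unstable corners by
    sign sampling), closed-form policy thresholds for penalties and subsidies,
    strategy-volume probabilities, and a fixed-step system-dynamics simulator
    with built-in policy-sensitivity scenario suites and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: jsonlite, yaml, stats, utils, graphics, grDevices, tools
Suggests: testthat (>= 3.0.0), deSolve, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
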