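Package: ringtae
Title: Recurrent Ring-Network Modeling and Psychophysics of Short-Term
    Tilt Aftereffects
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates a recurrently connected ring network of
    orientation-tuned V1 units with Mexican-hat connectivity, applies
    adaptation-induced firing-rate suppression with exponential recovery,
    decodes population activity through a labeled-line (population-vector)
    readout, and predicts the time course of the tilt aftereffect (TAE)
    for brief adapter-test protocols.  Also provides the matching
    behavioral analysis chain: logistic psychometric fitting with pooled
    lapse estimation, PSE-difference tilt aftereffects, parametric
    bootstrap (Monte Carlo) comparison of psychometric functions,
    catch-trial visibility statistics, and a synthetic two-alternative
    forced-choice observer for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
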