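Package: routecx
Title: Closed-Loop Central-Complex Model of Lateralised Visual Route Guidance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates insect visual route guidance as a closed loop between
    lateralised, orientation-tuned familiarity signals (a stand-in for mushroom
    body recognition output) and a central-complex-like steering circuit: a
    column-discretised compass bump, a decaying allocentric goal field charged
    by left/right familiarity input, and a lateral-offset comparison stage that
    drives turning. Includes the two in-silico experiments built on the model
    (a directional-bias by directional-noise robustness sweep, and a celestial
    cue rotation perturbation implemented as an integer bump shift in the
    compass), behavioural path and trackball metrics (turn ratio, side
    preference, arc-length path discretisation, bearings and turn angles,
    directional error, circular summaries, exact Wilcoxon signed-rank tests),
    and seeded synthetic-behaviour generators so every analysis runs without
    field recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    optparse,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
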