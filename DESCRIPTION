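Package: autrain
Title: Automated Unsupervised Operant Training and Psychoacoustics Simulator
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Headless re-implementation of a home-cage touchscreen training
    system for common marmosets: an automated unsupervised training (AUT)
    schedule with performance-based step progression, two- and
    three-alternative-choice audio-visual association tasks, an auditory
    detection task with a level-dependent reward scheme, simulated subjects
    standing in for animals, and the statistical and psychometric analysis
    pipeline (hit rates, d-prime, binomial tests against chance, Bonferroni
    correction, Kruskal-Wallis reaction-time comparisons, engagement
    summaries, and cumulative-normal psychometric threshold fitting with
    bootstrap confidence intervals).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
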