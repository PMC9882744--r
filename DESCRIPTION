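Package: forumpulse
Title: Lockdown-Period Analysis of Posting Behaviour in an Online
    Gambling Forum
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying how the 2020 COVID-19 lockdowns changed
    activity on a German online gambling discussion board. Provides a
    relational forum data model with CSV round-tripping, a synthetic-data
    generator that emulates the board's registration bursts, subforum
    posting rates, heavy-tailed post lengths and reply-latency decay,
    behavioural user typing from per-subforum post counts,
    period-segmented descriptive statistics, 8-hour reply-latency
    histograms, and a Bayesian exponential-decay model of reply latencies
    fitted by adaptive Markov chain Monte Carlo with split R-hat
    diagnostics, highest-density intervals and directional Bayes factors
    for lockdown versus pre-lockdown comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    grDevices,
    jsonlite,
    stats,
    utils
Suggests:
    rjags,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
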