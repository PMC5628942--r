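Package: mcesignal
Title: Early-Warning Signal Detection for Mass-Casualty Events from
    Social-Media Streams
Version: 0.1.0
Authors@R:
    person("Signal", "Surveillance Lab", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for syndromic surveillance of mass/multiple casualty
    events from microblogging (Twitter-style) activity streams. Ingests
    newline-delimited JSON tweet archives (with rate-limit notice
    accounting, deduplication and onset clipping), parses and evaluates the
    boolean keyword query language used for disaster-specific filtering,
    aggregates filtered messages into onset-anchored tweets-per-minute
    series, computes first-hour cumulative milestone statistics and event
    summaries, and detects threshold-crossing alerts with lead times
    against official disaster-timeline marks. A synthetic stream generator
    (inhomogeneous Poisson burst model with retweet mixture, heavy-tailed
    follower counts and keyword-bearing text) provides calibrated event and
    control streams for end-to-end validation, since real historical tweet
    corpora are not redistributable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
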