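---
title: "Methods: threshold alerting on social-media streams for mass-casualty early warning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: threshold alerting on social-media streams}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcesignal)
```

## The surveillance problem

Hospital activation for a mass/multiple casualty event (MCE) usually waits
on official channels — county disaster pages, standby notices — which lag
the incident. Public microblogging reacts within seconds of onset, and the
*volume* of event-related posts is itself a signal: it rises by orders of
magnitude within minutes and peaks within a few hours. `mcesignal`
implements and validates the simplest auditable detector built on that
signal: keyword-filter the stream, count filtered messages per minute from
onset, and alert when a minute's count reaches a threshold.

The method is deliberately transparent — no learning, no language models —
because an activation signal must be explainable to the hospital officers
who act on it. Its assumptions are correspondingly explicit:

* witnesses and relayers post promptly and in volume (events in populated,
  connected areas; the delayed-onset signature models the exception);
* the keyword rules capture the event vocabulary with useful precision;
* one-minute resolution is adequate (latencies under a minute are not
  claimed).

## The query language

Filter rules follow the convention of commercial tweet-archive search:
adjacency (space) is AND; a standalone uppercase `OR` separates
alternatives and binds looser than adjacency; parentheses group; quoted
spans match as exact phrases. Matching is case-insensitive and token-based:
text is lowercased and split into maximal runs of Unicode letters/digits,
so `#PrayForBoston` yields `prayforboston` and `'214'` cannot match inside
`62148` ("exactly, not tokenized" is interpreted as "not split into
independently matchable words", i.e. a consecutive-token phrase — raw
substring matching would reintroduce exactly the false positives quoting is
meant to prevent).

Two genuinely open choices, fixed as follows:

* **Unquoted multi-word OR alternatives** (`... OR finish line OR ...`) are
  parsed as phrases, not conjunctions. Treating `San Francisco` as
  AND-of-terms would let it match a text mentioning San Diego and Francisco
  Street; the phrase reading matches the evident intent of the rule
  authors. The pretty-printer (`render_rule()`) quotes phrases, and
  `parse_rule(render_rule(r))` is the identity on ASTs (property-tested).
* **Digit runs are tokens**, so `'6.0'` becomes the phrase `[6, 0]`. This
  keeps the tokenizer uniform; it slightly widens matching (`6 0` in
  running text would match) but never splits a number into unrelated hits.

Only uppercase standalone `OR` is an operator; lowercase `or` is an
ordinary term. There is no negation, stemming, fuzzy matching or stop-word
handling: the method is exact keyword search, and the evaluator is fuzzed
against a brute-force enumeration oracle (10,000 random rule/text pairs)
rather than trusted.

The prospective variant (`joint_match()`) requires at least one
*event*-vocabulary operand AND at least one *location*-vocabulary operand —
the generic-terms-plus-geographic-restriction filter used for monitoring a
region in advance of any specific event.

## Ingest conventions

Streams are newline-delimited JSON, optionally gzipped. Every input line is
classified exactly once — kept tweet, duplicate, malformed, rate-limit
notice, or pre-onset — and the bookkeeping identity
`records_read = kept + duplicates + malformed + notices + pre_onset`
is enforced by fuzz tests with randomly corrupted lines. Decisions a
maintainer should know:

* **Naive timestamps are malformed.** A timestamp without an explicit
  offset would have to be guessed into a zone; a wrong guess silently
  shifts every bin. Rejection is the only safe default.
* **Duplicate ids: first occurrence wins.** Upstream archives occasionally
  re-deliver; first-wins is deterministic and order-stable.
* **Retweet flag** is the disjunction of the available signals: an explicit
  flag, a share verb, a retweeted-id link, or the `RT @` text prefix.
* **Sorting is stable** (ties keep input order), so binning is
  deterministic.
* **Onset resolution** converts local civil time + IANA zone to UTC and
  *rejects* nonexistent (spring-forward) and ambiguous (fall-back) local
  times, naming the candidate instants. The package also repairs a broken
  `TZDIR` at load (some minimal R images ship the tz database where R does
  not look, in which case zone conversion silently degrades to UTC — fatal
  for onset anchoring, so it is detected and fixed or refused).

## Aggregation, milestones, alerting

* **Bins are 1-based and half-open**: bin *m* is
  `[onset + (m−1)·60 s, onset + m·60 s)`. "Reached in *k* minutes" means
  bin *k* qualified. This makes a crossing in the second minute of an event
  representable as 2 even with sub-minute data latency.
* **Milestones** use the exact real-valued target:
  `minute(p) = min{ m ≤ 60 : cum(m) ≥ (p/100)·cum(60) }`, undefined for an
  empty first hour. No rounding of the target — this is determinate and
  forces `minute(100)` to the last minute that adds volume (60 whenever
  bin 60 is non-empty). Milestone minutes are non-decreasing in *p*
  (property-tested).
* **Median across events**: middle order statistic for odd *n*; for even
  *n*, the mean of the central pair rounded half-up to whole minutes (the
  published tables only need *n* = 5; the even-*n* convention is fixed so
  the function is total).
* **Alerting is strict and single-bin by default**: fire at
  `min{ m : counts[m] ≥ T }`. A sustained variant (`window = w` consecutive
  qualifying bins) is exposed but defaults to 1, because the historical
  analyses speak of a threshold being *reached*. The alert instant is the
  **end** of the qualifying bin — a real-time system only knows a minute's
  count once the minute completes — and lead times are
  `t_mark − t_alert` (positive = alert first).
* **Mean followers** is computed per distinct user (last observed value),
  with a per-tweet variant behind a flag; published wording is ambiguous
  between "per user" and "per tweeter".

## The synthetic generator: what it states, what a green test means

Real MCE tweet corpora are commercially licensed and not redistributable,
so validation rests on synthetic streams whose *stated world* is:

| parameter | default | why |
|---|---|---|
| pulse shape | `λ(t) = b + (p−b)(t/τ)e^{1−t/τ}` | one-parameter rise time, closed-form max `p` at `t = τ`, fast rise + smooth decay matching observed event signatures |
| retweet share | 0.55 | published composition of historical event streams (45% unique / 55% retweets) |
| follower counts | log-normal, meanlog 7.2, sdlog 1.5 | heavy tail; implied mean ≈ 4.1k lies in the published per-event range 3382–9992 |
| retweet counts | Poisson mean 200 on ~30% of originals | published per-event means 82–564; cascades are *not* modeled |
| text | bag-of-words; event/location snippet with stated probability + decoys | only token membership matters to the filters |
| peaks (presets) | 3326 / 1423 / 957 / 739 / 209 tpm | published first-hour per-event peaks |
| rise times (presets) | τ = 25 / 20 / 20 / 5 / 3 min | *not published*; chosen once as realistic fast-rise constants (peak within the first hour). The published 200 tpm crossing minutes cannot all be reproduced jointly with these peaks under a single-timescale pulse, so presets are validated against their **own** analytic crossing, not the published ones |
| delayed onset | 20 min dead time (school-shooting-like preset) | models delayed signal scalability when few witnesses can post |
| control stream | flat 250/min total, joint-match probability 0.4 → expected 100 matched/min | high-volume public event whose *matched* rate stays at half the alert threshold |

Arrivals use Poisson thinning at the intensity maximum; dispersion of
per-minute counts is verified ≈ 1, and the closed-form bin masses are
checked against quadrature. `first_crossing_minute()` — the analytic
`min{ m : ∫_{m−1}^m λ ≥ T }` — is the recovery target for end-to-end tests
(generate → NDJSON → ingest → rules → bin → detect).

A green recovery test therefore establishes: *the pipeline faithfully
recovers the detector-relevant structure of a stream whose burst statistics
match the published summaries*. It does **not** establish performance on
real streams — no cascade structure, no multilingual or URL-laden text, no
adversarial or media-driven vocabulary drift, no spatial structure — and it
estimates no false-negative rate across disaster types.

The weakest stated case, knowingly: the 209 tpm preset barely clears the
200 tpm threshold, so Poisson noise near the crossing bin can shift the
empirical first crossing by a minute. The preset's steep rise keeps
per-run exact recovery around 0.6, and the acceptance criterion asks only
for a majority over 50 seeded runs; this is the honest behaviour of a
near-threshold event, not a tuning target.

## Numerical and degenerate-input conventions

* Zero-rate specs generate empty streams; empty streams yield all-zero
  series, `NA` fractions, undefined milestones and a non-firing alert —
  never errors.
* Generated timestamps are whole seconds (the NDJSON interchange precision),
  so write → read is the identity field-for-field and byte-for-byte on
  re-write; ingest of fractional-second input still parses.
* Identical spec + seed ⇒ byte-identical NDJSON (RNG state is saved and
  restored around generation).
* Output formatting is fixed (minutes integer, proportions 4 dp, rates
  1 dp) so reruns from a manifest are byte-identical.
* Closed-form pulse integrals are compared to quadrature at 1e-6 relative
  tolerance in tests; the detector and milestone scans are integer-exact.

## Known limitations

* Keyword precision/recall on real text is unmeasured here; rule quality is
  taken as given.
* Retweets are i.i.d. marks — no cascade dynamics, so retweet-driven
  super-linear growth is not emulated.
* The single-timescale pulse cannot simultaneously match a sub-hour peak
  and a slow (≈7-minute) threshold crossing at very high peaks; events
  with convex early growth are outside the stated family.
* One-minute bins bound achievable lead-time resolution; the end-of-bin
  alert anchor is conservative by up to 60 s.
* No hypothesis testing, sensitivity/specificity estimation, or live API
  connectivity.
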