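test_that("intensity has the documented pulse shape", {
  spec <- burst_spec(background_rate = 3, peak_rate = 100, time_to_peak = 8,
                     duration = 60)
  expect_equal(intensity(0, spec), 3)                       # pulse vanishes
  expect_equal(intensity(8, spec), 100)                     # max at tau
  tgrid <- seq(0, 60, by = 0.05)
  expect_lte(max(intensity(tgrid, spec)), 100 + 1e-9)
  expect_error(intensity(-1, spec), "t >= 0")

  # dead time: zero intensity, then the same pulse shifted
  spec_d <- burst_spec(background_rate = 3, peak_rate = 100, time_to_peak = 8,
                       duration = 60, dead_time = 10)
  expect_equal(intensity(c(0, 5, 9.9), spec_d), c(0, 0, 0))
  expect_equal(intensity(18, spec_d), 100)
})

test_that("closed-form pulse mass matches numeric quadrature", {
  spec <- burst_spec(background_rate = 2, peak_rate = 500, time_to_peak = 7,
                     duration = 120)
  # total pulse mass: (peak - background) * tau * e
  total <- stats::integrate(function(t) intensity(t, spec) - 2, 0, Inf,
                            rel.tol = 1e-10)$value
  expect_equal(total, (500 - 2) * 7 * exp(1), tolerance = 1e-6)
  # per-bin expected counts against a trapezoid Riemann sum
  for (m in c(1L, 3L, 7L, 30L)) {
    expect_equal(mcesignal:::expected_count(m - 1, m, spec),
                 riemann_bin_mass(spec, m), tolerance = 1e-6)
  }
})

test_that("analytic first crossing matches the Riemann-sum oracle", {
  specs <- list(
    event_preset("ne"), event_preset("bb"), event_preset("sf"),
    event_preset("mv"), event_preset("sh"),
    burst_spec(background_rate = 199, peak_rate = 199, time_to_peak = 1,
               duration = 30),
    burst_spec(background_rate = 500, peak_rate = 500, time_to_peak = 1,
               duration = 30)
  )
  for (spec in specs) {
    expect_identical(first_crossing_minute(spec, 200),
                     riemann_first_crossing(spec, 200))
  }
  # constant 199 never crosses 200; constant 500 crosses immediately
  expect_true(is.na(first_crossing_minute(specs[[6]], 200)))
  expect_identical(first_crossing_minute(specs[[7]], 200), 1L)
  # ne preset is calibrated so minute 2 is the first to reach 200
  expect_identical(first_crossing_minute(event_preset("ne"), 200), 2L)
})

test_that("generation is reproducible and respects degenerate specs", {
  spec <- burst_spec(background_rate = 20, peak_rate = 120, time_to_peak = 5,
                     duration = 10, seed = 11L)
  a <- generate_stream(spec)
  b <- generate_stream(spec)
  expect_identical(a, b)
  f1 <- tempfile(); f2 <- tempfile()
  write_stream(a, f1); write_stream(b, f2)
  expect_identical(readLines(f1), readLines(f2))     # byte-identical NDJSON
  expect_false(identical(a, generate_stream(spec, seed = 12L)))

  zero <- burst_spec(background_rate = 0, peak_rate = 0, time_to_peak = 1,
                     duration = 30)
  expect_identical(nrow(generate_stream(zero)), 0L)

  # generated streams are valid cleaned streams
  out <- read_stream(f1)
  expect_identical(nrow(out$tweets), nrow(a))
  expect_identical(out$stats$malformed_discarded, 0L)
})

test_that("arrival counts are Poisson with the intensity's mean", {
  # flat background 5/min for 60 min: mean total 300
  spec <- burst_spec(background_rate = 5, peak_rate = 5, time_to_peak = 1,
                     duration = 60)
  totals <- vapply(1:200, function(s) nrow(generate_stream(spec, seed = s)), 1L)
  se <- sqrt(300 / 200)
  expect_lt(abs(mean(totals) - 300), 3 * se)

  # dispersion of per-minute counts at rate 100/min: variance/mean near 1
  spec2 <- burst_spec(background_rate = 100, peak_rate = 100, time_to_peak = 1,
                      duration = 5)
  onset <- as.POSIXct("2016-02-07 15:00:00", tz = "UTC")
  counts <- unlist(lapply(1:500, function(s) {
    tw <- generate_stream(spec2, seed = 1000L + s)
    bin_per_minute(tw, onset, 5)$counts
  }))
  expect_length(counts, 2500L)
  disp <- stats::var(counts) / mean(counts)
  expect_gt(disp, 0.9)
  expect_lt(disp, 1.1)
})

test_that("mark distributions are calibrated", {
  spec <- burst_spec(background_rate = 400, peak_rate = 400, time_to_peak = 1,
                     duration = 50, retweet_prob = 0.55, seed = 21L)
  tw <- generate_stream(spec)
  expect_gt(nrow(tw), 19000)
  # retweet share concentrates at the configured 55%
  expect_gt(mean(tw$is_retweet), 0.54)
  expect_lt(mean(tw$is_retweet), 0.56)
  # retweets reference an earlier tweet id
  expect_true(all(is.na(tw$retweeted_id[!tw$is_retweet])))
  linked <- which(!is.na(tw$retweeted_id))
  expect_true(all(match(tw$retweeted_id[linked], tw$tweet_id) < linked))
  # follower counts: heavy-tailed, non-negative, constant within user
  expect_true(all(tw$follower_count >= 0L))
  per_user <- tapply(tw$follower_count, tw$user_id, function(x) length(unique(x)))
  expect_true(all(per_user == 1L))
})

test_that("text generation honours match probabilities", {
  kw <- keyword_sets(c("crash", "explosion"), c("sf", "bayarea"))
  spec <- burst_spec(background_rate = 300, peak_rate = 300, time_to_peak = 1,
                     duration = 40, event_vocab = c("crash", "explosion"),
                     location_vocab = c("sf", "bayarea"),
                     match_prob_event = 0.5, match_prob_location = 0.3,
                     seed = 31L)
  tw <- generate_stream(spec)
  toks <- mcesignal:::tokenize_all(tw$text)
  ev_hit <- vapply(toks, function(tk) any(c("crash", "explosion") %in% tk), TRUE)
  loc_hit <- vapply(toks, function(tk) any(c("sf", "bayarea") %in% tk), TRUE)
  n <- nrow(tw)
  expect_lt(abs(mean(ev_hit) - 0.5), 3 * sqrt(0.25 / n))
  expect_lt(abs(mean(loc_hit) - 0.3), 3 * sqrt(0.21 / n))
  joint <- mcesignal:::joint_match_many(kw, tw$text)
  expect_lt(abs(mean(joint) - 0.15), 4 * sqrt(0.1275 / n))
})

test_that("control generation caps the expected joint-match rate", {
  expect_error(generate_control(event_preset("control-sb50"), 0), "> 0")

  spec <- event_preset("control-sb50", duration = 10)
  kw <- prospective_keywords()
  tw <- generate_control(spec, joint_match_ceiling = 100, seed = 41L)
  expect_gt(nrow(tw), 2000)  # high-volume stream
  matched <- tw[mcesignal:::joint_match_many(kw, tw$text), ]
  onset <- as.POSIXct("2016-02-07 15:00:00", tz = "UTC")
  series <- bin_per_minute(matched, onset, 10)
  # expected matched rate 100/min; far below a 200 tpm alert threshold
  expect_lt(mean(series$counts), 130)
  expect_false(detect_threshold(series, 200)$fired)

  # ceiling above the spec's joint rate leaves the spec untouched;
  # a tight ceiling scales both match probabilities equally
  tight <- event_preset("control-sb50", duration = 5)
  tw2 <- generate_control(tight, joint_match_ceiling = 25, seed = 42L)
  matched2 <- sum(mcesignal:::joint_match_many(kw, tw2$text))
  expect_lt(matched2 / 5, 50)  # expected 25/min

  # zero match probabilities: no matching tweets at all
  nul <- burst_spec(background_rate = 200, peak_rate = 200, time_to_peak = 1,
                    duration = 5, match_prob_event = 0, match_prob_location = 0,
                    location_vocab = character(0), seed = 43L)
  tw3 <- generate_control(nul, joint_match_ceiling = 100)
  expect_identical(sum(mcesignal:::joint_match_many(kw, tw3$text)), 0L)
})

test_that("detector recovers the analytic crossing on strong pulses", {
  # pulse height >= 2x threshold: recovery of the analytic minute is near-certain
  spec <- burst_spec(background_rate = 2, peak_rate = 800, time_to_peak = 10,
                     duration = 4)
  m_star <- first_crossing_minute(spec, 200)
  expect_identical(m_star, 2L)
  onset <- as.POSIXct("2016-02-07 15:00:00", tz = "UTC")
  hits <- vapply(1:200, function(s) {
    tw <- generate_stream(spec, seed = 5000L + s)
    a <- detect_threshold(bin_per_minute(tw, onset, 4), 200)
    identical(a$fire_minute, m_star)
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})
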