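onset_utc <- function(s) as.POSIXct(s, tz = "UTC")

test_that("read_stream dedupes, counts notices and clips pre-onset tweets", {
  tw <- tweet_json("t1")
  path <- write_ndjson(c(tw, tw, limit_json(7L)))
  out <- read_stream(path)
  expect_identical(nrow(out$tweets), 1L)
  expect_identical(out$stats$tweets_kept, 1L)
  expect_identical(out$stats$duplicates_dropped, 1L)
  expect_identical(out$stats$rate_limit_notices, 1L)
  expect_identical(out$stats$rate_limited_missed, 7L)
  expect_true(stats_ledger_ok(out$stats))

  # tweets posted before the event onset are excluded from the sample
  early <- tweet_json("t2", ts = "2016-02-07T14:59:59Z")
  out2 <- read_stream(write_ndjson(early), onset = onset_utc("2016-02-07 15:00:00"))
  expect_identical(nrow(out2$tweets), 0L)
  expect_identical(out2$stats$pre_onset_excluded, 1L)
  expect_true(stats_ledger_ok(out2$stats))
})

test_that("truncated and invalid records are discarded, not fatal", {
  # 251 records: 248 truncated, 3 valid
  good <- vapply(1:3, function(i) tweet_json(paste0("g", i)), "")
  bad <- substr(rep(tweet_json("b"), 248), 1L, 40L)
  path <- write_ndjson(sample(c(good, bad)))
  out <- read_stream(path)
  expect_identical(out$stats$records_read, 251L)
  expect_identical(nrow(out$tweets), 3L)
  expect_identical(out$stats$malformed_discarded, 248L)
  expect_true(stats_ledger_ok(out$stats))

  # valid JSON that is neither tweet nor rate-limit notice is malformed too;
  # so are naive timestamps and negative follower counts
  weird <- c('{"foo": 1}', '[1,2,3]', '"just a string"',
             tweet_json("n1", ts = "2016-02-07 15:00:30"),
             sub('"follower_count":10', '"follower_count":-3', tweet_json("n2")))
  out2 <- read_stream(write_ndjson(c(weird, tweet_json("ok"))))
  expect_identical(out2$stats$malformed_discarded, 5L)
  expect_identical(out2$tweets$tweet_id, "ok")

  expect_error(read_stream(tempfile()), "cannot read")
})

test_that("activity-stream dialect records map onto the flat schema", {
  lines <- c(
    gnip_json("a1", body = "Big explosion in Boston", user = "act9",
              followers = 321L),
    gnip_json("a2", body = "RT news", verb = "share", object_id = "a1")
  )
  out <- read_stream(write_ndjson(lines))
  expect_identical(out$tweets$tweet_id, c("a1", "a2"))
  expect_identical(out$tweets$follower_count[1], 321L)
  expect_identical(out$tweets$user_id[1], "act9")
  expect_false(out$tweets$is_retweet[1])
  expect_true(out$tweets$is_retweet[2])
  expect_identical(out$tweets$retweeted_id[2], "a1")
})

test_that("retweet flag derivation covers all conventions", {
  lines <- c(
    tweet_json("r1", text = "RT @cnn: big news"),              # prefix
    tweet_json("r2", extra = ',"retweeted_id":"r1"'),          # link
    tweet_json("r3", extra = ',"is_retweet":true'),            # explicit
    tweet_json("r4", text = "original thoughts")               # none
  )
  out <- read_stream(write_ndjson(lines))
  expect_identical(out$tweets$is_retweet, c(TRUE, TRUE, TRUE, FALSE))
})

test_that("streams sort stably by time and read back identically", {
  tw <- make_tweets(12L)
  shuffled <- tw[c(5:12, 1:4), ]
  f <- tempfile(fileext = ".ndjson")
  write_stream(shuffled, f)
  out <- read_stream(f)
  expect_identical(out$tweets, tw)       # sorted back, all fields intact
  expect_identical(out$stats$malformed_discarded, 0L)
  expect_identical(out$stats$duplicates_dropped, 0L)

  # idempotence: re-reading the cleaned output changes nothing
  f2 <- tempfile(fileext = ".ndjson")
  write_stream(out$tweets, f2)
  expect_identical(read_stream(f2)$tweets, out$tweets)

  # ties in posted_at keep input order
  tied <- make_tweets(3L)[c(2L, 3L, 1L), ]
  tied$posted_at <- rep(onset_utc("2016-02-07 15:01:00"), 3L)
  f3 <- tempfile(fileext = ".ndjson")
  write_stream(tied, f3)
  expect_identical(read_stream(f3)$tweets$tweet_id, c("t002", "t003", "t001"))
})

test_that("text with JSON metacharacters survives a round trip", {
  tw <- make_tweets(3L)
  tw$text <- c('quote " backslash \\ done', "tab\there", "newline\nhere")
  f <- tempfile(fileext = ".ndjson")
  write_stream(tw, f)
  expect_identical(read_stream(f)$tweets$text, tw$text)
})

test_that("gzip-compressed input is decompressed transparently", {
  f <- tempfile(fileext = ".ndjson.gz")
  con <- gzfile(f, "wt")
  writeLines(c(tweet_json("z1"), tweet_json("z2")), con)
  close(con)
  out <- read_stream(f)
  expect_identical(out$tweets$tweet_id, c("z1", "z2"))
})

test_that("ISO-8601 parsing accepts offsets and rejects naive times", {
  expect_identical(parse_iso8601("2014-08-24T10:20:44Z"),
                   onset_utc("2014-08-24 10:20:44"))
  expect_identical(parse_iso8601("2014-08-24T03:20:44-07:00"),
                   onset_utc("2014-08-24 10:20:44"))
  expect_identical(parse_iso8601("2014-08-24 03:20:44-0700"),
                   onset_utc("2014-08-24 10:20:44"))
  expect_equal(as.numeric(parse_iso8601("2014-08-24T10:20:44.500Z")) %% 60,
               44.5, tolerance = 1e-9)
  expect_true(is.na(parse_iso8601("2014-08-24T10:20:44")))
  expect_true(is.na(parse_iso8601("not a time")))
})

test_that("onset resolution matches the tz database", {
  expect_identical(resolve_onset("2014-08-24 03:20:44", "America/Los_Angeles"),
                   onset_utc("2014-08-24 10:20:44"))
  expect_identical(resolve_onset("2012-12-14 09:35:00", "America/New_York"),
                   onset_utc("2012-12-14 14:35:00"))
  expect_identical(resolve_onset("2013-04-15 14:49:00", "America/New_York"),
                   onset_utc("2013-04-15 18:49:00"))
  # DST gap has no UTC image; fall-back times have two
  expect_error(resolve_onset("2015-03-08 02:30:00", "America/Los_Angeles"),
               "does not exist")
  expect_error(resolve_onset("2015-11-01 01:30:00", "America/Los_Angeles"),
               "ambiguous.*candidates")
  expect_error(resolve_onset("2015-01-01 00:00:00", "Mars/Olympus"),
               "unknown timezone")
})

test_that("event configs validate and resolve their onset", {
  cfg <- event_config("ne", "2014-08-24 03:20:44", "America/Los_Angeles",
                      rules = "Earthquake (Napa OR '6.0')",
                      horizon_minutes = 720,
                      timeline = list(first_911_call = "2014-08-24T10:21:30Z"))
  expect_identical(cfg$onset, onset_utc("2014-08-24 10:20:44"))
  expect_length(cfg$rules, 1L)
  expect_identical(names(cfg$timeline), "first_911_call")

  expect_error(event_config("x", "2014-08-24 03:20:44", "America/Los_Angeles",
                            horizon_minutes = 0), "positive")
  expect_error(
    event_config("x", "2014-08-24 03:20:44", "America/Los_Angeles",
                 timeline = list(early_mark = "2014-08-20T00:00:00Z")),
    "24h before onset")

  # JSON config file round trip
  f <- tempfile(fileext = ".json")
  writeLines('{
    "name": "ne",
    "onset": {"local_time": "2014-08-24 03:20:44", "tz": "America/Los_Angeles"},
    "rules": ["Earthquake (Napa OR \'6.0\')"],
    "horizon_minutes": 60,
    "timeline": {"first_911_call": "2014-08-24T10:21:30Z"}
  }', f)
  cfg2 <- read_event_config(f)
  expect_identical(cfg2$onset, cfg$onset)
  expect_identical(cfg2$horizon_minutes, 60L)
  expect_identical(render_rule(cfg2$rules[[1]]), "earthquake (napa OR '6 0')")
})

test_that("ingest ledger equation holds under random corruption (spot fuzz)", {
  set.seed(404)
  for (rep in 1:5) {
    n <- 120L
    kind <- sample(c("tweet", "dup", "bad", "limit", "early"), n, replace = TRUE,
                   prob = c(0.5, 0.1, 0.2, 0.1, 0.1))
    lines <- character(n)
    for (i in seq_len(n)) {
      lines[i] <- switch(kind[i],
        tweet = tweet_json(paste0("t", i)),
        dup = tweet_json("t-dup"),
        bad = substr(tweet_json(paste0("x", i)), 1L, sample(5:30, 1L)),
        limit = limit_json(sample(0:50, 1L)),
        early = tweet_json(paste0("e", i), ts = "2016-02-07T14:00:00Z"))
    }
    out <- read_stream(write_ndjson(lines),
                       onset = onset_utc("2016-02-07 15:00:00"))
    expect_true(stats_ledger_ok(out$stats))
    expect_identical(out$stats$records_read, n)
    expect_identical(out$stats$tweets_kept,
                     sum(kind == "tweet") + as.integer(any(kind == "dup")))
    expect_identical(out$stats$pre_onset_excluded, sum(kind == "early"))
    expect_identical(out$stats$malformed_discarded, sum(kind == "bad"))
    expect_identical(out$stats$duplicates_dropped,
                     max(0L, sum(kind == "dup") - 1L))
  }
})
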