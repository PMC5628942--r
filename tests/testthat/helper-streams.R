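# Builders for small NDJSON fixtures, constructed in code at test time.

tweet_json <- function(id, ts = "2016-02-07T15:00:30Z", text = "hello world",
                       user = "u1", followers = 10L, extra = "") {
  sprintf('{"id":"%s","posted_at":"%s","text":"%s","user_id":"%s","follower_count":%d%s}',
          id, ts, text, user, followers, extra)
}

limit_json <- function(missed) sprintf('{"limit":{"count":%d}}', missed)

gnip_json <- function(id, ts = "2016-02-07T15:00:30Z", body = "hello",
                      user = "a1", followers = 5L, verb = "post",
                      object_id = NULL) {
  obj <- if (!is.null(object_id)) sprintf(',"object":{"id":"%s"}', object_id) else ""
  sprintf('{"id":"%s","verb":"%s","postedTime":"%s","body":"%s","actor":{"id":"%s","followersCount":%d}%s}',
          id, verb, ts, body, user, followers, obj)
}

write_ndjson <- function(lines, path = tempfile(fileext = ".ndjson")) {
  writeLines(lines, path)
  path
}

# A well-formed synthetic tweet table with mixed marks, for round-trip and
# summary tests.
make_tweets <- function(n = 10L, onset = as.POSIXct("2016-02-07 15:00:00", tz = "UTC")) {
  if (n == 0L) return(mcesignal:::empty_tweets())
  data.frame(
    tweet_id = sprintf("t%03d", seq_len(n)),
    posted_at = onset + seq_len(n) * 13,
    text = paste("message number", seq_len(n)),
    user_id = sprintf("u%02d", (seq_len(n) - 1L) %% 4L + 1L),
    follower_count = as.integer(seq_len(n) * 7L),
    is_retweet = seq_len(n) %% 3L == 0L,
    retweeted_id = ifelse(seq_len(n) %% 3L == 0L, "t001", NA_character_),
    retweet_count = ifelse(seq_len(n) %% 4L == 0L, 5L, 0L),
    geo_lat = ifelse(seq_len(n) %% 5L == 0L, 37.77, NA_real_),
    geo_lon = ifelse(seq_len(n) %% 5L == 0L, -122.42, NA_real_),
    stringsAsFactors = FALSE
  )
}

# "RT @" prefixed texts must keep is_retweet consistent for round-trips.
SAMPLE_ONSET <- as.POSIXct("2016-02-07 15:00:00", tz = "UTC")
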