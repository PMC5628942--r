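## Ingest of newline-delimited JSON tweet streams.
##
## Canonical flat record schema (one JSON object per line):
##   {"id": "...", "posted_at": "2014-08-24T10:21:00Z", "text": "...",
##    "user_id": "...", "follower_count": 120,
##    "is_retweet": false, "retweeted_id": null, "retweet_count": 0,
##    "geo": {"lat": 37.77, "lon": -122.42}}
## A Gnip-style activity-stream dialect (actor/body/verb/postedTime) is
## accepted best-effort. A rate-limit notice is an object whose only payload
## is {"limit": {"count": <n missed>}}. Timestamps must carry an explicit
## UTC offset or trailing Z; naive timestamps are treated as malformed
## because silent local-time guessing corrupts onset-anchored binning.

TWEET_COLUMNS <- c("tweet_id", "posted_at", "text", "user_id",
                   "follower_count", "is_retweet", "retweeted_id",
                   "retweet_count", "geo_lat", "geo_lon")

## Zero-row tweet table with canonical column types.
empty_tweets <- function() {
  data.frame(
    tweet_id = character(0),
    posted_at = as.POSIXct(character(0), tz = "UTC"),
    text = character(0),
    user_id = character(0),
    follower_count = integer(0),
    is_retweet = logical(0),
    retweeted_id = character(0),
    retweet_count = integer(0),
    geo_lat = numeric(0),
    geo_lon = numeric(0),
    stringsAsFactors = FALSE
  )
}

#' Parse ISO-8601 timestamps with an explicit offset
#'
#' Vectorized. Accepts `YYYY-MM-DD[T ]HH:MM:SS[.fff](Z|+HH:MM|+HHMM)`.
#' Timestamps without an explicit offset (naive local times) yield `NA`.
#'
#' @param x Character vector.
#' @return `POSIXct` vector in UTC, `NA` where unparseable.
#' @export
parse_iso8601 <- function(x) {
  x <- as.character(x)
  pat <- paste0("^(\\d{4}-\\d{2}-\\d{2})[Tt ]",
                "(\\d{2}:\\d{2}:\\d{2})(\\.\\d+)?",
                "(Z|z|[+-]\\d{2}:?\\d{2})$")
  ok <- !is.na(x) & grepl(pat, x)
  out <- rep(as.POSIXct(NA, tz = "UTC"), length(x))
  if (!any(ok)) return(out)
  xs <- x[ok]
  date <- sub(pat, "\\1", xs)
  time <- sub(pat, "\\2", xs)
  frac <- sub(pat, "\\3", xs)
  off <- sub(pat, "\\4", xs)
  base <- as.POSIXct(paste(date, time), tz = "UTC")
  fsec <- ifelse(nzchar(frac), as.numeric(frac), 0)
  offsec <- ifelse(off %in% c("Z", "z"), 0, {
    sgn <- ifelse(startsWith(off, "-"), -1, 1)
    hh <- suppressWarnings(as.numeric(substr(off, 2L, 3L)))
    mm <- suppressWarnings(as.numeric(sub("^[+-]\\d{2}:?", "", off)))
    sgn * (hh * 3600 + mm * 60)
  })
  out[ok] <- base + fsec - offsec
  out
}

## ---- Ingest stats ----------------------------------------------------------

ingest_stats <- function(records_read = 0L, tweets_kept = 0L,
                         duplicates_dropped = 0L, malformed_discarded = 0L,
                         rate_limit_notices = 0L, rate_limited_missed = 0L,
                         pre_onset_excluded = 0L, beyond_horizon = 0L) {
  structure(
    list(records_read = as.integer(records_read),
         tweets_kept = as.integer(tweets_kept),
         duplicates_dropped = as.integer(duplicates_dropped),
         malformed_discarded = as.integer(malformed_discarded),
         rate_limit_notices = as.integer(rate_limit_notices),
         rate_limited_missed = as.integer(rate_limited_missed),
         pre_onset_excluded = as.integer(pre_onset_excluded)),
    class = "mce_ingest_stats"
  )
}

#' @export
print.mce_ingest_stats <- function(x, ...) {
  cat("<ingest stats>\n")
  for (f in names(x)) cat(sprintf("  %-20s %d\n", f, x[[f]]))
  invisible(x)
}

#' Check the ingest bookkeeping ledger equation
#'
#' Every input record must be accounted for exactly once:
#' `records_read = tweets_kept + duplicates_dropped + malformed_discarded +
#' rate_limit_notices + pre_onset_excluded`. (`rate_limited_missed` counts
#' tweets the upstream service withheld; those never appear as records.)
#'
#' @param stats An `mce_ingest_stats` object.
#' @return `TRUE` or `FALSE`.
#' @export
stats_ledger_ok <- function(stats) {
  stopifnot(inherits(stats, "mce_ingest_stats"))
  all(vapply(stats, function(v) v >= 0L, TRUE)) &&
    stats$records_read == stats$tweets_kept + stats$duplicates_dropped +
      stats$malformed_discarded + stats$rate_limit_notices +
      stats$pre_onset_excluded
}

## ---- Record extraction ----------------------------------------------------

## Classify one parsed JSON record. Returns a list with $type in
## c("tweet", "limit", "malformed") plus fields.
classify_record <- function(rec) {
  if (!is.list(rec) || is.null(names(rec))) return(list(type = "malformed"))
  if (!is.null(rec$limit)) {
    cnt <- rec$limit$count
    if (is.null(cnt)) cnt <- rec$limit$track
    if (length(cnt) == 1L && is.numeric(cnt) && !is.na(cnt) && cnt >= 0) {
      return(list(type = "limit", missed = as.integer(cnt)))
    }
    return(list(type = "malformed"))
  }
  gnip <- !is.null(rec$actor) || !is.null(rec$postedTime) || !is.null(rec$verb)
  if (gnip) {
    tweet <- list(
      tweet_id = rec$id,
      posted_at_raw = rec$postedTime,
      text = rec$body,
      user_id = rec$actor$id,
      follower_count = rec$actor$followersCount,
      retweeted_id = if (identical(rec$verb, "share")) rec$object$id,
      retweet_count = rec$retweetCount,
      is_retweet_raw = identical(rec$verb, "share"),
      geo = rec$geo$coordinates
    )
  } else {
    tweet <- list(
      tweet_id = rec$id,
      posted_at_raw = rec$posted_at,
      text = rec$text,
      user_id = rec$user_id,
      follower_count = rec$follower_count,
      retweeted_id = rec$retweeted_id,
      retweet_count = rec$retweet_count,
      is_retweet_raw = isTRUE(rec$is_retweet),
      geo = if (!is.null(rec$geo)) c(rec$geo$lat, rec$geo$lon)
    )
  }
  scalar_chr <- function(v) length(v) == 1L && !is.na(v) && nzchar(as.character(v))
  required_ok <- scalar_chr(tweet$tweet_id) &&
    scalar_chr(tweet$posted_at_raw) &&
    length(tweet$text) == 1L && !is.na(tweet$text) &&
    scalar_chr(tweet$user_id) &&
    length(tweet$follower_count) == 1L && is.numeric(tweet$follower_count) &&
    !is.na(tweet$follower_count) && tweet$follower_count >= 0
  if (!required_ok) return(list(type = "malformed"))
  if (!is.null(tweet$retweet_count) &&
      (!is.numeric(tweet$retweet_count) || is.na(tweet$retweet_count) ||
       tweet$retweet_count < 0)) {
    return(list(type = "malformed"))
  }
  tweet$type <- "tweet"
  tweet
}

#' Read and clean a newline-delimited JSON tweet stream
#'
#' Reads an NDJSON file (transparently gunzipped if compressed), validates and
#' classifies every line, deduplicates by tweet id (first occurrence wins),
#' stably sorts by posting time, and optionally clips tweets posted before the
#' event onset. Rate-limit notices contribute their reported missed count to
#' the bookkeeping but yield no tweets; malformed lines (bad JSON, missing
#' required fields, naive timestamps) are counted and skipped.
#'
#' @param path Path to an NDJSON file (optionally gzip-compressed).
#' @param onset Optional `POSIXct` UTC instant; tweets posted strictly before
#'   it are excluded and counted as `pre_onset_excluded`.
#' @return An object of class `mce_stream`: list with `tweets` (data frame,
#'   one row per kept tweet, ordered by `posted_at` with input order breaking
#'   ties) and `stats` (`mce_ingest_stats`).
#' @export
read_stream <- function(path, onset = NULL) {
  if (!file.exists(path)) stop("cannot read stream file: ", path, call. = FALSE)
  if (!is.null(onset)) stopifnot(inherits(onset, "POSIXct"))
  con <- gzfile(path, open = "rt", encoding = "UTF-8")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  n <- length(lines)

  tweet_id <- character(n); posted_raw <- character(n); text <- character(n)
  user_id <- character(n); follower <- integer(n); is_rt <- logical(n)
  rt_id <- rep(NA_character_, n); rt_count <- integer(n)
  geo_lat <- rep(NA_real_, n); geo_lon <- rep(NA_real_, n)
  keep <- logical(n)
  malformed <- 0L; notices <- 0L; missed <- 0L

  for (i in seq_len(n)) {
    rec <- tryCatch(jsonlite::fromJSON(lines[[i]], simplifyVector = FALSE),
                    error = function(e) NULL)
    cl <- if (is.null(rec)) list(type = "malformed") else classify_record(rec)
    if (cl$type == "malformed") {
      malformed <- malformed + 1L
    } else if (cl$type == "limit") {
      notices <- notices + 1L
      missed <- missed + cl$missed
    } else {
      keep[i] <- TRUE
      tweet_id[i] <- as.character(cl$tweet_id)
      posted_raw[i] <- as.character(cl$posted_at_raw)
      text[i] <- as.character(cl$text)
      user_id[i] <- as.character(cl$user_id)
      follower[i] <- as.integer(cl$follower_count)
      rt_id[i] <- if (is.null(cl$retweeted_id)) NA_character_ else as.character(cl$retweeted_id)
      rt_count[i] <- if (is.null(cl$retweet_count)) 0L else as.integer(cl$retweet_count)
      is_rt[i] <- isTRUE(cl$is_retweet_raw) || !is.na(rt_id[i]) ||
        startsWith(text[i], "RT @")
      if (!is.null(cl$geo) && length(cl$geo) == 2L && is.numeric(unlist(cl$geo))) {
        geo_lat[i] <- as.numeric(cl$geo[[1L]])
        geo_lon[i] <- as.numeric(cl$geo[[2L]])
      }
    }
  }

  idx <- which(keep)
  posted_at <- parse_iso8601(posted_raw[idx])
  bad_ts <- is.na(posted_at)
  malformed <- malformed + sum(bad_ts)
  idx <- idx[!bad_ts]
  posted_at <- posted_at[!bad_ts]

  dup <- duplicated(tweet_id[idx])
  duplicates <- sum(dup)
  idx <- idx[!dup]
  posted_at <- posted_at[!dup]

  pre_onset <- 0L
  if (!is.null(onset)) {
    early <- posted_at < onset
    pre_onset <- sum(early)
    idx <- idx[!early]
    posted_at <- posted_at[!early]
  }

  ord <- order(as.numeric(posted_at), seq_along(idx), method = "radix")
  idx <- idx[ord]
  tweets <- data.frame(
    tweet_id = tweet_id[idx],
    posted_at = posted_at[ord],
    text = text[idx],
    user_id = user_id[idx],
    follower_count = follower[idx],
    is_retweet = is_rt[idx],
    retweeted_id = rt_id[idx],
    retweet_count = rt_count[idx],
    geo_lat = geo_lat[idx],
    geo_lon = geo_lon[idx],
    stringsAsFactors = FALSE
  )
  rownames(tweets) <- NULL

  stats <- ingest_stats(
    records_read = n,
    tweets_kept = nrow(tweets),
    duplicates_dropped = duplicates,
    malformed_discarded = malformed,
    rate_limit_notices = notices,
    rate_limited_missed = missed,
    pre_onset_excluded = pre_onset
  )
  structure(list(tweets = tweets, stats = stats), class = "mce_stream")
}

#' @export
print.mce_stream <- function(x, ...) {
  cat(sprintf("<tweet stream> %d tweets", nrow(x$tweets)))
  if (nrow(x$tweets) > 0L) {
    cat(sprintf(" (%s .. %s UTC)",
                format(min(x$tweets$posted_at), "%Y-%m-%d %H:%M:%S"),
                format(max(x$tweets$posted_at), "%Y-%m-%d %H:%M:%S")))
  }
  cat("\n")
  print(x$stats)
  invisible(x)
}

## JSON string escaping for the vectorized NDJSON writer. Control characters
## other than tab/newline/CR (which get named escapes) are replaced by spaces.
json_escape <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\"", "\\\"", x, fixed = TRUE)
  x <- gsub("\n", "\\n", x, fixed = TRUE)
  x <- gsub("\r", "\\r", x, fixed = TRUE)
  x <- gsub("\t", "\\t", x, fixed = TRUE)
  gsub("[\x01-\x1f]", " ", x)
}

#' Write tweets as newline-delimited JSON
#'
#' Emits the canonical flat record schema (one object per line, UTC `Z`
#' timestamps at second precision). `read_stream()` on the result reproduces
#' the input field-for-field.
#'
#' @param tweets Tweet data frame (as produced by [read_stream()] or
#'   [generate_stream()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_stream <- function(tweets, path) {
  stopifnot(is.data.frame(tweets), all(TWEET_COLUMNS %in% names(tweets)))
  ts <- format(tweets$posted_at, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  lines <- sprintf(
    '{"id":"%s","posted_at":"%s","text":"%s","user_id":"%s","follower_count":%d,"is_retweet":%s,"retweet_count":%d',
    json_escape(tweets$tweet_id), ts, json_escape(tweets$text),
    json_escape(tweets$user_id), as.integer(tweets$follower_count),
    ifelse(tweets$is_retweet, "true", "false"),
    as.integer(tweets$retweet_count)
  )
  has_rt <- !is.na(tweets$retweeted_id)
  lines[has_rt] <- paste0(lines[has_rt], ',"retweeted_id":"',
                          json_escape(tweets$retweeted_id[has_rt]), '"')
  has_geo <- !is.na(tweets$geo_lat) & !is.na(tweets$geo_lon)
  lines[has_geo] <- paste0(
    lines[has_geo],
    sprintf(',"geo":{"lat":%.6f,"lon":%.6f}',
            tweets$geo_lat[has_geo], tweets$geo_lon[has_geo])
  )
  lines <- paste0(lines, "}")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

## ---- Event configuration ---------------------------------------------------

#' Resolve a local civil onset time to a UTC instant
#'
#' Converts an event's local onset (civil time plus IANA zone name) to the
#' unique corresponding UTC instant. Times that do not exist (spring-forward
#' gap) or are ambiguous (fall-back repeat) are rejected with an error naming
#' the candidates, since a mass-casualty onset must anchor to exactly one
#' instant.
#'
#' @param x Either an `mce_event_config` or a local time string
#'   `"YYYY-MM-DD HH:MM:SS"`.
#' @param tz IANA zone name (required when `x` is a time string).
#' @return `POSIXct` UTC instant.
#' @examples
#' \dontrun{
#' resolve_onset("2014-08-24 03:20:44", "America/Los_Angeles")
#' }
#' @export
resolve_onset <- function(x, tz = NULL) {
  if (inherits(x, "mce_event_config")) return(x$onset)
  resolve_local_time(x, tz)
}

resolve_local_time <- function(local_time, tz) {
  stopifnot(is.character(local_time), length(local_time) == 1L,
            is.character(tz), length(tz) == 1L)
  if (!tz %in% OlsonNames()) {
    stop("config error: unknown timezone '", tz, "'", call. = FALSE)
  }
  if (!grepl("^\\d{4}-\\d{2}-\\d{2}[T ]\\d{2}:\\d{2}:\\d{2}$", local_time)) {
    stop("config error: onset local time must be 'YYYY-MM-DD HH:MM:SS', got '",
         local_time, "'", call. = FALSE)
  }
  local_time <- sub("T", " ", local_time, fixed = TRUE)
  if (tz %in% c("UTC", "GMT", "Etc/UTC", "Etc/GMT")) {
    return(as.POSIXct(local_time, tz = "UTC"))
  }
  if (!tzdb_works()) {
    stop("config error: timezone database unavailable; cannot resolve '",
         local_time, " ", tz, "'", call. = FALSE)
  }
  # Enumerate the UTC offsets in force around the nominal instant and keep
  # the candidates whose local rendering reproduces the input exactly.
  guess <- as.POSIXct(local_time, tz = "UTC")
  offs <- unique(vapply(c(-86400, 0, 86400),
                        function(d) format(guess + d, "%z", tz = tz), ""))
  off_secs <- vapply(offs, function(o) {
    sgn <- if (startsWith(o, "-")) -1 else 1
    sgn * (as.numeric(substr(o, 2L, 3L)) * 3600 + as.numeric(substr(o, 4L, 5L)) * 60)
  }, 0)
  cand <- guess - off_secs
  hit <- vapply(cand, function(ct)
    identical(format(ct, "%Y-%m-%d %H:%M:%S", tz = tz), local_time), TRUE)
  cand <- unique(cand[hit])
  if (length(cand) == 0L) {
    stop("config error: local time '", local_time, "' does not exist in ", tz,
         " (daylight-saving gap)", call. = FALSE)
  }
  if (length(cand) > 1L) {
    stop("config error: local time '", local_time, "' is ambiguous in ", tz,
         "; UTC candidates: ",
         paste(format(cand, "%Y-%m-%d %H:%M:%S UTC"), collapse = ", "),
         call. = FALSE)
  }
  attr(cand, "tzone") <- "UTC"
  cand
}

#' Construct an event configuration
#'
#' @param name Event name.
#' @param onset_local Local onset time `"YYYY-MM-DD HH:MM:SS"`.
#' @param tz IANA zone name for `onset_local`.
#' @param rules Character vector of filter-rule texts (parsed with
#'   [parse_rule()]), or a list of already-parsed `mce_rule` objects.
#' @param horizon_minutes Positive number of one-minute bins to analyze
#'   (default 720, i.e. the first twelve hours).
#' @param timeline Optional named list/vector of ISO-8601 instants (with
#'   explicit offset) for official marks such as `first_911_call`,
#'   `county_disaster_page`, `hospital_standby`, `first_patient_arrival`.
#'   Marks earlier than 24 h before onset are rejected as implausible.
#' @return An object of class `mce_event_config`.
#' @export
event_config <- function(name, onset_local, tz, rules = list(),
                         horizon_minutes = 720L, timeline = list()) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  horizon_minutes <- as.integer(horizon_minutes)
  if (is.na(horizon_minutes) || horizon_minutes <= 0L) {
    stop("config error: horizon_minutes must be a positive integer", call. = FALSE)
  }
  onset <- resolve_local_time(onset_local, tz)
  if (is.character(rules)) rules <- lapply(rules, parse_rule)
  stopifnot(all(vapply(rules, inherits, TRUE, "mce_rule")))
  marks <- as.POSIXct(character(0), tz = "UTC")
  if (length(timeline) > 0L) {
    if (is.null(names(timeline)) || any(!nzchar(names(timeline)))) {
      stop("config error: timeline marks must be named", call. = FALSE)
    }
    marks <- parse_iso8601(unlist(timeline, use.names = FALSE))
    names(marks) <- names(timeline)
    if (anyNA(marks)) {
      stop("config error: unparseable timeline mark(s): ",
           paste(names(timeline)[is.na(marks)], collapse = ", "), call. = FALSE)
    }
    if (any(marks < onset - 86400)) {
      stop("config error: timeline mark(s) more than 24h before onset: ",
           paste(names(marks)[marks < onset - 86400], collapse = ", "),
           call. = FALSE)
    }
  }
  structure(
    list(name = name, onset_local = onset_local, tz = tz, onset = onset,
         rules = rules, horizon_minutes = horizon_minutes, timeline = marks),
    class = "mce_event_config"
  )
}

#' @export
print.mce_event_config <- function(x, ...) {
  cat(sprintf("<event config> %s\n  onset: %s %s = %s UTC\n  rules: %d; horizon: %d min; timeline marks: %s\n",
              x$name, x$onset_local, x$tz,
              format(x$onset, "%Y-%m-%d %H:%M:%S"),
              length(x$rules), x$horizon_minutes,
              if (length(x$timeline)) paste(names(x$timeline), collapse = ", ")
              else "none"))
  invisible(x)
}

#' Read an event configuration file
#'
#' JSON is the canonical format (YAML is read when the optional `yaml`
#' package is installed). Keys: `name`, `onset` (object with `local_time`
#' and `tz`), `rules` (array of rule strings) or `rules_file` (path,
#' relative to the config file), `horizon_minutes`, `timeline` (object of
#' mark name to ISO-8601 instant).
#'
#' @param path Path to the config file.
#' @return An `mce_event_config`.
#' @export
read_event_config <- function(path) {
  if (!file.exists(path)) stop("cannot read config file: ", path, call. = FALSE)
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("config error: YAML config requires the 'yaml' package; use JSON",
           call. = FALSE)
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  }
  for (key in c("name", "onset")) {
    if (is.null(cfg[[key]])) {
      stop("config error: missing key '", key, "' in ", path, call. = FALSE)
    }
  }
  if (is.null(cfg$onset$local_time) || is.null(cfg$onset$tz)) {
    stop("config error: onset must have local_time and tz", call. = FALSE)
  }
  rules <- cfg$rules
  if (!is.null(cfg$rules_file)) {
    rules <- c(rules, vapply(
      read_rules(file.path(dirname(path), cfg$rules_file)), render_rule, ""))
  }
  event_config(
    name = cfg$name,
    onset_local = cfg$onset$local_time,
    tz = cfg$onset$tz,
    rules = as.character(unlist(rules)),
    horizon_minutes = if (is.null(cfg$horizon_minutes)) 720L else cfg$horizon_minutes,
    timeline = if (is.null(cfg$timeline)) list() else cfg$timeline
  )
}
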