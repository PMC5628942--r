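## Onset-anchored tweets-per-minute aggregation, first-hour cumulative
## milestone statistics, event summaries, and threshold alert detection.
##
## Bin convention (used throughout): bins are 1-based and half-open,
## bin m covers [onset + (m-1)*60 s, onset + m*60 s). "Reached in k minutes"
## means the statistic first holds in bin k. The alert instant is anchored to
## the END of the qualifying bin: in real time the count for a minute is only
## known once that minute completes.

#' Aggregate tweets into an onset-anchored per-minute series
#'
#' @param tweets Tweet data frame (cleaned: no tweets before `onset`).
#' @param onset `POSIXct` UTC event onset.
#' @param horizon_minutes Positive integer; number of one-minute bins.
#' @return An object of class `mce_minute_series`: list with `onset`,
#'   `horizon_minutes`, integer vector `counts` of length `horizon_minutes`,
#'   and `beyond_horizon` (tweets past the horizon, ignored but counted).
#' @examples
#' onset <- as.POSIXct("2014-08-24 10:20:44", tz = "UTC")
#' tw <- data.frame(posted_at = onset + c(0, 59, 60))
#' bin_per_minute(tw, onset, horizon_minutes = 5)$counts
#' @export
bin_per_minute <- function(tweets, onset, horizon_minutes) {
  stopifnot(inherits(onset, "POSIXct"))
  horizon_minutes <- as.integer(horizon_minutes)
  if (is.na(horizon_minutes) || horizon_minutes <= 0L) {
    stop("config error: horizon_minutes must be positive", call. = FALSE)
  }
  secs <- as.numeric(tweets$posted_at) - as.numeric(onset)
  if (any(secs < 0)) {
    stop("bin_per_minute expects a cleaned stream with no pre-onset tweets; ",
         sum(secs < 0), " tweet(s) precede onset", call. = FALSE)
  }
  m <- floor(secs / 60) + 1L
  beyond <- sum(m > horizon_minutes)
  counts <- tabulate(m[m <= horizon_minutes], nbins = horizon_minutes)
  structure(
    list(onset = onset, horizon_minutes = horizon_minutes,
         counts = as.integer(counts), beyond_horizon = as.integer(beyond)),
    class = "mce_minute_series"
  )
}

## Build a series directly from a counts vector (fixtures, tests).
minute_series <- function(counts, onset = as.POSIXct("2000-01-01", tz = "UTC"),
                          beyond_horizon = 0L) {
  counts <- as.integer(counts)
  stopifnot(length(counts) >= 1L, !anyNA(counts), all(counts >= 0L))
  structure(
    list(onset = onset, horizon_minutes = length(counts), counts = counts,
         beyond_horizon = as.integer(beyond_horizon)),
    class = "mce_minute_series"
  )
}

#' @export
print.mce_minute_series <- function(x, ...) {
  cat(sprintf("<minute series> onset %s UTC, %d bins, %d tweets (+%d beyond horizon), peak %d tpm at minute %d\n",
              format(x$onset, "%Y-%m-%d %H:%M:%S"), x$horizon_minutes,
              sum(x$counts), x$beyond_horizon,
              if (sum(x$counts) > 0L) max(x$counts) else 0L,
              if (sum(x$counts) > 0L) which.max(x$counts) else NA_integer_))
  invisible(x)
}

#' First-hour cumulative milestone minutes
#'
#' For each percentage `p`, the milestone minute is the first minute `m` in
#' 1..60 at which the cumulative count reaches `p`% of the first-hour total:
#' `min{m : cum(m) >= (p/100) * cum(60)}` (exact real-valued target, no
#' rounding). `NA` when the first hour is empty.
#'
#' @param series An `mce_minute_series` with horizon >= 60.
#' @param percents Numeric vector of percentages in (0, 100].
#' @return Data frame with columns `percent`, `minute`, `window_total`.
#' @export
milestones <- function(series, percents = c(1, 2, 5, 10, 50, 75, 90, 100)) {
  stopifnot(inherits(series, "mce_minute_series"))
  if (series$horizon_minutes < 60L) {
    stop("milestones require a series horizon of at least 60 minutes",
         call. = FALSE)
  }
  if (any(is.na(percents)) || any(percents <= 0) || any(percents > 100)) {
    stop("config error: milestone percents must lie in (0, 100]", call. = FALSE)
  }
  cum <- cumsum(series$counts[1:60])
  total <- cum[60L]
  minute <- vapply(percents, function(p) {
    if (total == 0L) return(NA_integer_)
    which(cum >= (p / 100) * total)[1L]
  }, integer(1L))
  data.frame(percent = percents, minute = minute, window_total = total)
}

#' Median milestone minute across events
#'
#' Middle order statistic for an odd number of events; for an even number,
#' the mean of the central pair rounded half-up to whole minutes.
#'
#' @param per_event_minutes Named or unnamed numeric vector, one milestone
#'   minute per event.
#' @return Integer median minute.
#' @examples
#' median_across_events(c(bb = 9, sf = 13, ne = 2, mv = 19, sh = 21))
#' @export
median_across_events <- function(per_event_minutes) {
  x <- as.numeric(per_event_minutes)
  if (length(x) == 0L || anyNA(x)) {
    stop("median_across_events requires at least one non-missing minute",
         call. = FALSE)
  }
  x <- sort(x)
  n <- length(x)
  if (n %% 2L == 1L) {
    as.integer(x[(n + 1L) %/% 2L])
  } else {
    as.integer(floor((x[n %/% 2L] + x[n %/% 2L + 1L]) / 2 + 0.5))
  }
}

#' Summarize a filtered event stream
#'
#' Composition and volume statistics: total kept tweets, unique vs retweet
#' fractions, mean followers (per distinct user by default, last observed
#' value per user; per-tweet variant via `followers_per`), mean retweet count
#' over tweets that were retweeted at least once, and peak tweets-per-minute
#' within the first hour and overall.
#'
#' @param tweets Tweet data frame.
#' @param series The matching `mce_minute_series`.
#' @param followers_per `"user"` (default) or `"tweet"`.
#' @return An object of class `mce_event_summary`.
#' @export
summarize_event <- function(tweets, series, followers_per = c("user", "tweet")) {
  stopifnot(inherits(series, "mce_minute_series"))
  followers_per <- match.arg(followers_per)
  n <- nrow(tweets)
  retweet_fraction <- if (n > 0L) mean(tweets$is_retweet) else NA_real_
  mean_followers <- if (n == 0L) {
    NA_real_
  } else if (followers_per == "user") {
    last <- !duplicated(tweets$user_id, fromLast = TRUE)
    mean(tweets$follower_count[last])
  } else {
    mean(tweets$follower_count)
  }
  retweeted <- tweets$retweet_count > 0L
  mean_retweets <- if (any(retweeted)) mean(tweets$retweet_count[retweeted]) else NA_real_
  first60 <- series$counts[seq_len(min(60L, series$horizon_minutes))]
  structure(
    list(
      total_tweets = n,
      unique_fraction = if (n > 0L) 1 - retweet_fraction else NA_real_,
      retweet_fraction = retweet_fraction,
      mean_followers = mean_followers,
      mean_retweets_of_retweeted = mean_retweets,
      peak_tpm_60 = if (length(first60)) max(first60) else 0L,
      peak_tpm_overall = if (sum(series$counts) > 0L) max(series$counts) else 0L,
      peak_minute_overall = if (sum(series$counts) > 0L) which.max(series$counts) else NA_integer_
    ),
    class = "mce_event_summary"
  )
}

#' @export
print.mce_event_summary <- function(x, ...) {
  cat("<event summary>\n")
  cat(sprintf("  total tweets        %d\n", x$total_tweets))
  cat(sprintf("  unique / retweet    %s / %s\n",
              format_prop(x$unique_fraction), format_prop(x$retweet_fraction)))
  cat(sprintf("  mean followers      %s\n",
              if (is.na(x$mean_followers)) "NA" else sprintf("%.1f", x$mean_followers)))
  cat(sprintf("  mean retweet count  %s\n",
              if (is.na(x$mean_retweets_of_retweeted)) "NA"
              else sprintf("%.1f", x$mean_retweets_of_retweeted)))
  cat(sprintf("  peak tpm (60m/all)  %d / %d (minute %s)\n",
              x$peak_tpm_60, x$peak_tpm_overall,
              ifelse(is.na(x$peak_minute_overall), "NA",
                     as.character(x$peak_minute_overall))))
  invisible(x)
}

format_prop <- function(p) if (is.na(p)) "NA" else sprintf("%.4f", p)

#' Detect a tweets-per-minute threshold crossing
#'
#' The alert fires at the first minute whose count reaches the threshold
#' (optionally requiring `window` consecutive qualifying minutes). The alert
#' instant is the end of the qualifying bin, and lead times against official
#' timeline marks are `mark_instant - fire_instant` in seconds (positive when
#' the alert precedes the mark).
#'
#' @param series An `mce_minute_series`.
#' @param threshold_tpm Positive integer threshold (tweets per minute).
#' @param timeline Optional named `POSIXct` vector of timeline marks.
#' @param window Number of consecutive bins that must each reach the
#'   threshold (default 1, a single bin).
#' @return An object of class `mce_alert`: `threshold_tpm`, `fired`,
#'   `fire_minute`, `fire_instant`, `lead_times` (named seconds).
#' @export
detect_threshold <- function(series, threshold_tpm, timeline = NULL, window = 1L) {
  stopifnot(inherits(series, "mce_minute_series"))
  threshold_tpm <- as.integer(threshold_tpm)
  window <- as.integer(window)
  if (is.na(threshold_tpm) || threshold_tpm < 1L) {
    stop("config error: threshold_tpm must be >= 1", call. = FALSE)
  }
  if (is.na(window) || window < 1L) {
    stop("config error: window must be >= 1", call. = FALSE)
  }
  qual <- series$counts >= threshold_tpm
  fire_minute <- NA_integer_
  if (window == 1L) {
    hit <- which(qual)
    if (length(hit)) fire_minute <- hit[1L]
  } else if (length(qual) >= window) {
    runs <- stats::filter(as.numeric(qual), rep(1, window), sides = 1)
    hit <- which(!is.na(runs) & runs == window)
    if (length(hit)) fire_minute <- hit[1L] # alert known at end of the run
  }
  fired <- !is.na(fire_minute)
  fire_instant <- if (fired) series$onset + fire_minute * 60 else as.POSIXct(NA, tz = "UTC")
  lead <- numeric(0)
  if (!is.null(timeline) && length(timeline) > 0L) {
    stopifnot(inherits(timeline, "POSIXct"), !is.null(names(timeline)))
    lead <- if (fired) as.numeric(timeline) - as.numeric(fire_instant)
            else rep(NA_real_, length(timeline))
    names(lead) <- names(timeline)
  }
  structure(
    list(threshold_tpm = threshold_tpm, window = window, fired = fired,
         fire_minute = fire_minute, fire_instant = fire_instant,
         lead_times = lead),
    class = "mce_alert"
  )
}

#' @export
print.mce_alert <- function(x, ...) {
  if (x$fired) {
    cat(sprintf("<alert> threshold %d tpm FIRED at minute %d (%s UTC)\n",
                x$threshold_tpm, x$fire_minute,
                format(x$fire_instant, "%Y-%m-%d %H:%M:%S")))
  } else {
    cat(sprintf("<alert> threshold %d tpm did not fire\n", x$threshold_tpm))
  }
  for (nm in names(x$lead_times)) {
    lt <- x$lead_times[[nm]]
    cat(sprintf("  lead vs %-22s %s\n", nm,
                if (is.na(lt)) "NA" else sprintf("%+.1f min", lt / 60)))
  }
  invisible(x)
}

#' Fraction of total collected volume inside the first hour
#'
#' `cum(60) / cum(end)` over the whole series (tweets beyond the horizon are
#' included in the denominator); `NA` when the series is empty.
#'
#' @param series An `mce_minute_series` covering the full collection period.
#' @return Proportion in `[0, 1]`, or `NA`.
#' @export
first_hour_fraction <- function(series) {
  stopifnot(inherits(series, "mce_minute_series"))
  total <- sum(series$counts) + series$beyond_horizon
  if (total == 0L) return(NA_real_)
  sum(series$counts[seq_len(min(60L, series$horizon_minutes))]) / total
}
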