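## Synthetic tweet-stream generator.
##
## Events are drawn from an inhomogeneous Poisson process whose intensity is
## a flat background plus a single-timescale gamma-like pulse:
##
##   lambda(t) = background + (peak - background) * (t/tau) * exp(1 - t/tau)
##
## (t in minutes since onset, tau = time_to_peak). The pulse vanishes at
## t = 0, attains its maximum `peak_rate` exactly at t = tau, and decays
## smoothly - the qualitative signature of mass-casualty event streams:
## near-immediate first tweets, a peak within a few hours, then decline.
## An optional dead time d models delayed signal initiation (intensity is
## zero for the first d minutes, the pulse clock starts at d). Retweet flags
## are i.i.d. marks, follower counts are log-normal per user, and text is
## bag-of-words from event/location/decoy vocabularies.

#' Specify a synthetic burst stream
#'
#' @param background_rate Background chatter rate, tweets/min (>= 0).
#' @param peak_rate Maximum intensity, tweets/min (>= background; zero gives
#'   an empty stream).
#' @param time_to_peak Minutes from (effective) onset to the intensity
#'   maximum (> 0).
#' @param duration Minutes of stream to generate (> 0).
#' @param dead_time Minutes of zero intensity before the signal starts
#'   (default 0); models delayed signal initiation.
#' @param retweet_prob Probability a tweet is a retweet (default 0.55, the
#'   observed retweet share of historical event streams).
#' @param follower_log_mean,follower_log_sd Log-scale parameters of the
#'   per-user log-normal follower-count distribution. Defaults imply a
#'   heavy-tailed mean of ~4.1k, inside the observed 3382--9992 per-event
#'   range.
#' @param mean_retweet_count Mean retweet count assigned to original tweets
#'   that get retweeted (default 200, inside the observed 82--564 range).
#' @param event_vocab,location_vocab,decoy_vocab Word/phrase vocabularies;
#'   event and location entries may be multi-word snippets.
#' @param match_prob_event,match_prob_location Independent probabilities that
#'   a tweet's text carries >= 1 event / location vocabulary entry.
#' @param seed Integer seed; the stream is fully reproducible from it.
#' @return An object of class `mce_burst_spec`.
#' @export
burst_spec <- function(background_rate = 5,
                       peak_rate = 200,
                       time_to_peak = 10,
                       duration = 60,
                       dead_time = 0,
                       retweet_prob = 0.55,
                       follower_log_mean = 7.2,
                       follower_log_sd = 1.5,
                       mean_retweet_count = 200,
                       event_vocab = c("crash", "explosion"),
                       location_vocab = c("sf", "bayarea"),
                       decoy_vocab = DEFAULT_DECOY_VOCAB,
                       match_prob_event = 1,
                       match_prob_location = 0,
                       seed = 1L) {
  stopifnot(
    is.numeric(background_rate), background_rate >= 0,
    is.numeric(peak_rate), peak_rate >= 0, peak_rate >= background_rate,
    is.numeric(time_to_peak), time_to_peak > 0,
    is.numeric(duration), duration > 0,
    is.numeric(dead_time), dead_time >= 0,
    is.numeric(retweet_prob), retweet_prob >= 0, retweet_prob <= 1,
    is.numeric(match_prob_event), match_prob_event >= 0, match_prob_event <= 1,
    is.numeric(match_prob_location), match_prob_location >= 0,
    match_prob_location <= 1,
    is.numeric(mean_retweet_count), mean_retweet_count >= 0,
    is.character(decoy_vocab), length(decoy_vocab) >= 1L
  )
  if (match_prob_event > 0 && length(event_vocab) == 0L) {
    stop("config error: event_vocab empty but match_prob_event > 0", call. = FALSE)
  }
  if (match_prob_location > 0 && length(location_vocab) == 0L) {
    stop("config error: location_vocab empty but match_prob_location > 0",
         call. = FALSE)
  }
  structure(
    list(background_rate = background_rate, peak_rate = peak_rate,
         time_to_peak = time_to_peak, duration = duration,
         dead_time = dead_time, retweet_prob = retweet_prob,
         follower_log_mean = follower_log_mean,
         follower_log_sd = follower_log_sd,
         mean_retweet_count = mean_retweet_count,
         event_vocab = as.character(event_vocab),
         location_vocab = as.character(location_vocab),
         decoy_vocab = as.character(decoy_vocab),
         match_prob_event = match_prob_event,
         match_prob_location = match_prob_location,
         seed = as.integer(seed)),
    class = "mce_burst_spec"
  )
}

#' @export
print.mce_burst_spec <- function(x, ...) {
  cat(sprintf("<burst spec> background %.1f/min, peak %.1f/min at %.1f min%s, duration %.0f min, retweet p=%.2f, seed %d\n",
              x$background_rate, x$peak_rate, x$time_to_peak,
              if (x$dead_time > 0) sprintf(" (+%.0f min dead time)", x$dead_time) else "",
              x$duration, x$retweet_prob, x$seed))
  invisible(x)
}

## Generic filler words, disjoint from every packaged rule/keyword vocabulary
## so decoy text can never satisfy a filter by accident.
DEFAULT_DECOY_VOCAB <- c(
  "the", "a", "of", "to", "and", "in", "on", "for", "with", "about",
  "today", "tonight", "morning", "coffee", "lunch", "dinner", "weather",
  "sunny", "cloudy", "music", "movie", "game", "team", "score", "photo",
  "love", "happy", "great", "nice", "weekend", "friday", "monday", "work",
  "home", "traffic", "commute", "dog", "cat", "birthday", "party", "concert",
  "book", "reading", "running", "gym", "recipe", "cooking", "garden", "rain"
)

#' Expected intensity of the synthetic burst process
#'
#' \eqn{\lambda(t) = b + (p - b)\,(t'/\tau)\exp(1 - t'/\tau)} with
#' \eqn{t' = t - d} (dead time), zero for \eqn{t < d}.
#'
#' @param t Minutes since onset (vectorized, >= 0).
#' @param spec An `mce_burst_spec`.
#' @return Expected tweets/min at `t`.
#' @export
intensity <- function(t, spec) {
  stopifnot(inherits(spec, "mce_burst_spec"), is.numeric(t))
  if (any(t < 0)) stop("intensity is defined for t >= 0 only", call. = FALSE)
  tp <- t - spec$dead_time
  lam <- numeric(length(t))
  live <- tp >= 0
  x <- tp[live] / spec$time_to_peak
  lam[live] <- spec$background_rate +
    (spec$peak_rate - spec$background_rate) * x * exp(1 - x)
  lam
}

## Closed-form integral of the pulse term over [0, t'] (t' minutes past dead
## time): A * tau * e * (1 - (1 + x) exp(-x)), x = t'/tau. Total pulse mass
## as t' -> Inf is A * tau * e.
pulse_mass <- function(tprime, spec) {
  a <- spec$peak_rate - spec$background_rate
  x <- pmax(tprime, 0) / spec$time_to_peak
  a * spec$time_to_peak * exp(1) * (1 - (1 + x) * exp(-x))
}

## Expected count on [t1, t2] minutes since onset (closed form).
expected_count <- function(t1, t2, spec) {
  live1 <- pmax(t1, spec$dead_time)
  live2 <- pmax(t2, spec$dead_time)
  spec$background_rate * pmax(live2 - live1, 0) +
    pulse_mass(live2 - spec$dead_time, spec) -
    pulse_mass(live1 - spec$dead_time, spec)
}

#' Analytic first threshold-crossing minute
#'
#' The smallest integer minute `m` whose expected count
#' \eqn{\int_{m-1}^{m} \lambda(t)\,dt} reaches the threshold; `NA` when no
#' bin within the duration qualifies. Serves as ground truth for detector
#' recovery tests on generated streams.
#'
#' @param spec An `mce_burst_spec`.
#' @param threshold_tpm Threshold in tweets/min.
#' @return Integer minute or `NA`.
#' @export
first_crossing_minute <- function(spec, threshold_tpm) {
  stopifnot(inherits(spec, "mce_burst_spec"), is.numeric(threshold_tpm),
            threshold_tpm > 0)
  for (m in seq_len(floor(spec$duration))) {
    if (expected_count(m - 1, m, spec) >= threshold_tpm) return(m)
  }
  NA_integer_
}

#' Generate a synthetic tweet stream
#'
#' Draws arrival times by thinning a homogeneous Poisson process at the
#' intensity maximum, then attaches marks: retweet flags (i.i.d.
#' `retweet_prob`), per-user log-normal follower counts, retweet counts, and
#' bag-of-words text containing at least one event-vocabulary entry with
#' probability `match_prob_event` and at least one location entry with
#' probability `match_prob_location` (independent), padded with decoy words.
#' Identical spec and seed give byte-identical output.
#'
#' @param spec An `mce_burst_spec`.
#' @param onset `POSIXct` UTC instant mapped to t = 0.
#' @param seed Optional integer overriding `spec$seed`.
#' @return Tweet data frame in [read_stream()] column layout, ordered by
#'   posting time.
#' @export
generate_stream <- function(spec, onset = as.POSIXct("2016-02-07 15:00:00", tz = "UTC"),
                            seed = NULL) {
  stopifnot(inherits(spec, "mce_burst_spec"), inherits(onset, "POSIXct"))
  if (is.null(seed)) seed <- spec$seed
  old_seed <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(restore_seed(old_seed), add = TRUE)
  set.seed(seed)

  lambda_max <- max(spec$peak_rate, spec$background_rate)
  if (lambda_max == 0) return(empty_tweets())
  n_cand <- stats::rpois(1L, lambda_max * spec$duration)
  times <- sort(stats::runif(n_cand, 0, spec$duration))
  keep <- stats::runif(n_cand) < intensity(times, spec) / lambda_max
  times <- times[keep]
  n <- length(times)
  if (n == 0L) return(empty_tweets())

  # user pool ~70% of stream size: some users post repeatedly
  n_users <- max(1L, ceiling(0.7 * n))
  followers_by_user <- pmax(0L, as.integer(round(
    stats::rlnorm(n_users, spec$follower_log_mean, spec$follower_log_sd))))
  user_idx <- sample.int(n_users, n, replace = TRUE)

  is_rt <- stats::runif(n) < spec$retweet_prob
  # retweets point at a random earlier tweet when one exists
  rt_id <- rep(NA_character_, n)
  which_rt <- which(is_rt & seq_len(n) > 1L)
  if (length(which_rt)) {
    src <- vapply(which_rt, function(i) sample.int(i - 1L, 1L), 1L)
    rt_id[which_rt] <- sprintf("s%08d", src)
  }
  is_rt[is_rt & seq_len(n) == 1L] <- FALSE
  # originals that themselves got retweeted carry a heavy retweet count
  rt_count <- integer(n)
  orig <- which(!is_rt)
  if (length(orig)) {
    amplified <- stats::runif(length(orig)) < 0.3
    rt_count[orig[amplified]] <-
      stats::rpois(sum(amplified), spec$mean_retweet_count)
  }

  text <- build_texts(n, spec)
  text[is_rt] <- paste0("RT @u", user_idx[is_rt], ": ", text[is_rt])

  tweets <- data.frame(
    tweet_id = sprintf("s%08d", seq_len(n)),
    # whole seconds: the NDJSON interchange format carries second precision
    posted_at = onset + round(times * 60),
    text = text,
    user_id = sprintf("u%06d", user_idx),
    follower_count = followers_by_user[user_idx],
    is_retweet = is_rt,
    retweeted_id = rt_id,
    retweet_count = rt_count,
    geo_lat = rep(NA_real_, n),
    geo_lon = rep(NA_real_, n),
    stringsAsFactors = FALSE
  )
  rownames(tweets) <- NULL
  tweets
}

restore_seed <- function(old_seed) {
  if (is.null(old_seed)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old_seed, envir = globalenv())
  }
}

## Vectorized bag-of-words text assembly.
build_texts <- function(n, spec) {
  n_decoy <- 4L
  mat <- matrix(sample(spec$decoy_vocab, n * n_decoy, replace = TRUE),
                nrow = n)
  ev <- rep("", n)
  take_ev <- stats::runif(n) < spec$match_prob_event
  if (any(take_ev)) {
    ev[take_ev] <- sample(spec$event_vocab, sum(take_ev), replace = TRUE)
  }
  loc <- rep("", n)
  take_loc <- stats::runif(n) < spec$match_prob_location
  if (any(take_loc)) {
    loc[take_loc] <- sample(spec$location_vocab, sum(take_loc), replace = TRUE)
  }
  txt <- paste(mat[, 1L], mat[, 2L], ev, mat[, 3L], loc, mat[, 4L])
  gsub(" +", " ", trimws(txt))
}

#' Generate a high-volume control stream with a capped joint-match rate
#'
#' Emulates prospective monitoring of a high-profile public gathering: total
#' volume may far exceed an alert threshold, but the expected rate of tweets
#' passing the joint event+location filter stays at or below
#' `joint_match_ceiling`. When the spec's expected joint rate
#' (rate x match_prob_event x match_prob_location) exceeds the ceiling, both
#' match probabilities are scaled down equally so the expected joint rate
#' equals the ceiling.
#'
#' @param spec An `mce_burst_spec` (typically flat: peak = background).
#' @param joint_match_ceiling Maximum expected matched tweets/min (> 0).
#' @param onset,seed Passed to [generate_stream()].
#' @return Tweet data frame.
#' @export
generate_control <- function(spec, joint_match_ceiling,
                             onset = as.POSIXct("2016-02-07 15:00:00", tz = "UTC"),
                             seed = NULL) {
  stopifnot(inherits(spec, "mce_burst_spec"))
  if (!is.numeric(joint_match_ceiling) || joint_match_ceiling <= 0) {
    stop("config error: joint_match_ceiling must be > 0", call. = FALSE)
  }
  top_rate <- max(spec$peak_rate, spec$background_rate)
  joint_peak <- top_rate * spec$match_prob_event * spec$match_prob_location
  if (joint_peak > joint_match_ceiling) {
    shrink <- sqrt(joint_match_ceiling / joint_peak)
    spec$match_prob_event <- spec$match_prob_event * shrink
    spec$match_prob_location <- spec$match_prob_location * shrink
  }
  generate_stream(spec, onset = onset, seed = seed)
}

## ---- Calibrated presets ----------------------------------------------------

#' Calibrated synthetic stream presets
#'
#' Five event-like presets reproduce the published first-hour peak rates of
#' the historical case studies (bb 3326, sf 1423, mv 957, ne 739, sh 209
#' tweets/min); rise times are fast (peak within the first hour) and the sh
#' preset adds a 20-minute dead time for its delayed signal initiation. Two
#' control presets emulate prospective monitoring: `control-sb50` (high
#' total volume, expected joint-match rate 100/min) and `control-chp`
#' (an embedded low-casualty incident whose matched burst stays below
#' 200/min). Event-preset text is generated to satisfy the corresponding
#' packaged filter rules.
#'
#' @param name One of `"bb"`, `"sf"`, `"mv"`, `"ne"`, `"sh"`,
#'   `"control-sb50"`, `"control-chp"`.
#' @param duration Optional override of the generated duration in minutes
#'   (the defaults cover the first hour).
#' @return An `mce_burst_spec`.
#' @export
event_preset <- function(name, duration = NULL) {
  presets <- list(
    bb = list(background = 2, peak = 3326, tau = 25, dead = 0,
              event_vocab = c("bomb boston", "boston explosion",
                              "bomb marathon finish line")),
    sf = list(background = 2, peak = 1423, tau = 20, dead = 0,
              event_vocab = c("plane crash", "asiana crash", "plane sfo")),
    mv = list(background = 2, peak = 957, tau = 20, dead = 0,
              event_vocab = c("school shooting", "marysville shooting",
                              "school gunman")),
    ne = list(background = 1, peak = 739, tau = 5, dead = 0,
              event_vocab = c("earthquake napa", "earthquake 6.0")),
    sh = list(background = 0.5, peak = 209, tau = 3, dead = 20,
              event_vocab = c("school shooting", "newtown shooting",
                              "school gunman"))
  )
  if (name %in% names(presets)) {
    p <- presets[[name]]
    return(burst_spec(
      background_rate = p$background, peak_rate = p$peak,
      time_to_peak = p$tau, dead_time = p$dead,
      duration = if (is.null(duration)) 60 else duration,
      event_vocab = p$event_vocab,
      location_vocab = "city",
      match_prob_event = 1, match_prob_location = 0,
      seed = 1L
    ))
  }
  if (name == "control-sb50") {
    # flat 250/min; joint-match probability 0.8 * 0.5 = 0.4 -> expected
    # matched rate 100/min, half the 200 tpm alert threshold
    return(burst_spec(
      background_rate = 250, peak_rate = 250, time_to_peak = 1,
      duration = if (is.null(duration)) 30 else duration,
      event_vocab = c("breaking", "news", "pray", "crash"),
      location_vocab = c("sf", "bayarea", "sanfrancisco", "norcal"),
      match_prob_event = 0.8, match_prob_location = 0.5,
      seed = 1L
    ))
  }
  if (name == "control-chp") {
    # two-hour window around a single-victim incident: every tweet carries
    # joint-matching text but the matched burst peaks at 150/min < 200
    return(burst_spec(
      background_rate = 50, peak_rate = 150, time_to_peak = 15,
      duration = if (is.null(duration)) 120 else duration,
      event_vocab = c("stabbing", "stabbed", "attack"),
      location_vocab = c("sf", "sanfrancisco"),
      match_prob_event = 1, match_prob_location = 1,
      seed = 1L
    ))
  }
  stop("unknown preset: ", name, call. = FALSE)
}
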