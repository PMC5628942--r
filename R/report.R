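## Reporting layer: end-to-end event analysis, alert detection, stream
## simulation, and cross-event median tables, each leaving a reloadable run
## manifest beside its outputs.
##
## Output formatting is fixed for diff-stable tests: minutes as integers,
## proportions to 4 decimals, rates to 1 decimal.

PKG_VERSION <- function() as.character(utils::packageVersion("mcesignal"))

## ---- Packaged reference tables ---------------------------------------------

#' Published per-event reference statistics
#'
#' Printed summary numbers for the five historical mass-casualty case
#' studies: total collected tweets over seven days, peak tweets/min in the
#' first hour, the minute a 200 tpm threshold was reached (where published),
#' and the local onset time with its zone.
#'
#' @return Data frame, one row per event.
#' @export
reference_stats <- function() {
  path <- system.file("extdata", "event_reference_stats.csv",
                      package = "mcesignal", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Published first-hour milestone minutes
#'
#' The per-event minutes at which cumulative first-hour volume reached each
#' percentage threshold, plus the published cross-event median column.
#'
#' @return Data frame with columns `percent`, `bb`, `sf`, `ne`, `mv`, `sh`,
#'   `median`.
#' @export
reference_milestones <- function() {
  path <- system.file("extdata", "event_milestones.csv",
                      package = "mcesignal", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Cross-event median milestone table
#'
#' Recomputes the median column of a per-event milestone table with
#' [median_across_events()].
#'
#' @param milestone_table Data frame with a `percent` column and one column
#'   of milestone minutes per event (defaults to the packaged reference
#'   table; a published `median` column, if present, is ignored as input).
#' @return Data frame `percent`, per-event columns, recomputed `median`.
#' @export
report_medians <- function(milestone_table = reference_milestones()) {
  stopifnot(is.data.frame(milestone_table), "percent" %in% names(milestone_table))
  events <- setdiff(names(milestone_table), c("percent", "median"))
  if (length(events) == 0L) {
    stop("milestone table has no event columns", call. = FALSE)
  }
  out <- milestone_table[c("percent", events)]
  out$median <- vapply(seq_len(nrow(out)), function(i)
    median_across_events(unlist(out[i, events])), integer(1L))
  out
}

## ---- Manifests -------------------------------------------------------------

write_manifest <- function(out_dir, command, inputs, params, outputs, seed = NULL) {
  manifest <- list(
    tool = "mcesignal", version = PKG_VERSION(), command = command,
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    inputs = as.list(inputs), params = params,
    seed = seed, outputs = as.list(outputs)
  )
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Re-run a recorded pipeline command from its manifest
#'
#' Re-executes the command a manifest records, writing into `out_dir`
#' (default: the manifest's own directory, overwriting the original
#' outputs). Numeric outputs are reproduced byte-identically for fixed
#' inputs and seed.
#'
#' @param manifest_path Path to a `manifest.json`.
#' @param out_dir Output directory.
#' @return The re-run's result, invisibly.
#' @export
rerun_manifest <- function(manifest_path, out_dir = dirname(manifest_path)) {
  m <- jsonlite::fromJSON(manifest_path, simplifyVector = TRUE,
                          simplifyDataFrame = FALSE)
  switch(m$command,
    analyze = run_analyze(config = m$inputs$config,
                          stream_paths = unlist(m$inputs$streams),
                          out_dir = out_dir,
                          threshold = m$params$threshold),
    detect = run_detect(config = m$inputs$config,
                        stream_paths = unlist(m$inputs$streams),
                        out_dir = out_dir,
                        threshold = m$params$threshold,
                        window = m$params$window),
    simulate = run_simulate(preset = m$params$preset,
                            spec_path = m$inputs$spec,
                            out_path = file.path(out_dir, basename(m$outputs$stream)),
                            seed = m$seed,
                            duration = m$params$duration),
    stop("manifest records unknown command: ", m$command, call. = FALSE)
  )
}

## ---- Shared plumbing -------------------------------------------------------

## Read and merge one or more NDJSON stream files: per-file cleaning, then
## cross-file dedupe (first occurrence wins) and a stable re-sort.
read_streams <- function(paths, onset = NULL) {
  stopifnot(length(paths) >= 1L)
  parts <- lapply(paths, read_stream, onset = onset)
  tweets <- do.call(rbind, lapply(parts, `[[`, "tweets"))
  agg <- ingest_stats()
  for (p in parts) for (f in names(agg)) agg[[f]] <- agg[[f]] + p$stats[[f]]
  dup <- duplicated(tweets$tweet_id)
  agg$duplicates_dropped <- agg$duplicates_dropped + sum(dup)
  agg$tweets_kept <- agg$tweets_kept - sum(dup)
  tweets <- tweets[!dup, , drop = FALSE]
  ord <- order(as.numeric(tweets$posted_at), seq_len(nrow(tweets)),
               method = "radix")
  tweets <- tweets[ord, , drop = FALSE]
  rownames(tweets) <- NULL
  structure(list(tweets = tweets, stats = agg), class = "mce_stream")
}

as_config <- function(config) {
  if (inherits(config, "mce_event_config")) config else read_event_config(config)
}

## Filter a merged stream by an event's rules (no rules = keep everything).
filter_by_rules <- function(tweets, rules) {
  if (length(rules) == 0L || nrow(tweets) == 0L) return(tweets)
  keep <- matches_any_many(rules, tweets$text)
  out <- tweets[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

fmt_minutes <- function(m) ifelse(is.na(m), NA_integer_, as.integer(m))

## ---- Commands --------------------------------------------------------------

#' Analyze an event stream end-to-end
#'
#' Reads and cleans the stream files, filters by the event's rules, bins
#' tweets per minute from onset, and writes `minute_series.csv`,
#' `milestones.csv`, `summary.json` and `manifest.json` into `out_dir`.
#'
#' @param config An `mce_event_config` or path to a config file.
#' @param stream_paths Character vector of NDJSON stream files.
#' @param out_dir Output directory (created if needed).
#' @param threshold Alert threshold recorded in the summary (default 200
#'   tweets/min).
#' @return Invisibly, a list with `series`, `milestones`, `summary`,
#'   `stats`, `alert`.
#' @export
run_analyze <- function(config, stream_paths, out_dir, threshold = 200L) {
  cfg <- as_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stream <- read_streams(stream_paths, onset = cfg$onset)
  kept <- filter_by_rules(stream$tweets, cfg$rules)
  series <- bin_per_minute(kept, cfg$onset, cfg$horizon_minutes)
  mst <- if (cfg$horizon_minutes >= 60L) milestones(series) else NULL
  summ <- summarize_event(kept, series)
  alert <- detect_threshold(series, threshold, timeline = cfg$timeline)

  series_csv <- file.path(out_dir, "minute_series.csv")
  utils::write.csv(
    data.frame(minute = seq_len(series$horizon_minutes), count = series$counts),
    series_csv, row.names = FALSE)
  outputs <- list(series = basename(series_csv))
  if (!is.null(mst)) {
    mst_csv <- file.path(out_dir, "milestones.csv")
    utils::write.csv(
      data.frame(percent = mst$percent, minute = fmt_minutes(mst$minute),
                 window_total = mst$window_total),
      mst_csv, row.names = FALSE)
    outputs$milestones <- basename(mst_csv)
  }
  summary_json <- file.path(out_dir, "summary.json")
  jsonlite::write_json(
    list(event = cfg$name,
         onset_utc = format(cfg$onset, "%Y-%m-%dT%H:%M:%SZ"),
         total_tweets = summ$total_tweets,
         unique_fraction = round_or_null(summ$unique_fraction, 4),
         retweet_fraction = round_or_null(summ$retweet_fraction, 4),
         mean_followers = round_or_null(summ$mean_followers, 1),
         mean_retweets_of_retweeted = round_or_null(summ$mean_retweets_of_retweeted, 1),
         peak_tpm_60 = summ$peak_tpm_60,
         peak_tpm_overall = summ$peak_tpm_overall,
         peak_minute_overall = na_to_null(summ$peak_minute_overall),
         first_hour_fraction = round_or_null(first_hour_fraction(series), 4),
         ingest_stats = unclass(stream$stats)),
    summary_json, auto_unbox = TRUE, pretty = TRUE, digits = NA, null = "null")
  outputs$summary <- basename(summary_json)

  write_manifest(
    out_dir, "analyze",
    inputs = list(config = if (is.character(config)) config else cfg$name,
                  streams = stream_paths),
    params = list(threshold = as.integer(threshold),
                  horizon_minutes = cfg$horizon_minutes),
    outputs = outputs)
  invisible(list(series = series, milestones = mst, summary = summ,
                 stats = stream$stats, alert = alert))
}

round_or_null <- function(x, digits) if (is.na(x)) NULL else round(x, digits)
na_to_null <- function(x) if (is.na(x)) NULL else x

#' Detect a threshold alert for an event stream
#'
#' Same ingest/filter/bin pipeline as [run_analyze()], then threshold
#' detection with lead times against the config's timeline marks. Writes
#' `alert.json` and `manifest.json`.
#'
#' @inheritParams run_analyze
#' @param threshold Alert threshold in tweets/min.
#' @param window Consecutive qualifying bins required (default 1).
#' @return Invisibly, the `mce_alert`.
#' @export
run_detect <- function(config, stream_paths, out_dir, threshold = 200L,
                       window = 1L) {
  cfg <- as_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stream <- read_streams(stream_paths, onset = cfg$onset)
  kept <- filter_by_rules(stream$tweets, cfg$rules)
  series <- bin_per_minute(kept, cfg$onset, cfg$horizon_minutes)
  alert <- detect_threshold(series, threshold, timeline = cfg$timeline,
                            window = window)
  alert_json <- file.path(out_dir, "alert.json")
  jsonlite::write_json(
    list(event = cfg$name,
         threshold_tpm = alert$threshold_tpm,
         window = alert$window,
         fired = alert$fired,
         fire_minute = na_to_null(alert$fire_minute),
         fire_instant_utc = if (alert$fired)
           format(alert$fire_instant, "%Y-%m-%dT%H:%M:%SZ") else NULL,
         lead_times_seconds = as.list(alert$lead_times)),
    alert_json, auto_unbox = TRUE, pretty = TRUE, digits = NA, null = "null")
  write_manifest(
    out_dir, "detect",
    inputs = list(config = if (is.character(config)) config else cfg$name,
                  streams = stream_paths),
    params = list(threshold = as.integer(threshold), window = as.integer(window)),
    outputs = list(alert = basename(alert_json)))
  invisible(alert)
}

#' Simulate a synthetic stream to NDJSON with a ground-truth sidecar
#'
#' Generates a stream from a named preset or a burst-spec JSON file and
#' writes it as NDJSON plus a `<out>.truth.json` sidecar recording the
#' analytic 200 tpm first-crossing minute, expected and realized totals, and
#' the spec. Identical seed gives identical files.
#'
#' @param preset Preset name for [event_preset()], or `NULL` when
#'   `spec_path` is given.
#' @param out_path Output NDJSON path.
#' @param seed Integer seed (overrides the spec's).
#' @param spec_path Optional path to a JSON file of [burst_spec()] arguments.
#' @param duration Optional duration override, minutes.
#' @param onset UTC onset instant for t = 0.
#' @return Invisibly, a list with `stream` (tweet data frame) and `truth`.
#' @export
run_simulate <- function(preset = NULL, out_path, seed = NULL, spec_path = NULL,
                         duration = NULL,
                         onset = as.POSIXct("2016-02-07 15:00:00", tz = "UTC")) {
  spec <- if (!is.null(preset)) {
    event_preset(preset, duration = duration)
  } else if (!is.null(spec_path)) {
    args <- jsonlite::fromJSON(spec_path, simplifyVector = TRUE)
    if (!is.null(duration)) args$duration <- duration
    do.call(burst_spec, args)
  } else {
    stop("config error: simulate needs a preset name or a spec file",
         call. = FALSE)
  }
  if (!is.null(seed)) spec$seed <- as.integer(seed)
  dir.create(dirname(out_path), showWarnings = FALSE, recursive = TRUE)
  tweets <- generate_stream(spec, onset = onset)
  write_stream(tweets, out_path)
  crossing <- first_crossing_minute(spec, 200)
  truth <- list(
    preset = preset,
    seed = spec$seed,
    onset_utc = format(onset, "%Y-%m-%dT%H:%M:%SZ"),
    first_crossing_200 = na_to_null(crossing),
    expected_total = round(expected_count(0, spec$duration, spec), 1),
    realized_total = nrow(tweets),
    spec = unclass(spec)
  )
  truth_path <- paste0(out_path, ".truth.json")
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  write_manifest(
    dirname(out_path), "simulate",
    inputs = list(spec = spec_path),
    params = list(preset = preset, duration = duration),
    outputs = list(stream = basename(out_path), truth = basename(truth_path)),
    seed = spec$seed)
  invisible(list(stream = tweets, truth = truth))
}
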