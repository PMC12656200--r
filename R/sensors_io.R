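# Electronic-nose log parsing, baseline adjustment, campaign means, and the
# Bureau-of-Meteorology-style daily weather table.

#' Gas sensor channel names of the nine-sensor MOS array
#' @export
ENOSE_CHANNELS <- c("MQ3", "MQ4", "MQ7", "MQ8", "MQ135", "MQ136", "MQ137",
                    "MQ138", "MG811")

enose_header <- function() {
  c("timestamp", "lat", "lon", "alt", ENOSE_CHANNELS, "temp_C", "rh_pct")
}

#' Read an E-nose CSV log
#'
#' Expects the fixed header
#' `timestamp,lat,lon,alt,MQ3,MQ4,MQ7,MQ8,MQ135,MQ136,MQ137,MQ138,MG811,temp_C,rh_pct`
#' with ISO-8601 timestamps. Voltages outside the 0--5 V supply range are
#' flagged (logical `flagged` column) but the rows are retained; rows with
#' unparseable timestamps are dropped with a message.
#'
#' @param path CSV log path.
#' @return `data.frame` with typed columns plus `flagged`.
#' @export
read_enose_log <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(enose_header(), names(df))
  if (length(miss)) stop("E-nose log missing column(s): ",
                         paste(miss, collapse = ", "))
  ts <- parse_utc(df$timestamp)
  bad <- is.na(ts)
  if (any(bad)) {
    message("dropping ", sum(bad), " row(s) with unparseable timestamps")
    df <- df[!bad, , drop = FALSE]
    ts <- ts[!bad]
  }
  out <- df[enose_header()]
  out$timestamp <- ts
  for (ch in c(ENOSE_CHANNELS, "temp_C", "rh_pct"))
    out[[ch]] <- as.numeric(out[[ch]])
  v <- as.matrix(out[ENOSE_CHANNELS])
  out$flagged <- apply(v < 0 | v > 5, 1L, any)
  if (any(out$flagged))
    message(sum(out$flagged), " row(s) flagged with out-of-range voltages")
  out
}

#' Write an E-nose CSV log
#'
#' Inverse of [read_enose_log()] (round-trips all fields).
#'
#' @param samples `data.frame` in the [read_enose_log()] layout.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_enose_log <- function(samples, path) {
  out <- samples[enose_header()]
  out$timestamp <- format_utc(samples$timestamp)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Baseline adjustment of gas channels
#'
#' Subtracts, per channel, the mean over a clean-air baseline window
#' recorded before the campaign proper. Off by default in the pipeline:
#' campaign summaries are reported on raw voltages, and the hook exists for
#' deployments that log a warm-up window.
#'
#' @param samples E-nose `data.frame` (see [read_enose_log()]).
#' @param baseline_window_s Length of the baseline window in seconds,
#'   measured from the first sample.
#' @return `samples` with gas channels shifted; attribute `baseline` holds
#'   the per-channel means subtracted.
#' @export
baseline_adjust <- function(samples, baseline_window_s) {
  stopifnot(nrow(samples) >= 1L, baseline_window_s > 0)
  t0 <- as.numeric(samples$timestamp[1])
  in_window <- as.numeric(samples$timestamp) < t0 + baseline_window_s
  if (!any(in_window)) stop("calibration error: empty baseline window")
  base <- vapply(ENOSE_CHANNELS,
                 function(ch) mean(samples[[ch]][in_window]), numeric(1))
  for (ch in ENOSE_CHANNELS) samples[[ch]] <- samples[[ch]] - base[[ch]]
  attr(samples, "baseline") <- base
  samples
}

#' Per-campaign mean gas sensor values
#'
#' Arithmetic mean of every gas channel (plus ambient temperature and
#' humidity) over one measurement campaign, with the stacked total used for
#' cross-campaign bar comparisons.
#'
#' @param samples E-nose `data.frame`.
#' @param campaign_id Label such as `"M1"`.
#' @return Object of class `campaign_summary`: list with `campaign_id`,
#'   `means` (named vector over channels), `temp_C`, `rh_pct`,
#'   `stacked_total` (sum of channel means), `start`, `end`, `n_samples`.
#' @export
campaign_means <- function(samples, campaign_id = "M1") {
  if (nrow(samples) == 0L) stop("no samples in campaign")
  means <- vapply(ENOSE_CHANNELS, function(ch) mean(samples[[ch]]), numeric(1))
  structure(list(
    campaign_id = campaign_id,
    means = means,
    temp_C = mean(samples$temp_C),
    rh_pct = mean(samples$rh_pct),
    stacked_total = sum(means),
    start = min(samples$timestamp),
    end = max(samples$timestamp),
    n_samples = nrow(samples)
  ), class = "campaign_summary")
}

#' @export
print.campaign_summary <- function(x, ...) {
  cat("Campaign", x$campaign_id, "-", x$n_samples, "samples\n")
  print(round(x$means, 4))
  cat(sprintf("  stacked total %.3f V; ambient %.1f C / %.1f %%RH\n",
              x$stacked_total, x$temp_C, x$rh_pct))
  invisible(x)
}

WEATHER_COLS <- c("date", "t_min", "t_max", "rainfall", "wind_dir",
                  "wind_speed_max", "wind_time_max", "t_9am", "rh_9am",
                  "wind_dir_9am", "ws_9am", "mslp_9am", "t_3pm", "rh_3pm",
                  "wind_dir_3pm", "ws_3pm", "mslp_3pm")

#' Read a daily weather table
#'
#' Parses the Bureau-of-Meteorology style daily observation table: min/max
#' temperature, rainfall, maximum wind gust (direction, speed, time), and
#' 9 am / 3 pm temperature, relative humidity, wind and mean sea-level
#' pressure. A wind-speed cell of `"Calm"` parses to 0 km/h with a missing
#' direction.
#'
#' @param path CSV with columns
#'   `date,t_min,t_max,rainfall,wind_dir,wind_speed_max,wind_time_max,t_9am,rh_9am,wind_dir_9am,ws_9am,mslp_9am,t_3pm,rh_3pm,wind_dir_3pm,ws_3pm,mslp_3pm`.
#' @return Typed `data.frame`; validation fails when `t_min > t_max` or
#'   rainfall is negative.
#' @export
read_weather_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        colClasses = "character")
  miss <- setdiff(WEATHER_COLS, names(df))
  if (length(miss)) stop("weather table missing column(s): ",
                         paste(miss, collapse = ", "))
  df <- df[WEATHER_COLS]
  num_cols <- c("t_min", "t_max", "rainfall", "t_9am", "rh_9am", "mslp_9am",
                "t_3pm", "rh_3pm", "mslp_3pm")
  for (cn in num_cols) df[[cn]] <- as.numeric(df[[cn]])
  for (cn in c("wind_speed_max", "ws_9am", "ws_3pm")) {
    calm <- trimws(df[[cn]]) == "Calm"
    df[[cn]] <- suppressWarnings(as.numeric(df[[cn]]))
    df[[cn]][calm] <- 0
  }
  for (cn in c("wind_dir", "wind_dir_9am", "wind_dir_3pm"))
    df[[cn]][trimws(df[[cn]]) == ""] <- NA_character_
  if (any(df$t_min > df$t_max, na.rm = TRUE))
    stop("weather validation: t_min exceeds t_max")
  if (any(df$rainfall < 0, na.rm = TRUE))
    stop("weather validation: negative rainfall")
  df
}
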