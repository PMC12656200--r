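# Radiometric thermal frames: canopy segmentation, wet/dry reference
# temperatures, and the water-status indices TWSI, Ig and CTD.
#
# Upward-looking radiometric sky temperatures sit far below 0 C while
# foliage tracks air temperature, so a simple temperature cutoff separates
# canopy from sky.

#' Segment canopy pixels in a thermal frame
#'
#' Canopy is taken as pixels strictly warmer than `sky_cutoff` (default
#' 0 C); colder pixels are open sky.
#'
#' @param frame A `thermal_frame` or plain numeric matrix of Celsius values.
#' @param sky_cutoff Temperature cut in Celsius (default 0).
#' @return Logical matrix, `TRUE` = canopy. If no pixel is above the cutoff
#'   an error of class `canopysense_empty_canopy` is raised so batch drivers
#'   can skip and log the frame.
#' @export
canopy_mask_thermal <- function(frame, sky_cutoff = 0) {
  temps <- if (inherits(frame, "thermal_frame")) frame$temperatures else frame
  stopifnot(is.matrix(temps), is.numeric(temps))
  if (length(temps) == 0L) stop("empty thermal frame")
  mask <- temps > sky_cutoff
  if (!any(mask)) {
    stop(structure(class = c("canopysense_empty_canopy", "error", "condition"),
                   list(message = "no canopy pixels above the sky cutoff",
                        call = sys.call(-1))))
  }
  mask
}

#' Wet and dry reference temperatures from the in-frame distribution
#'
#' The coldest canopy pixels approximate a fully transpiring (wet) leaf and
#' the warmest a non-transpiring (dry) leaf. The references are taken as
#' percentiles of the canopy temperature distribution (linear interpolation
#' between order statistics), a practical stand-in for manual wet/dry
#' leaf referencing which is infeasible from a moving vehicle.
#'
#' @param canopy_temps Numeric vector of canopy pixel temperatures (C).
#' @param p_wet,p_dry Percentiles for the wet and dry references
#'   (defaults 5 and 95).
#' @return Named list with `t_wet` and `t_dry` (`t_wet < t_dry` enforced).
#' @export
reference_temperatures <- function(canopy_temps, p_wet = 5, p_dry = 95) {
  canopy_temps <- canopy_temps[is.finite(canopy_temps)]
  if (length(canopy_temps) < 20L)
    stop("need at least 20 canopy pixels for reference temperatures")
  q <- stats::quantile(canopy_temps, probs = c(p_wet, p_dry) / 100,
                       names = FALSE, type = 7)
  if (q[1] >= q[2])
    stop("degenerate canopy temperature distribution: t_wet >= t_dry")
  list(t_wet = q[1], t_dry = q[2])
}

#' Water-status indices from canopy and reference temperatures
#'
#' Computes the raw stress index
#' \deqn{(T_{canopy} - T_{wet}) / (T_{dry} - T_{wet}),}
#' its `[0, 1]`-clipped form TWSI, the infrared (stomatal conductance)
#' index \deqn{I_g = (T_{dry} - T_{canopy}) / (T_{canopy} - T_{wet}),}
#' and the canopy temperature depression
#' \deqn{CTD = T_{canopy} - T_{average}} where `t_average` is ambient air
#' temperature (from the E-nose environmental sensors). `Ig` is capped at
#' `ig_max` when `t_canopy` does not exceed `t_wet` (the index diverges
#' there).
#'
#' @param t_canopy Mean canopy temperature (C).
#' @param t_wet,t_dry Reference temperatures (C), `t_wet < t_dry`.
#' @param t_average Ambient air temperature (C); `NA` gives `ctd = NA`.
#' @param ig_max Cap for the infrared index (default 10).
#' @return Object of class `water_status`: list with `t_canopy`, `t_wet`,
#'   `t_dry`, `raw_index`, `twsi`, `ig`, `ctd`, `t_average`.
#' @export
compute_stress_indices <- function(t_canopy, t_wet, t_dry, t_average = NA_real_,
                                   ig_max = 10) {
  if (t_dry <= t_wet) stop("reference error: t_dry must exceed t_wet")
  raw <- (t_canopy - t_wet) / (t_dry - t_wet)
  twsi <- min(max(raw, 0), 1)
  ig <- if (t_canopy > t_wet) {
    min((t_dry - t_canopy) / (t_canopy - t_wet), ig_max)
  } else {
    ig_max
  }
  ctd <- t_canopy - t_average
  structure(list(t_canopy = t_canopy, t_wet = t_wet, t_dry = t_dry,
                 raw_index = raw, twsi = twsi, ig = ig, ctd = ctd,
                 t_average = t_average),
            class = "water_status")
}

#' Full water-status analysis of one thermal frame
#'
#' Segments the canopy, extracts the mean canopy temperature and in-frame
#' wet/dry references, and computes all indices.
#'
#' @param frame A `thermal_frame` or numeric matrix (Celsius).
#' @param t_average Ambient air temperature (C).
#' @param sky_cutoff,p_wet,p_dry,ig_max Passed through.
#' @return A `water_status` object.
#' @export
analyze_thermal_frame <- function(frame, t_average = NA_real_, sky_cutoff = 0,
                                  p_wet = 5, p_dry = 95, ig_max = 10) {
  temps <- if (inherits(frame, "thermal_frame")) frame$temperatures else frame
  mask <- canopy_mask_thermal(temps, sky_cutoff)
  canopy <- temps[mask]
  refs <- reference_temperatures(canopy, p_wet, p_dry)
  compute_stress_indices(mean(canopy), refs$t_wet, refs$t_dry, t_average,
                         ig_max = ig_max)
}

#' Batch thermal analysis over a list of frames
#'
#' @param frames List of `thermal_frame` objects (see
#'   [read_thermal_frames()]).
#' @param t_average Ambient air temperature, scalar or one value per frame.
#' @param ... Passed to [analyze_thermal_frame()].
#' @return `data.frame` with one row per frame: `frame_id`, `timestamp`,
#'   `t_canopy`, `t_wet`, `t_dry`, `raw_index`, `twsi`, `ig`, `ctd`.
#'   Frames with no canopy pixels are skipped with a message.
#' @export
analyze_thermal_frames <- function(frames, t_average = NA_real_, ...) {
  t_average <- rep_len(t_average, length(frames))
  rows <- lapply(seq_along(frames), function(i) {
    fr <- frames[[i]]
    ws <- tryCatch(analyze_thermal_frame(fr, t_average[i], ...),
                   canopysense_empty_canopy = function(e) {
                     message("skipping frame ", fr$frame_id %||% i,
                             ": no canopy pixels")
                     NULL
                   })
    if (is.null(ws)) return(NULL)
    data.frame(frame_id = fr$frame_id %||% as.character(i),
               timestamp = fr$timestamp %||% as.POSIXct(NA),
               t_canopy = ws$t_canopy, t_wet = ws$t_wet, t_dry = ws$t_dry,
               raw_index = ws$raw_index, twsi = ws$twsi, ig = ws$ig,
               ctd = ws$ctd)
  })
  do.call(rbind, rows)
}

#' Campaign summary statistics
#'
#' Minimum, maximum, mean and standard deviation (n-1 denominator; 0 for a
#' single frame) of per-frame metrics over one measurement campaign.
#'
#' @param metrics `data.frame` of per-frame values; all numeric columns are
#'   summarised.
#' @return `data.frame` with columns `metric`, `min`, `max`, `mean`, `sd`.
#' @export
summarize_campaign <- function(metrics) {
  if (is.null(dim(metrics))) metrics <- data.frame(value = metrics)
  if (nrow(metrics) == 0L) stop("no frames to summarise")
  num <- vapply(metrics, is.numeric, logical(1))
  cols <- names(metrics)[num]
  if (length(cols) == 0L) stop("no numeric columns to summarise")
  rows <- lapply(cols, function(cn) {
    v <- metrics[[cn]]
    v <- v[is.finite(v)]
    if (length(v) == 0L)
      return(data.frame(metric = cn, min = NA_real_, max = NA_real_,
                        mean = NA_real_, sd = NA_real_))
    data.frame(metric = cn, min = min(v), max = max(v), mean = mean(v),
               sd = if (length(v) > 1L) stats::sd(v) else 0)
  })
  do.call(rbind, rows)
}

#' @export
print.water_status <- function(x, ...) {
  cat("Canopy water status\n")
  cat(sprintf("  T_canopy : %.3f C   (T_wet %.3f, T_dry %.3f)\n",
              x$t_canopy, x$t_wet, x$t_dry))
  cat(sprintf("  raw index: %.4f   TWSI: %.4f   Ig: %.4f   CTD: %.3f C\n",
              x$raw_index, x$twsi, x$ig, x$ctd))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
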