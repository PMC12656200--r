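# GPS track densification, per-tree geofencing and stream fusion.
#
# Ground distances use an equirectangular approximation, which is accurate
# to well under a metre over the sub-10 km extents of a street transect —
# far smaller than any geofence radius.

EARTH_RADIUS_M <- 6371008.8

#' Construct a GPS track
#'
#' @param timestamp POSIXct vector, strictly increasing.
#' @param latitude,longitude Degrees (WGS84).
#' @param altitude Metres (carried through, unused by the geometry).
#' @return `data.frame` of class `geo_track`.
#' @export
geo_track <- function(timestamp, latitude, longitude, altitude = 0) {
  stopifnot(inherits(timestamp, "POSIXct"))
  if (any(diff(as.numeric(timestamp)) <= 0))
    stop("track timestamps must be strictly increasing")
  if (any(latitude < -90 | latitude > 90)) stop("latitude out of [-90, 90]")
  if (any(longitude < -180 | longitude > 180)) stop("longitude out of [-180, 180]")
  out <- data.frame(timestamp = timestamp, latitude = latitude,
                    longitude = longitude,
                    altitude = rep_len(altitude, length(latitude)))
  class(out) <- c("geo_track", "data.frame")
  out
}

#' Equirectangular ground distance
#'
#' @param lat1,lon1,lat2,lon2 Degrees; vectors recycle.
#' @return Distance in metres.
#' @export
ground_distance <- function(lat1, lon1, lat2, lon2) {
  to_rad <- pi / 180
  x <- (lon2 - lon1) * to_rad * cos((lat1 + lat2) / 2 * to_rad)
  y <- (lat2 - lat1) * to_rad
  EARTH_RADIUS_M * sqrt(x^2 + y^2)
}

#' Densify a GPS track to a uniform rate by linear interpolation
#'
#' Resamples the track onto a uniform time grid from the first to the last
#' input timestamp inclusive, interpolating each coordinate axis linearly.
#' A one-second span at 10 Hz therefore yields 11 samples.
#'
#' @param track A `geo_track` with at least 2 samples.
#' @param rate_hz Output sampling rate (default 10).
#' @return A `geo_track` on the uniform grid.
#' @export
densify_track <- function(track, rate_hz = 10) {
  stopifnot(inherits(track, "geo_track"), nrow(track) >= 2L)
  t <- as.numeric(track$timestamp)
  span <- t[length(t)] - t[1]
  step <- 1 / rate_hz
  grid <- t[1] + step * seq(0L, floor(span / step + 1e-9))
  if (max(grid) < t[length(t)] - 1e-9) grid <- c(grid, t[length(t)])
  geo_track(
    timestamp = as.POSIXct(grid, tz = "UTC",
                           origin = as.POSIXct("1970-01-01", tz = "UTC")),
    latitude = stats::approx(t, track$latitude, xout = grid)$y,
    longitude = stats::approx(t, track$longitude, xout = grid)$y,
    altitude = stats::approx(t, track$altitude, xout = grid)$y
  )
}

#' Read tree anchor coordinates
#'
#' @param path CSV with columns `tree_id`, `latitude`, `longitude`.
#' @return `data.frame` with those columns; `tree_id` as character.
#' @export
read_anchors <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("tree_id", "latitude", "longitude")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("anchors file missing column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(df$tree_id)) stop("duplicate tree_id in anchors")
  df$tree_id <- as.character(df$tree_id)
  df[need]
}

#' Build non-overlapping circular geofences around tree anchors
#'
#' Each tree's radius is the minimum of `max_radius_m` and half the ground
#' distance to each neighbouring anchor along the transect, which keeps
#' adjacent regions disjoint so no sample can be attributed to two trees.
#'
#' @param anchors `data.frame` with `tree_id`, `latitude`, `longitude`,
#'   ordered along the transect.
#' @param max_radius_m Radius cap in metres (default 15, a typical
#'   street-tree half spacing).
#' @return `data.frame` with `tree_id`, `latitude`, `longitude`,
#'   `radius_m`.
#' @export
build_geofences <- function(anchors, max_radius_m = 15) {
  n <- nrow(anchors)
  if (n == 0L) stop("no anchors")
  if (n > 1L) {
    d <- ground_distance(anchors$latitude[-n], anchors$longitude[-n],
                         anchors$latitude[-1], anchors$longitude[-1])
    if (any(d == 0)) stop("degenerate anchors: duplicate coordinates")
    prev_d <- c(Inf, d)
    next_d <- c(d, Inf)
  } else {
    prev_d <- next_d <- Inf
  }
  radius <- pmin(max_radius_m, prev_d / 2, next_d / 2)
  data.frame(tree_id = as.character(anchors$tree_id),
             latitude = anchors$latitude, longitude = anchors$longitude,
             radius_m = radius)
}

#' Entry/exit intervals of a track through geofenced regions
#'
#' For each region, finds the contiguous runs of track samples whose ground
#' distance to the centre is at most the radius. Each run yields one
#' interval (first and last timestamp of the run); an out-and-back transect
#' therefore produces one interval per pass, all tagged with the tree id.
#' Trees never entered are absent from the output.
#'
#' @param dense A densified `geo_track`.
#' @param regions Geofence table from [build_geofences()].
#' @return `data.frame` with `tree_id`, `entry_time`, `exit_time`, `pass`
#'   (pass number for that tree).
#' @export
region_intervals <- function(dense, regions) {
  stopifnot(inherits(dense, "geo_track"))
  out <- lapply(seq_len(nrow(regions)), function(i) {
    d <- ground_distance(dense$latitude, dense$longitude,
                         regions$latitude[i], regions$longitude[i])
    inside <- d <= regions$radius_m[i]
    if (!any(inside)) return(NULL)
    r <- rle(inside)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- which(r$values)
    data.frame(tree_id = regions$tree_id[i],
               entry_time = dense$timestamp[starts[runs]],
               exit_time = dense$timestamp[ends[runs]],
               pass = seq_along(runs))
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(tree_id = character(0),
                      entry_time = as.POSIXct(character(0), tz = "UTC"),
                      exit_time = as.POSIXct(character(0), tz = "UTC"),
                      pass = integer(0))
  }
  out[order(out$entry_time), , drop = FALSE]
}

#' Aggregate timestamped streams per tree
#'
#' For every tree, averages each parameter over the stream samples that
#' fall inside any of the tree's intervals (`entry <= t <= exit`). Samples
#' from multiple passes are pooled into one per-tree mean. Empty windows
#' yield `NA`, never zero; per-parameter sample counts are recorded.
#'
#' @param stream `data.frame` with a POSIXct `timestamp` column and one or
#'   more numeric parameter columns, sorted by time.
#' @param intervals Interval table from [region_intervals()].
#' @return `data.frame` with one row per tree: `tree_id`, `entry_time`
#'   (earliest), `exit_time` (latest), `<param>` means and `n_<param>`
#'   counts.
#' @export
aggregate_by_interval <- function(stream, intervals) {
  stopifnot("timestamp" %in% names(stream))
  params <- names(stream)[vapply(stream, is.numeric, logical(1))]
  params <- setdiff(params, "timestamp")
  ts <- as.numeric(stream$timestamp)
  trees <- unique(intervals$tree_id)
  rows <- lapply(trees, function(id) {
    iv <- intervals[intervals$tree_id == id, , drop = FALSE]
    inside <- rep(FALSE, length(ts))
    for (j in seq_len(nrow(iv))) {
      inside <- inside | (ts >= as.numeric(iv$entry_time[j]) &
                          ts <= as.numeric(iv$exit_time[j]))
    }
    row <- data.frame(tree_id = id, entry_time = min(iv$entry_time),
                      exit_time = max(iv$exit_time))
    for (p in params) {
      v <- stream[[p]][inside]
      v <- v[is.finite(v)]
      row[[p]] <- if (length(v)) mean(v) else NA_real_
      row[[paste0("n_", p)]] <- length(v)
    }
    row
  })
  do.call(rbind, rows)
}

#' Fuse several streams into per-tree records
#'
#' Aggregates each stream independently against the same intervals (no
#' cross-resampling between sensors running at different rates) and joins
#' the per-tree means by tree id.
#'
#' @param streams Named list of stream `data.frame`s (see
#'   [aggregate_by_interval()]).
#' @param intervals Interval table from [region_intervals()].
#' @return Per-tree `data.frame`; parameter columns keep their stream's
#'   names (prefixed with the stream name on collision).
#' @export
fuse_streams <- function(streams, intervals) {
  stopifnot(is.list(streams), length(streams) >= 1L)
  aggs <- lapply(streams, aggregate_by_interval, intervals = intervals)
  out <- aggs[[1]]
  if (length(aggs) > 1L) {
    for (i in 2:length(aggs)) {
      a <- aggs[[i]]
      a$entry_time <- NULL; a$exit_time <- NULL
      clash <- setdiff(intersect(names(a), names(out)), "tree_id")
      names(a)[match(clash, names(a))] <-
        paste(names(streams)[i], clash, sep = "_")
      out <- merge(out, a, by = "tree_id", all = TRUE, sort = FALSE)
    }
  }
  out[order(out$entry_time), , drop = FALSE]
}
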