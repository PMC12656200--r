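# Reading and writing image frames and GPS sidecars.

#' Read an 8-bit RGB frame
#'
#' Reads a PNG or TIFF image and returns intensities on the 0--255 scale.
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @return Numeric array `h x w x 3` with values in `[0, 255]`.
#' @export
read_rgb_frame <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported frame format: ", ext, " (use PNG or TIFF)")
  )
  if (length(dim(img)) == 2L) stop("frame is greyscale; RGB required")
  img <- img[, , 1:3, drop = FALSE]
  round(img * 255)
}

#' Write an 8-bit RGB frame as PNG
#'
#' @param frame Numeric array `h x w x 3`, values in `[0, 255]`.
#' @param path Output `.png` path.
#' @return `path`, invisibly.
#' @export
write_rgb_frame <- function(frame, path) {
  png::writePNG(pmin(pmax(frame / 255, 0), 1), path)
  invisible(path)
}

#' Read radiometric thermal frames from a directory
#'
#' Reads per-frame TIFFs holding raw 14-bit counts and converts them to
#' degrees Celsius with a linear calibration `temp = gain * counts + offset`.
#' Plain-text matrices (`.csv` of temperatures, one row per pixel row) are
#' read as already-calibrated Celsius.
#'
#' @param dir Directory of `.tif`/`.tiff` (raw counts) or `.csv`
#'   (temperature matrix) frames, ordered lexicographically.
#' @param gain,offset Linear count-to-Celsius calibration applied to TIFF
#'   input. The defaults map the full 14-bit range onto -40..120 C.
#' @param timestamps Optional vector of POSIXct timestamps, one per frame
#'   (e.g. from [read_srt_track()]).
#' @return List of `thermal_frame` objects (fields `temperatures`,
#'   `timestamp`, `frame_id`).
#' @export
read_thermal_frames <- function(dir, gain = 160 / 16383, offset = -40,
                                timestamps = NULL) {
  files <- list_frame_files(dir, c("tif", "tiff", "csv"))
  lapply(seq_along(files), function(i) {
    f <- files[i]
    ext <- tolower(tools::file_ext(f))
    temps <- if (ext == "csv") {
      as.matrix(utils::read.csv(f, header = FALSE))
    } else {
      raw <- tiff::readTIFF(f, as.is = TRUE)
      gain * raw + offset
    }
    storage.mode(temps) <- "double"
    thermal_frame(temps,
                  timestamp = if (!is.null(timestamps)) timestamps[i] else NULL,
                  frame_id = frame_id_of(f))
  })
}

#' Construct a thermal frame object
#'
#' @param temperatures Numeric matrix of Celsius values.
#' @param timestamp Optional POSIXct instant.
#' @param frame_id Optional identifier.
#' @param emissivity Emissivity metadata (pass-through; default 0.96).
#' @return Object of class `thermal_frame`.
#' @export
thermal_frame <- function(temperatures, timestamp = NULL, frame_id = NULL,
                          emissivity = 0.96) {
  stopifnot(is.matrix(temperatures), is.numeric(temperatures))
  if (any(!is.finite(temperatures)))
    stop("thermal frame contains non-finite temperatures")
  if (any(temperatures < -80 | temperatures > 80))
    warning("temperatures outside the plausible [-80, 80] C range")
  structure(list(temperatures = temperatures, timestamp = timestamp,
                 frame_id = frame_id, emissivity = emissivity),
            class = "thermal_frame")
}

#' Read a GPS track from a SubRip (SRT) sidecar
#'
#' Video GPS sidecars store one subtitle block per frame; the payload line
#' carries latitude, longitude, altitude and the wall-clock time, e.g.
#' `GPS: -37.790612, 144.958214, 35.2 TIME: 2021-04-19T15:02:07.100Z`.
#'
#' @param path Path to the `.srt` file.
#' @return A `geo_track` (see [geo_track()]).
#' @export
read_srt_track <- function(path) {
  lines <- readLines(path, warn = FALSE)
  pay <- grep("GPS:", lines, value = TRUE)
  if (length(pay) == 0L) stop("no GPS payload lines in ", path)
  m <- regmatches(pay, regexec(
    "GPS:\\s*(-?[0-9.]+),\\s*(-?[0-9.]+),\\s*(-?[0-9.]+)\\s+TIME:\\s*(\\S+)",
    pay))
  bad <- vapply(m, length, integer(1)) != 5L
  if (any(bad)) stop("malformed GPS payload at line(s): ",
                     paste(which(bad), collapse = ", "))
  m <- do.call(rbind, m)
  geo_track(
    timestamp = parse_utc(m[, 5]),
    latitude = as.numeric(m[, 2]),
    longitude = as.numeric(m[, 3]),
    altitude = as.numeric(m[, 4])
  )
}

#' Write a GPS track as a SubRip (SRT) sidecar
#'
#' Inverse of [read_srt_track()]; subtitle display times are derived from
#' the offset of each sample to the first.
#'
#' @param track A `geo_track`.
#' @param path Output `.srt` path.
#' @return `path`, invisibly.
#' @export
write_srt_track <- function(track, path) {
  t0 <- track$timestamp[1]
  rel <- as.numeric(track$timestamp - t0, units = "secs")
  blocks <- vapply(seq_len(nrow(track)), function(i) {
    paste0(i, "\n",
           srt_clock(rel[i]), " --> ", srt_clock(rel[i] + 0.1), "\n",
           sprintf("GPS: %.7f, %.7f, %.1f TIME: %s", track$latitude[i],
                   track$longitude[i], track$altitude[i],
                   format_utc(track$timestamp[i])),
           "\n")
  }, character(1))
  writeLines(paste(blocks, collapse = "\n"), path)
  invisible(path)
}

srt_clock <- function(s) {
  h <- floor(s / 3600); m <- floor((s %% 3600) / 60)
  sec <- floor(s %% 60); ms <- round((s - floor(s)) * 1000)
  sprintf("%02d:%02d:%02d,%03d", h, m, sec, ms)
}

parse_utc <- function(x) {
  x <- sub("Z$", "", x)
  a <- as.POSIXct(strptime(x, "%Y-%m-%dT%H:%M:%OS", tz = "UTC"))
  b <- as.POSIXct(strptime(x, "%Y-%m-%d %H:%M:%OS", tz = "UTC"))
  a[is.na(a)] <- b[is.na(a)]
  a
}

format_utc <- function(t) {
  paste0(format(t, "%Y-%m-%dT%H:%M:%OS3", tz = "UTC"), "Z")
}
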