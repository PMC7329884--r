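# Trace container and I/O.
#
# Timestamps are stored as epoch milliseconds UTC throughout; all local-day
# and night-window logic goes through the one IANA timezone attached to the
# trace.  Coordinates are WGS84 decimal degrees; no projection is ever
# applied -- every distance in the package is a haversine distance.

#' Construct a location trace
#'
#' @param points A data frame with columns `timestamp` (epoch milliseconds
#'   UTC, numeric), `lat`, `lon` (WGS84 decimal degrees) and optionally
#'   `confidence_m` (68%-containment radius, meters; `NA` allowed).
#' @param subject_id Opaque subject identifier.
#' @param timezone IANA timezone for local-day computations.
#' @param validate Drop out-of-bounds rows and deduplicate timestamps?
#'   Default `TRUE`.
#'
#' @details Points are sorted by timestamp.  Rows with missing or
#'   out-of-bounds coordinates (|lat| > 90, |lon| > 180) or negative
#'   confidence are dropped; duplicate timestamps keep the first occurrence.
#'   Counts of dropped rows are recorded in the `load_report` attribute.
#'
#' @return An object of class `geo_trace`: a list with elements
#'   `subject_id`, `timezone` and `points` (a tibble).
#' @export
new_trace <- function(points, subject_id = "subject", timezone = "UTC",
                      validate = TRUE) {
  if (!is_valid_timezone(timezone)) {
    stop("invalid timezone: '", timezone, "'", call. = FALSE)
  }
  points <- tibble::as_tibble(points)
  required <- c("timestamp", "lat", "lon")
  missing_cols <- setdiff(required, names(points))
  if (length(missing_cols)) {
    stop("trace points lack required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!"confidence_m" %in% names(points)) points$confidence_m <- NA_real_
  points$timestamp <- as.numeric(points$timestamp)
  points$lat <- as.numeric(points$lat)
  points$lon <- as.numeric(points$lon)
  points$confidence_m <- as.numeric(points$confidence_m)

  n_in <- nrow(points)
  n_invalid <- 0L
  n_dupes <- 0L
  if (validate && n_in > 0) {
    ok <- is.finite(points$timestamp) &
      is.finite(points$lat) & is.finite(points$lon) &
      points$lat >= -90 & points$lat <= 90 &
      points$lon >= -180 & points$lon <= 180 &
      (is.na(points$confidence_m) | points$confidence_m >= 0)
    n_invalid <- sum(!ok)
    points <- points[ok, , drop = FALSE]
    points <- points[order(points$timestamp), , drop = FALSE]
    dup <- duplicated(points$timestamp)
    n_dupes <- sum(dup)
    points <- points[!dup, , drop = FALSE]
  }
  structure(
    list(subject_id = as.character(subject_id), timezone = timezone,
         points = points),
    load_report = list(n_rows_in = n_in, n_invalid_dropped = n_invalid,
                       n_duplicates_dropped = n_dupes),
    class = "geo_trace"
  )
}

#' @export
print.geo_trace <- function(x, ...) {
  cat(sprintf("<geo_trace> subject '%s', %d fixes, tz %s\n",
              x$subject_id, nrow(x$points), x$timezone))
  if (nrow(x$points) > 0) {
    span <- range(x$points$timestamp)
    cat(sprintf("  span: %s -- %s\n",
                format(ms_to_posix(span[1], x$timezone)),
                format(ms_to_posix(span[2], x$timezone))))
  }
  invisible(x)
}

# epoch ms <-> POSIXct helpers (single source of time-conversion truth)
ms_to_posix <- function(ms, tz = "UTC") {
  as.POSIXct(ms / 1000, origin = "1970-01-01", tz = tz)
}
posix_to_ms <- function(t) as.numeric(t) * 1000

#' Read a location trace from delimited text
#'
#' @param path CSV file path.
#' @param schema Named list mapping the canonical fields `subject_id`,
#'   `timestamp`, `lat`, `lon`, `confidence` to column names in the file.
#'   Defaults to `subject_id, timestamp, lat, lon, accuracy`.
#' @param timezone IANA timezone attached to the trace.
#' @param subject_id Overrides the subject id found in the file, if given.
#'
#' @details Timestamps may be epoch milliseconds or ISO-8601 strings
#'   (parsed as UTC unless they carry an offset).  Rows with unparseable or
#'   out-of-bounds coordinates are dropped and counted in the trace's
#'   `load_report` attribute.
#'
#' @return A `geo_trace`.
#' @export
read_trace <- function(path,
                       schema = list(subject_id = "subject_id",
                                     timestamp = "timestamp",
                                     lat = "lat", lon = "lon",
                                     confidence = "accuracy"),
                       timezone = "UTC", subject_id = NULL) {
  if (!file.exists(path)) stop("trace file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop("empty trace file: ", path, call. = FALSE)
  for (field in c("timestamp", "lat", "lon")) {
    col <- schema[[field]]
    if (is.null(col) || !col %in% names(df)) {
      stop("schema error: required column '", field, "' (mapped to '",
           if (is.null(col)) "<unmapped>" else col,
           "') not found in ", path, call. = FALSE)
    }
  }
  ts_raw <- df[[schema$timestamp]]
  ts <- if (is.numeric(ts_raw)) {
    as.numeric(ts_raw)
  } else {
    parsed <- as.POSIXct(as.character(ts_raw), tz = "UTC",
                         tryFormats = c("%Y-%m-%dT%H:%M:%OS%z",
                                        "%Y-%m-%dT%H:%M:%OS",
                                        "%Y-%m-%d %H:%M:%OS",
                                        "%Y-%m-%d"))
    posix_to_ms(parsed)
  }
  conf <- if (!is.null(schema$confidence) &&
              schema$confidence %in% names(df)) {
    suppressWarnings(as.numeric(df[[schema$confidence]]))
  } else {
    NA_real_
  }
  sid <- subject_id
  if (is.null(sid)) {
    sid <- if (!is.null(schema$subject_id) &&
               schema$subject_id %in% names(df)) {
      as.character(df[[schema$subject_id]][1])
    } else {
      tools::file_path_sans_ext(basename(path))
    }
  }
  pts <- tibble::tibble(
    timestamp = ts,
    lat = suppressWarnings(as.numeric(df[[schema$lat]])),
    lon = suppressWarnings(as.numeric(df[[schema$lon]])),
    confidence_m = conf
  )
  new_trace(pts, subject_id = sid, timezone = timezone)
}

#' Write a trace to CSV
#'
#' Writes the canonical `subject_id, timestamp, lat, lon, accuracy` layout,
#' round-trippable through [read_trace()].
#'
#' @param trace A `geo_trace`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "geo_trace"))
  out <- data.frame(
    subject_id = trace$subject_id,
    timestamp = format(trace$points$timestamp, scientific = FALSE,
                       trim = TRUE),
    lat = trace$points$lat,
    lon = trace$points$lon,
    accuracy = trace$points$confidence_m
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Filter a trace on positional confidence
#'
#' Keeps exactly the fixes whose 68%-containment confidence radius is at
#' most `max_confidence_m`.  Fixes with missing confidence are kept or
#' dropped according to `missing`.
#'
#' @param trace A `geo_trace`.
#' @param max_confidence_m Threshold in meters (> 0).
#' @param missing `"keep"` (default) or `"drop"` fixes without a confidence.
#' @return The filtered `geo_trace` (an empty result is legal).
#' @export
filter_by_confidence <- function(trace, max_confidence_m = 200,
                                 missing = c("keep", "drop")) {
  stopifnot(inherits(trace, "geo_trace"), max_confidence_m > 0)
  missing <- match.arg(missing)
  conf <- trace$points$confidence_m
  keep <- !is.na(conf) & conf <= max_confidence_m
  if (missing == "keep") keep <- keep | is.na(conf)
  trace$points <- trace$points[keep, , drop = FALSE]
  trace
}

#' Split a trace into gap-free segments
#'
#' A new segment begins whenever the time between consecutive fixes exceeds
#' `max_gap_min`.  Segmentation partitions the trace: every fix belongs to
#' exactly one segment and order is preserved.
#'
#' @param trace A `geo_trace`.
#' @param max_gap_min Maximum within-segment gap, minutes (> 0).
#' @return The `geo_trace` with an integer `segment_id` column added to its
#'   points (ids increase with time, starting at 1).
#' @export
segment_on_gaps <- function(trace, max_gap_min = 60) {
  stopifnot(inherits(trace, "geo_trace"), max_gap_min > 0)
  ts <- trace$points$timestamp
  n <- length(ts)
  if (n == 0) {
    trace$points$segment_id <- integer(0)
    return(trace)
  }
  gap_ms <- max_gap_min * 60000
  breaks <- c(FALSE, diff(ts) > gap_ms)
  trace$points$segment_id <- cumsum(breaks) + 1L
  trace
}

#' Local calendar day of each fix
#'
#' Assigns each fix the local civil date (midnight-to-midnight in the
#' trace's timezone) of its timestamp.  Every fix gets exactly one date,
#' including on DST transition days.
#'
#' @param trace A `geo_trace`.
#' @return A `Date` vector, one element per fix.
#' @export
assign_local_days <- function(trace) {
  stopifnot(inherits(trace, "geo_trace"))
  local_date(trace$points$timestamp, trace$timezone)
}

local_date <- function(ms, tz) {
  as.Date(format(ms_to_posix(ms, tz), "%Y-%m-%d"))
}

# epoch ms of local midnight starting the given Date in tz
local_midnight_ms <- function(date, tz) {
  posix_to_ms(as.POSIXct(paste0(format(date, "%Y-%m-%d"), " 00:00:00"),
                         tz = tz))
}

#' Export a trace or stay points as GeoJSON
#'
#' Produces a `FeatureCollection` of point features (for traces or stay
#' points) for quick inspection in any GeoJSON viewer.
#'
#' @param x A `geo_trace`, or a stay-point / cluster tibble with
#'   `centroid_lat`/`centroid_lon` columns.
#' @param path Optional output path; if `NULL` the GeoJSON string is
#'   returned.
#' @return The GeoJSON string (invisibly if written to `path`).
#' @export
to_geojson <- function(x, path = NULL) {
  if (inherits(x, "geo_trace")) {
    coords <- cbind(x$points$lon, x$points$lat)
    props <- data.frame(timestamp = x$points$timestamp,
                        confidence_m = x$points$confidence_m)
  } else {
    stopifnot(all(c("centroid_lat", "centroid_lon") %in% names(x)))
    coords <- cbind(x$centroid_lon, x$centroid_lat)
    props <- as.data.frame(x[setdiff(names(x),
                                     c("centroid_lat", "centroid_lon"))])
  }
  feats <- lapply(seq_len(nrow(coords)), function(i) {
    list(type = "Feature",
         geometry = list(type = "Point", coordinates = coords[i, ]),
         properties = as.list(props[i, , drop = FALSE]))
  })
  gj <- jsonlite::toJSON(list(type = "FeatureCollection", features = feats),
                         auto_unbox = TRUE, digits = NA, na = "null")
  if (is.null(path)) return(gj)
  writeLines(gj, path)
  invisible(gj)
}
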