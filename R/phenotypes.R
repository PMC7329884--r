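# Behavioral phenotypes derived from context-enriched location data.
#
# Conventions, fixed for reproducibility:
#  * count phenotypes assign a stay point to its arrival day and a
#    trajectory to its start day; a visit spanning midnight is counted once;
#  * dwell *time* (home stay, entropy) is attributed to days proportionally
#    to the overlap of each stay point with the local day, so hours conserve;
#  * the home-stay denominator is total stay-point dwell by default
#    (smartphone gaps make elapsed time unreliable), with the full 24-h
#    local day available as the "elapsed" alternative;
#  * night-window bounds are fixed offsets from local midnight.

# ---- interval helpers ------------------------------------------------------

# Split stay points over local days: one row per (stay point, date) with the
# overlap in ms.  sp must carry arrival, departure (epoch ms) and sp_id.
sp_day_overlap <- function(sp, tz) {
  if (nrow(sp) == 0) {
    return(tibble::tibble(sp_id = integer(), cluster_id = integer(),
                          date = as.Date(character()), overlap_ms = double()))
  }
  rows <- lapply(seq_len(nrow(sp)), function(i) {
    d0 <- local_date(sp$arrival[i], tz)
    d1 <- local_date(sp$departure[i], tz)
    dates <- seq(d0, d1, by = "day")
    starts <- local_midnight_ms(dates, tz)
    ends <- local_midnight_ms(dates + 1, tz)
    ov <- pmin(sp$departure[i], ends) - pmax(sp$arrival[i], starts)
    keep <- ov > 0 | (dates == d0)  # zero-duration stay still belongs to a day
    tibble::tibble(sp_id = sp$sp_id[i],
                   cluster_id = if ("cluster_id" %in% names(sp))
                     sp$cluster_id[i] else NA_integer_,
                   date = dates[keep], overlap_ms = pmax(0, ov[keep]))
  })
  dplyr::bind_rows(rows)
}

# Overlap of [arrival, departure] with the nightly window (hours after
# local midnight) summed over all covered nights.  Supports windows that
# wrap past midnight (e.g. c(22, 6)).
night_overlap_ms <- function(arrival, departure, tz, night_window = c(0, 6)) {
  s <- night_window[1]
  e <- night_window[2]
  vapply(seq_along(arrival), function(i) {
    d0 <- local_date(arrival[i], tz) - 1  # window of the previous date may wrap in
    d1 <- local_date(departure[i], tz)
    dates <- seq(d0, d1, by = "day")
    mid <- local_midnight_ms(dates, tz)
    if (s < e) {
      ws <- mid + s * 3600000
      we <- mid + e * 3600000
    } else {
      # wraps: [s, 24) of each date plus [0, e) of the next
      ws <- c(mid + s * 3600000, mid)
      we <- c(local_midnight_ms(dates + 1, tz), mid + e * 3600000)
    }
    sum(pmax(0, pmin(departure[i], we) - pmax(arrival[i], ws)))
  }, numeric(1))
}

# ---- count phenotypes ------------------------------------------------------

#' Per-day count phenotypes
#'
#' Counts of places visited (stay points), unique places visited (distinct
#' clusters) and trajectories per local day.  A stay point is counted on
#' its arrival day, a trajectory on its start day, so nothing is counted
#' twice across midnight.
#'
#' @param staypoints Stay points with a `cluster_id` column (from
#'   [cluster_staypoints()]).
#' @param trajectories Trajectory tibble from [detect_staypoints()].
#' @param tz IANA timezone.
#' @param dates Optional `Date` vector of days to report (defaults to the
#'   span of the data); days without activity report zeros.
#' @return A tibble with `date`, `places_visited`, `unique_places`,
#'   `trajectories`.
#' @export
count_phenotypes <- function(staypoints, trajectories, tz, dates = NULL) {
  sp_dates <- if (nrow(staypoints)) local_date(staypoints$arrival, tz)
              else as.Date(character())
  tr_dates <- if (nrow(trajectories)) local_date(trajectories$start, tz)
              else as.Date(character())
  if (is.null(dates)) {
    all_d <- c(sp_dates, tr_dates)
    if (!length(all_d)) {
      return(tibble::tibble(date = as.Date(character()),
                            places_visited = integer(),
                            unique_places = integer(),
                            trajectories = integer()))
    }
    dates <- seq(min(all_d), max(all_d), by = "day")
  }
  per_day <- tibble::tibble(
    date = dates,
    places_visited = vapply(dates, function(d) sum(sp_dates == d),
                            integer(1)),
    unique_places = vapply(dates, function(d) {
      length(unique(staypoints$cluster_id[sp_dates == d]))
    }, integer(1)),
    trajectories = vapply(dates, function(d) sum(tr_dates == d), integer(1))
  )
  per_day
}

# ---- home inference and home stay ------------------------------------------

#' Infer the home place from nighttime dwell
#'
#' The home is the place cluster with the largest total stay-point dwell
#' overlapping the nightly window over the whole observation period.  Ties
#' are broken deterministically by larger total dwell, then by earlier
#' first visit.
#'
#' @param clustered The list returned by [cluster_staypoints()].
#' @param tz IANA timezone.
#' @param night_window Local clock interval in hours after midnight,
#'   default `c(0, 6)`.
#' @return A list: `home_cluster_id` (NA when no stay point overlaps the
#'   night window at all, flagged by `determined = FALSE`), `determined`,
#'   and `night_dwell`, a tibble of nighttime dwell minutes per cluster.
#' @export
infer_home <- function(clustered, tz, night_window = c(0, 6)) {
  sp <- clustered$staypoints
  sp <- sp[sp$cluster_id != 0L, , drop = FALSE]
  if (nrow(sp) == 0) {
    return(list(home_cluster_id = NA_integer_, determined = FALSE,
                night_dwell = tibble::tibble(cluster_id = integer(),
                                             night_dwell_min = double())))
  }
  night_ms <- night_overlap_ms(sp$arrival, sp$departure, tz, night_window)
  per_cluster <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(cluster_id = sp$cluster_id,
                                   night_ms = night_ms),
                    .data$cluster_id),
    night_dwell_min = sum(.data$night_ms) / 60000, .groups = "drop")
  if (all(per_cluster$night_dwell_min <= 0)) {
    return(list(home_cluster_id = NA_integer_, determined = FALSE,
                night_dwell = per_cluster))
  }
  cand <- merge(per_cluster, clustered$clusters, by = "cluster_id")
  cand <- cand[order(-cand$night_dwell_min, -cand$total_dwell_min,
                     cand$first_arrival), , drop = FALSE]
  list(home_cluster_id = cand$cluster_id[1], determined = TRUE,
       night_dwell = per_cluster)
}

#' Per-day home stay
#'
#' Hours and percentage of time attributed to the home cluster per local
#' day.  Stay points spanning midnight contribute to each day
#' proportionally to their overlap with it, so hours conserve and never
#' exceed 24 per day.
#'
#' @param clustered The list returned by [cluster_staypoints()].
#' @param home_cluster_id The home cluster (from [infer_home()]).
#' @param tz IANA timezone.
#' @param dates Optional `Date` vector of days to report.
#' @param denominator `"dwell"`: percent of that day's total stay-point
#'   dwell (default); `"elapsed"`: percent of the 24-h local day.
#' @return A tibble with `date`, `home_stay_hours`, `total_dwell_hours`,
#'   `home_stay_pct` (`NA` on days with a zero denominator).
#' @export
home_stay <- function(clustered, home_cluster_id, tz, dates = NULL,
                      denominator = c("dwell", "elapsed")) {
  denominator <- match.arg(denominator)
  if (is.na(home_cluster_id)) stop("home cluster is undetermined",
                                   call. = FALSE)
  ov <- sp_day_overlap(clustered$staypoints, tz)
  if (is.null(dates)) {
    dates <- if (nrow(ov)) seq(min(ov$date), max(ov$date), by = "day")
             else as.Date(character())
  }
  out <- tibble::tibble(
    date = dates,
    home_stay_hours = vapply(dates, function(d) {
      sum(ov$overlap_ms[ov$date == d & ov$cluster_id == home_cluster_id]) /
        3600000
    }, numeric(1)),
    total_dwell_hours = vapply(dates, function(d) {
      sum(ov$overlap_ms[ov$date == d]) / 3600000
    }, numeric(1))
  )
  if (denominator == "dwell") {
    out$home_stay_pct <- ifelse(out$total_dwell_hours > 0,
                                100 * out$home_stay_hours /
                                  out$total_dwell_hours, NA_real_)
  } else {
    day_h <- (local_midnight_ms(dates + 1, tz) -
                local_midnight_ms(dates, tz)) / 3600000
    out$home_stay_pct <- 100 * out$home_stay_hours / day_h
  }
  # the ratio of two sums of the same overlaps can drift past 100 by an ulp
  out$home_stay_pct <- pmin(100, pmax(0, out$home_stay_pct))
  out
}

# ---- entropy ---------------------------------------------------------------

#' Normalized location entropy
#'
#' Shannon entropy of the dwell-time distribution across visited places,
#' normalized by its maximum: \eqn{-\sum_i p_i \ln p_i / \ln N} for
#' \eqn{N \ge 2} places, defined as 0 when all dwell is at a single place.
#' Low values mean stay time concentrated on few places; 1 means dwell
#' spread uniformly over all visited places.
#'
#' @param p Dwell-time proportions per place (positive, summing to 1).
#' @return A value in \[0, 1\].
#' @export
#' @examples
#' normalized_entropy(rep(0.25, 4))   # 1
#' normalized_entropy(1)              # 0
#' normalized_entropy(c(0.8, 0.2))    # ~0.7219
normalized_entropy <- function(p) {
  stopifnot(all(p > 0), abs(sum(p) - 1) < 1e-9)
  n <- length(p)
  if (n == 1) return(0)
  h <- -sum(p * log(p))
  h / log(n)
}

# dwell-time proportions per cluster from (cluster_id, dwell) pairs
dwell_distribution <- function(cluster_id, dwell) {
  tot <- tapply(dwell, cluster_id, sum)
  tot <- tot[tot > 0]
  as.numeric(tot) / sum(tot)
}

# ---- diurnal movement ------------------------------------------------------

#' Diurnal movement regularity
#'
#' Spectral energy of the location time series in a period band around
#' 24 h.  The stay-point centroids are resampled to a regular grid
#' (position carried forward through travel and short gaps; gaps longer
#' than `max_gap_min` left missing), a least-squares (Lomb) spectral
#' estimate is computed for the latitude and longitude series separately,
#' and the score is \eqn{\ln(E_{lat} + E_{lon})} with \eqn{E} the summed
#' power over the band.  Higher scores indicate a repetitive, regular
#' 24-hour movement routine; the score is floored at `log(1e-12)` for
#' degenerate (e.g. constant-location) series.
#'
#' @param staypoints Stay points of one subject (any tibble with
#'   `arrival`, `departure`, `centroid_lat`, `centroid_lon`).
#' @param tz IANA timezone (used only to count distinct local days).
#' @param grid_interval_min Resampling interval, minutes. Default 10.
#' @param band_h Period band in hours, default `c(23.5, 24.5)`.
#' @param max_gap_min Maximum carry-forward through a gap, minutes.
#' @return The score, or `NA` with fewer than 3 days of data.
#' @export
diurnal_movement <- function(staypoints, tz, grid_interval_min = 10,
                             band_h = c(23.5, 24.5), max_gap_min = 60) {
  sp <- staypoints[order(staypoints$arrival), , drop = FALSE]
  if (nrow(sp) == 0) return(NA_real_)
  n_days <- length(unique(c(local_date(sp$arrival, tz),
                            local_date(sp$departure, tz))))
  if (n_days < 3) return(NA_real_)
  grid <- seq(sp$arrival[1], sp$departure[nrow(sp)],
              by = grid_interval_min * 60000)
  pos <- grid_positions(grid, sp, max_gap_min * 60000)
  span_s <- (grid[length(grid)] - grid[1]) / 1000
  freqs <- band_frequencies(band_h, span_s)
  t_s <- (grid - grid[1]) / 1000
  e_lat <- lomb_scargle_power(t_s, pos$lat, freqs)
  e_lon <- lomb_scargle_power(t_s, pos$lon, freqs)
  energy <- sum(e_lat, na.rm = TRUE) + sum(e_lon, na.rm = TRUE)
  log(max(energy, 1e-12))
}

# position of each grid time: inside a stay point -> its centroid; after a
# stay point, carried forward up to max_gap_ms; otherwise missing.
grid_positions <- function(grid, sp, max_gap_ms) {
  idx <- findInterval(grid, sp$arrival)  # last sp with arrival <= t
  lat <- rep(NA_real_, length(grid))
  lon <- rep(NA_real_, length(grid))
  has <- idx > 0
  i <- idx[has]
  within <- grid[has] <= sp$departure[i] |
    (grid[has] - sp$departure[i]) <= max_gap_ms
  lat[has][within] <- sp$centroid_lat[i][within]
  lon[has][within] <- sp$centroid_lon[i][within]
  list(lat = lat, lon = lon)
}

# ---- duration adjustment ---------------------------------------------------

#' Adjust count phenotypes for observation length
#'
#' Regresses each count phenotype on the number of days observed across
#' subjects (ordinary least squares) and replaces the raw value by its
#' residual plus the grand mean, so the adjusted scale remains
#' interpretable.  Residuals are exactly orthogonal to the duration
#' regressor.
#'
#' @param cohort A data frame with one row per subject.
#' @param count_cols Names of the count columns to adjust.
#' @param n_days_col Name of the observation-length column.
#' @return `cohort` with an `<col>_adj` column added per count column.
#'   With fewer than 3 subjects, or when all durations are equal (the
#'   model reduces to the intercept and adjusted values equal the raw
#'   counts), a warning is raised.
#' @export
adjust_counts_for_duration <- function(cohort,
                                       count_cols = c("places_visited",
                                                      "unique_places",
                                                      "trajectories"),
                                       n_days_col = "n_days_observed") {
  stopifnot(n_days_col %in% names(cohort),
            all(count_cols %in% names(cohort)))
  if (nrow(cohort) < 3) {
    warning("duration adjustment with fewer than 3 subjects is unreliable")
  }
  n_days <- cohort[[n_days_col]]
  constant <- length(unique(n_days)) == 1
  if (constant) {
    warning("all subjects observed equally long; adjustment leaves counts unchanged")
  }
  for (col in count_cols) {
    y <- cohort[[col]]
    if (constant || nrow(cohort) < 2) {
      adj <- y
    } else {
      fit <- stats::lm(y ~ n_days)
      adj <- stats::resid(fit) + mean(y)
    }
    cohort[[paste0(col, "_adj")]] <- as.numeric(adj)
  }
  cohort
}

# ---- per-subject driver ----------------------------------------------------

#' Derive all phenotypes for one subject
#'
#' Runs the full per-subject pipeline -- confidence filter, gap
#' segmentation, stay-point detection, place clustering, home inference --
#' and derives the six phenotypes per local day and for the whole window.
#'
#' @param trace A `geo_trace`.
#' @param config A [geopheno_config()].
#' @return A list with:
#'   `per_day` (one row per observed local day: counts, home-stay hours
#'   and percent, normalized entropy), `summary` (one row: window totals,
#'   per-day means, window entropy, diurnal movement, `n_days_observed`,
#'   `home_determined`), plus the intermediate `staypoints`,
#'   `trajectories`, `clusters` and `home` objects.
#' @export
derive_phenotypes <- function(trace, config = geopheno_config()) {
  stopifnot(inherits(trace, "geo_trace"))
  tz <- trace$timezone
  filtered <- filter_by_confidence(trace, config$max_confidence_m,
                                   missing = config$missing_confidence)
  segmented <- segment_on_gaps(filtered, config$max_gap_min)
  det <- detect_staypoints(segmented, config$theta_t_min, config$theta_d_m)
  clustered <- cluster_staypoints(det$staypoints, config$epsilon_m,
                                  config$min_points)
  home <- infer_home(clustered, tz, config$night_window)

  observed_dates <- sort(unique(local_date(segmented$points$timestamp, tz)))
  n_days_observed <- length(observed_dates)

  per_day <- count_phenotypes(clustered$staypoints, det$trajectories, tz,
                              dates = observed_dates)
  ov <- sp_day_overlap(clustered$staypoints, tz)
  per_day$normalized_entropy <- vapply(per_day$date, function(d) {
    sub <- ov[ov$date == d & ov$overlap_ms > 0, , drop = FALSE]
    if (nrow(sub) == 0) return(NA_real_)
    normalized_entropy(dwell_distribution(sub$cluster_id, sub$overlap_ms))
  }, numeric(1))
  if (home$determined) {
    hs <- home_stay(clustered, home$home_cluster_id, tz,
                    dates = observed_dates,
                    denominator = config$homestay_denominator)
    per_day$home_stay_hours <- hs$home_stay_hours
    per_day$home_stay_pct <- hs$home_stay_pct
  } else {
    per_day$home_stay_hours <- NA_real_
    per_day$home_stay_pct <- NA_real_
  }

  win_entropy <- if (nrow(clustered$staypoints)) {
    normalized_entropy(dwell_distribution(
      clustered$staypoints$cluster_id,
      clustered$staypoints$duration_min))
  } else NA_real_
  summary <- tibble::tibble(
    subject_id = trace$subject_id,
    n_days_observed = n_days_observed,
    places_visited = nrow(clustered$staypoints),
    unique_places = length(unique(clustered$staypoints$cluster_id)),
    trajectories = nrow(det$trajectories),
    places_visited_per_day = mean(per_day$places_visited),
    unique_places_per_day = mean(per_day$unique_places),
    trajectories_per_day = mean(per_day$trajectories),
    home_stay_hours = mean(per_day$home_stay_hours, na.rm = TRUE),
    home_stay_pct = mean(per_day$home_stay_pct, na.rm = TRUE),
    normalized_entropy = win_entropy,
    diurnal_movement = diurnal_movement(
      clustered$staypoints, tz, config$grid_interval_min,
      config$period_band_h, config$max_gap_min),
    home_determined = home$determined
  )
  if (!home$determined) {
    summary$home_stay_hours <- NA_real_
    summary$home_stay_pct <- NA_real_
  }
  list(per_day = per_day, summary = summary,
       staypoints = clustered$staypoints, trajectories = det$trajectories,
       clusters = clustered$clusters, home = home)
}
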