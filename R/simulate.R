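# Labelled synthetic location traces.
#
# The simulator emulates the structure the preprocessing framework is built
# for: a small set of recurrent places (home plus a few daytime places), a
# daily routine of dwell episodes joined by straight-line travel legs,
# duty-cycled sampling with dropout bursts, and per-fix positional noise
# expressed as a 68%-containment confidence radius.  Because the positional
# error is radial-Gaussian (Rayleigh), drawing the Gaussian scale as
# sigma = confidence / sqrt(-2 ln 0.32) makes the 68th percentile of the
# radial error equal the stated confidence.  Every generated fix and
# episode carries ground-truth labels, so all downstream metrics can be
# scored exactly.

RAYLEIGH_68 <- sqrt(-2 * log(0.32))  # ~1.5096

# sample() that never falls into the scalar-x trap
resample <- function(x, size = 1, ...) x[sample.int(length(x), size, ...)]

#' Positional noise model
#'
#' @param mean_range Range (meters) from which each subject's mean
#'   confidence radius is drawn uniformly; the default 25--170 m spans the
#'   per-subject means observed on real smartphone data.
#' @param jitter_frac Per-fix confidence is the subject mean times a
#'   uniform factor in `1 +/- jitter_frac`. Default 0.2.
#' @return A noise-model list, or use `NULL` anywhere a noise model is
#'   accepted for noiseless fixes.
#' @export
noise_model <- function(mean_range = c(25, 170), jitter_frac = 0.2) {
  stopifnot(length(mean_range) == 2, mean_range[1] <= mean_range[2],
            mean_range[1] >= 0, jitter_frac >= 0, jitter_frac < 1)
  list(mean_range = mean_range, jitter_frac = jitter_frac)
}

#' Lay out simulated places
#'
#' Home sits at the base coordinate; the other places are placed at random
#' bearings with all pairwise separations at least `min_separation_m`
#' (rejection sampling under the current RNG state).
#'
#' @param n_other Number of non-home places.
#' @param base_lat,base_lon Home coordinate, decimal degrees.
#' @param min_separation_m Minimum pairwise separation, meters. Default 600.
#' @param max_radius_m Maximum distance of a place from home. Default 3000.
#' @return A tibble with `place_id`, `lat`, `lon`, `role`.
#' @export
sim_places <- function(n_other = 3, base_lat = 52.10, base_lon = 5.12,
                       min_separation_m = 600, max_radius_m = 3000) {
  stopifnot(n_other >= 0, min_separation_m > 0,
            max_radius_m > min_separation_m)
  mpd <- meters_per_degree(base_lat)
  lat <- base_lat
  lon <- base_lon
  while (length(lat) < n_other + 1) {
    r <- stats::runif(1, min_separation_m, max_radius_m)
    ang <- stats::runif(1, 0, 2 * pi)
    cand_lat <- base_lat + r * sin(ang) / mpd["lat"]
    cand_lon <- base_lon + r * cos(ang) / mpd["lon"]
    if (all(haversine_m(cand_lat, cand_lon, lat, lon) >= min_separation_m)) {
      lat <- c(lat, cand_lat)
      lon <- c(lon, cand_lon)
    }
  }
  tibble::tibble(place_id = seq_len(n_other + 1), lat = lat, lon = lon,
                 role = c("home", rep("other", n_other)))
}

#' Simulate one subject's labelled trace
#'
#' Generates a daily routine -- overnight at home (with probability
#' `p_home_night` per night), a morning departure, a few visits to other
#' places joined by straight-line travel legs, and an evening return --
#' then samples it at a fixed interval with bursty dropout and applies the
#' confidence-scaled positional noise.  Dwell and travel episodes tile the
#' simulated span exactly.
#'
#' @param seed Integer seed; the same seed reproduces the output exactly.
#' @param subject_id Subject identifier.
#' @param n_days Number of simulated days. Default 14.
#' @param n_other_places Number of non-home places. Default 3.
#' @param trips_per_day Integer range `c(lo, hi)` of daytime place visits
#'   per day. Default `c(2, 4)`.
#' @param dwell_min_range Dwell duration range at daytime places, minutes.
#'   Default `c(90, 180)`.
#' @param leave_home_h Morning departure window, hours after local
#'   midnight. Default `c(8, 9.5)`.
#' @param day_end_h Latest time by which the subject heads to the night
#'   place, hours. Default 22.
#' @param speed_mps Travel speed, meters per second. Default 8.
#' @param sampling_interval_min Fix sampling interval, minutes. Default 5.
#' @param dropout_rate Long-run fraction of fixes lost to dropout bursts.
#'   Default 0.10.
#' @param dropout_mean_min Mean dropout-burst length, minutes. Default 15.
#' @param noise A [noise_model()], or `NULL` for noiseless fixes (missing
#'   confidence).
#' @param p_home_night Probability a night is spent at home. Default 1.
#' @param base_lat,base_lon Home coordinate.
#' @param min_separation_m Minimum pairwise place separation, meters.
#' @param start_date First local day (`Date` or string).
#' @param timezone IANA timezone of the subject.
#'
#' @return A list: `trace` (a `geo_trace`) and `truth`, which carries
#'   `episodes` (`episode_id`, `type` dwell/travel, `place_id`,
#'   `from_place`/`to_place`, `start`, `end` in epoch ms), `fixes`
#'   (per retained fix: `timestamp`, ground-truth `state`, `episode_id`,
#'   `place_id`, `true_lat`, `true_lon`), `home_place_id`, `places`, and
#'   the subject's mean confidence `confidence_mean_m` (`NA` if noiseless).
#' @export
simulate_subject <- function(seed, subject_id = "S1", n_days = 14,
                             n_other_places = 3, trips_per_day = c(2, 4),
                             dwell_min_range = c(90, 180),
                             leave_home_h = c(8, 9.5), day_end_h = 22,
                             speed_mps = 8, sampling_interval_min = 5,
                             dropout_rate = 0.10, dropout_mean_min = 15,
                             noise = noise_model(), p_home_night = 1,
                             base_lat = 52.10, base_lon = 5.12,
                             min_separation_m = 600,
                             start_date = "2024-03-04", timezone = "UTC") {
  stopifnot(n_days >= 1, speed_mps > 0, sampling_interval_min > 0,
            dropout_rate >= 0, dropout_rate < 1,
            dwell_min_range[1] > 0, p_home_night >= 0, p_home_night <= 1)
  set.seed(as.integer(seed))
  places <- sim_places(n_other_places, base_lat, base_lon, min_separation_m)
  date0 <- as.Date(start_date)
  mids <- local_midnight_ms(date0 + 0:n_days, timezone)
  schedule <- build_schedule(places, n_days, mids, trips_per_day,
                             dwell_min_range, leave_home_h, day_end_h,
                             speed_mps, p_home_night)
  sample_schedule(schedule, places, subject_id, timezone,
                  sampling_interval_min, dropout_rate, dropout_mean_min,
                  noise, base_lat)
}

# dwell/travel episode list tiling [mids[1], mids[n_days+1]]
build_schedule <- function(places, n_days, mids, trips_per_day,
                           dwell_min_range, leave_home_h, day_end_h,
                           speed_mps, p_home_night) {
  other_ids <- places$place_id[places$role != "home"]
  dist_m <- function(a, b) {
    haversine_m(places$lat[a], places$lon[a], places$lat[b], places$lon[b])
  }
  eps <- list()
  push <- function(type, place = NA_integer_, from = NA_integer_,
                   to = NA_integer_, s, e) {
    eps[[length(eps) + 1L]] <<- list(type = type, place_id = place,
                                     from_place = from, to_place = to,
                                     start = s, end = e)
  }
  cur <- 1L            # overnight place before day 1 is home
  dwell_start <- mids[1]
  for (d in seq_len(n_days)) {
    leave <- mids[d] + stats::runif(1, leave_home_h[1], leave_home_h[2]) *
      3600000
    day_end <- mids[d] + day_end_h * 3600000
    n_trips <- if (length(other_ids)) {
      resample(seq(trips_per_day[1], trips_per_day[2]))
    } else 0L
    t <- leave
    made_trip <- FALSE
    for (k in seq_len(n_trips)) {
      choices <- setdiff(other_ids, cur)
      if (!length(choices)) break
      dest <- resample(choices)
      travel_ms <- dist_m(cur, dest) / speed_mps * 1000
      dwell_ms <- stats::runif(1, dwell_min_range[1], dwell_min_range[2]) *
        60000
      back_ms <- dist_m(dest, 1L) / speed_mps * 1000
      if (t + travel_ms + dwell_ms + back_ms > day_end) break
      # close the open dwell at the current place, then travel
      push("dwell", place = cur, s = dwell_start, e = t)
      push("travel", from = cur, to = dest, s = t, e = t + travel_ms)
      cur <- dest
      dwell_start <- t + travel_ms
      t <- dwell_start + dwell_ms
      made_trip <- TRUE
    }
    # head to the night place
    night_place <- if (stats::runif(1) < p_home_night) 1L else {
      resample(other_ids)
    }
    if (cur != night_place) {
      depart <- if (made_trip) t else leave
      travel_ms <- dist_m(cur, night_place) / speed_mps * 1000
      push("dwell", place = cur, s = dwell_start, e = depart)
      push("travel", from = cur, to = night_place, s = depart,
           e = depart + travel_ms)
      cur <- night_place
      dwell_start <- depart + travel_ms
    }
    # otherwise the open dwell simply continues into the night
  }
  push("dwell", place = cur, s = dwell_start, e = mids[n_days + 1])
  ep <- dplyr::bind_rows(lapply(eps, tibble::as_tibble))
  if (any(ep$end < ep$start)) stop("infeasible schedule generated",
                                   call. = FALSE)
  ep$episode_id <- seq_len(nrow(ep))
  ep
}

sample_schedule <- function(episodes, places, subject_id, timezone,
                            sampling_interval_min, dropout_rate,
                            dropout_mean_min, noise, base_lat) {
  interval_ms <- sampling_interval_min * 60000
  t0 <- episodes$start[1]
  t1 <- episodes$end[nrow(episodes)]
  grid <- seq(t0, t1, by = interval_ms)
  keep <- dropout_mask(length(grid), dropout_rate,
                       max(1, round(dropout_mean_min /
                                      sampling_interval_min)))
  grid <- grid[keep]
  # ground-truth position per fix
  ep_idx <- pmin(findInterval(grid, episodes$start), nrow(episodes))
  lat <- numeric(length(grid))
  lon <- numeric(length(grid))
  for (i in seq_along(grid)) {
    e <- ep_idx[i]
    if (episodes$type[e] == "dwell") {
      p <- episodes$place_id[e]
      lat[i] <- places$lat[p]
      lon[i] <- places$lon[p]
    } else {
      frac <- (grid[i] - episodes$start[e]) /
        max(1, episodes$end[e] - episodes$start[e])
      a <- episodes$from_place[e]
      b <- episodes$to_place[e]
      lat[i] <- places$lat[a] + frac * (places$lat[b] - places$lat[a])
      lon[i] <- places$lon[a] + frac * (places$lon[b] - places$lon[a])
    }
  }
  conf_mean <- NA_real_
  conf <- rep(NA_real_, length(grid))
  obs_lat <- lat
  obs_lon <- lon
  if (!is.null(noise)) {
    conf_mean <- stats::runif(1, noise$mean_range[1], noise$mean_range[2])
    conf <- conf_mean * stats::runif(length(grid), 1 - noise$jitter_frac,
                                     1 + noise$jitter_frac)
    sigma <- conf / RAYLEIGH_68
    mpd <- meters_per_degree(base_lat)
    obs_lat <- lat + stats::rnorm(length(grid), 0, sigma) / mpd["lat"]
    obs_lon <- lon + stats::rnorm(length(grid), 0, sigma) / mpd["lon"]
  }
  trace <- new_trace(
    tibble::tibble(timestamp = grid, lat = obs_lat, lon = obs_lon,
                   confidence_m = conf),
    subject_id = subject_id, timezone = timezone)
  fixes <- tibble::tibble(
    timestamp = grid,
    state = ifelse(episodes$type[ep_idx] == "dwell", "stationary",
                   "non-stationary"),
    episode_id = episodes$episode_id[ep_idx],
    place_id = episodes$place_id[ep_idx],
    true_lat = lat, true_lon = lon)
  list(trace = trace,
       truth = list(episodes = episodes, fixes = fixes,
                    home_place_id = 1L, places = places,
                    confidence_mean_m = conf_mean))
}

# bursty dropout: two-state Markov chain whose stationary off-fraction is
# `rate` and whose mean off-run is `mean_run` samples; starts on.
dropout_mask <- function(n, rate, mean_run) {
  if (rate <= 0 || n == 0) return(rep(TRUE, n))
  p_exit <- 1 / mean_run
  p_enter <- p_exit * rate / (1 - rate)
  keep <- logical(n)
  on <- TRUE
  u <- stats::runif(n)
  for (i in seq_len(n)) {
    keep[i] <- on
    on <- if (on) u[i] >= p_enter else u[i] < p_exit
  }
  keep
}

#' Simulate a labelled cohort
#'
#' Independent subjects with per-subject seeds derived deterministically
#' from the master seed.  Archetypes shift routine parameters (places,
#' trips per day, noise) between groups of subjects so that phenotype
#' distributions move in a configured direction.
#'
#' @param n_subjects Number of subjects when `archetypes` is `NULL`.
#' @param seed Master seed.
#' @param archetypes Optional list of archetype specs; each is a list with
#'   `n` (subjects in the group) plus any [simulate_subject()] argument to
#'   override, and optionally a `name`.
#' @param n_other_places Scalar, or range `c(lo, hi)` sampled per subject.
#' @param trips_per_day Passed to [simulate_subject()].
#' @param ... Further arguments passed to every [simulate_subject()] call.
#' @return A list of [simulate_subject()] results; each element gains
#'   `archetype` (group name) and `subject_id` is `"S01"`, `"S02"`, ...
#' @export
simulate_cohort <- function(n_subjects = 10, seed = 1, archetypes = NULL,
                            n_other_places = c(2, 4),
                            trips_per_day = c(2, 4), ...) {
  set.seed(as.integer(seed))
  if (is.null(archetypes)) {
    archetypes <- list(list(n = n_subjects, name = "default"))
  }
  specs <- list()
  for (a in seq_along(archetypes)) {
    arch <- archetypes[[a]]
    nm <- if (!is.null(arch$name)) arch$name else paste0("arch", a)
    for (k in seq_len(arch$n)) {
      ov <- arch[setdiff(names(arch), c("n", "name"))]
      specs[[length(specs) + 1L]] <- list(name = nm, overrides = ov)
    }
  }
  n_total <- length(specs)
  seeds <- sample.int(.Machine$integer.max - 1L, n_total)
  n_other_each <- if (length(n_other_places) > 1) {
    resample(seq(n_other_places[1], n_other_places[2]), n_total,
             replace = TRUE)
  } else rep(n_other_places, n_total)
  common <- list(...)
  lapply(seq_len(n_total), function(i) {
    args <- c(list(seed = seeds[i],
                   subject_id = sprintf("S%02d", i),
                   trips_per_day = trips_per_day),
              common)
    args$n_other_places <- n_other_each[i]
    for (nm in names(specs[[i]]$overrides)) {
      args[[nm]] <- specs[[i]]$overrides[[nm]]
    }
    out <- do.call(simulate_subject, args)
    out$archetype <- specs[[i]]$name
    out
  })
}
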