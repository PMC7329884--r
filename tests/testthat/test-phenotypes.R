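# Count phenotypes, home inference, home stay, entropy, diurnal movement,
# duration adjustment.

# build a clustered stay-point structure from dwell episodes given as
# (offset_m north of base, arrival_h, departure_h) rows; places far apart
# cluster separately at eps = 150 m
clustered_from <- function(offsets_m, arrival_h, departure_h) {
  n <- length(offsets_m)
  sp <- tibble::tibble(
    subject_id = "T", segment_id = 1L,
    centroid_lat = 52 + deg_lat(offsets_m), centroid_lon = 5,
    arrival = 1709510400000 + arrival_h * 3600000,
    departure = 1709510400000 + departure_h * 3600000,
    first_idx = seq_len(n), last_idx = seq_len(n), n_fixes = 1L,
    sp_id = seq_len(n),
    duration_min = (departure_h - arrival_h) * 60)
  cluster_staypoints(sp, epsilon_m = 150)
}

test_that("count phenotypes per day, with midnight spans counted once on arrival", {
  # day 1: 3 stay points in 2 places, the third arriving 23:50 and spanning
  # midnight; 2 trajectories
  cl <- clustered_from(c(0, 1000, 0),
                       arrival_h = c(8, 12, 23 + 50 / 60),
                       departure_h = c(10, 14, 26))
  tra <- tibble::tibble(subject_id = "T", segment_id = 1L,
                        start = 1709510400000 + c(10, 14) * 3600000,
                        end = 1709510400000 + c(12, 15) * 3600000,
                        first_idx = 1:2, last_idx = 2:3, n_fixes = 2L,
                        traj_id = 1:2)
  counts <- count_phenotypes(cl$staypoints, tra, tz = "UTC",
                             dates = as.Date("2024-03-04") + 0:1)
  expect_equal(counts$places_visited, c(3, 0))  # midnight span: arrival day only
  expect_equal(counts$unique_places, c(2, 0))
  expect_equal(counts$trajectories, c(2, 0))
  # empty day yields zeros
  counts2 <- count_phenotypes(cl$staypoints[0, ], tra[0, ], tz = "UTC",
                              dates = as.Date("2024-03-04"))
  expect_equal(unlist(counts2[1, -1]), c(places_visited = 0,
                                         unique_places = 0,
                                         trajectories = 0))
})

test_that("home is the dominant-nighttime cluster; ties break by total dwell", {
  # A occupied overnight, B by day, across 3 days
  cl <- clustered_from(
    rep(c(0, 2000), 3),
    arrival_h = c(0, 9, 20, 33, 44, 57),
    departure_h = c(8, 17, 32, 41, 56, 65))
  home <- infer_home(cl, tz = "UTC")
  expect_true(home$determined)
  place_a <- cl$staypoints$cluster_id[1]
  expect_equal(home$home_cluster_id, place_a)

  # equal nighttime dwell (3 h each), A has more total dwell -> A wins
  cl_tie <- clustered_from(c(0, 2000, 0),
                           arrival_h = c(0, 3, 10),
                           departure_h = c(3, 6, 15))
  home_tie <- infer_home(cl_tie, tz = "UTC")
  expect_equal(home_tie$home_cluster_id, cl_tie$staypoints$cluster_id[1])

  # no nighttime dwell at all -> undetermined
  cl_day <- clustered_from(c(0, 2000), arrival_h = c(9, 13),
                           departure_h = c(12, 16))
  home_day <- infer_home(cl_day, tz = "UTC")
  expect_false(home_day$determined)
  expect_true(is.na(home_day$home_cluster_id))
})

test_that("home stay: arithmetic, conservation, and proportional midnight split", {
  # 18 h at home + 6 h elsewhere on one day
  cl <- clustered_from(c(0, 2000, 0), arrival_h = c(0, 6, 12),
                       departure_h = c(6, 12, 24))
  home_id <- cl$staypoints$cluster_id[1]
  hs <- home_stay(cl, home_id, tz = "UTC",
                  dates = as.Date("2024-03-04"))
  expect_equal(hs$home_stay_hours, 18)
  expect_equal(hs$home_stay_pct, 75)
  expect_equal(hs$total_dwell_hours, 24)
  # all dwell at home -> 100%
  cl_all <- clustered_from(0, arrival_h = 0, departure_h = 24)
  hs_all <- home_stay(cl_all, cl_all$staypoints$cluster_id[1], tz = "UTC",
                      dates = as.Date("2024-03-04"))
  expect_equal(hs_all$home_stay_pct, 100)
  # a home stay 20:00 -> 04:00 splits 4 h / 4 h over the two days
  cl_span <- clustered_from(0, arrival_h = 20, departure_h = 28)
  hs_span <- home_stay(cl_span, cl_span$staypoints$cluster_id[1],
                       tz = "UTC")
  expect_equal(hs_span$home_stay_hours, c(4, 4))
  expect_true(all(hs_span$home_stay_hours <= 24))
  # elapsed denominator uses the 24-h day
  hs_el <- home_stay(cl_span, cl_span$staypoints$cluster_id[1], tz = "UTC",
                     denominator = "elapsed")
  expect_equal(hs_el$home_stay_pct, c(100 * 4 / 24, 100 * 4 / 24))
})

test_that("normalized entropy matches its closed forms and stays in [0, 1]", {
  expect_equal(normalized_entropy(rep(0.25, 4)), 1)
  expect_equal(normalized_entropy(1), 0)
  expect_equal(normalized_entropy(c(0.8, 0.2)),
               -(0.8 * log(0.8) + 0.2 * log(0.2)) / log(2))
  expect_equal(normalized_entropy(c(0.8, 0.2)), 0.7219281, tolerance = 1e-6)
  set.seed(3)
  for (k in 1:25) {
    p <- runif(sample(1:6, 1))
    p <- p / sum(p)
    h <- normalized_entropy(p)
    expect_gte(h, 0)
    expect_lte(h, 1)
  }
  expect_error(normalized_entropy(c(0.5, 0.4)))  # not a distribution
})

test_that("diurnal movement ranks a periodic routine above an irregular one", {
  # 14 days, home overnight and a work place 2 km away
  make_routine <- function(work_starts_h) {
    n_days <- length(work_starts_h)
    rows <- lapply(seq_len(n_days) - 1, function(d) {
      ws <- 24 * d + work_starts_h[d + 1]
      tibble::tibble(offset = c(0, 2000, 0),
                     arr = c(24 * d, ws, ws + 8.2),
                     dep = c(ws - 0.2, ws + 8, 24 * (d + 1)))
    })
    df <- dplyr::bind_rows(rows)
    clustered_from(df$offset, df$arr, df$dep)$staypoints
  }
  periodic <- make_routine(rep(9, 14))
  set.seed(57)
  irregular <- make_routine(runif(14, 2, 15))
  s_per <- diurnal_movement(periodic, tz = "UTC")
  s_irr <- diurnal_movement(irregular, tz = "UTC")
  expect_gt(s_per, s_irr)
  # constant location: zero band energy, guarded at the documented floor
  const <- clustered_from(rep(0, 5), arrival_h = (0:4) * 24,
                          departure_h = (1:5) * 24 - 0.01)
  expect_equal(diurnal_movement(const$staypoints, tz = "UTC"), log(1e-12))
  # under 3 days of data the phenotype is missing
  short <- clustered_from(0, 0, 20)
  expect_true(is.na(diurnal_movement(short$staypoints, tz = "UTC")))
})

test_that("the spectral estimate equals a direct least-squares sinusoid fit", {
  set.seed(61)
  t_s <- sort(runif(300, 0, 10 * 86400))
  x <- 3 * sin(2 * pi * t_s / 86400 + 0.7) + rnorm(300, 0, 0.5)
  f <- 1 / 86400
  got <- geopheno:::lomb_scargle_power(t_s, x, f)
  xc <- x - mean(x)
  fit <- lm(xc ~ 0 + cos(2 * pi * f * t_s) + sin(2 * pi * f * t_s))
  want <- (sum(xc^2) - sum(resid(fit)^2)) / 2
  expect_equal(got, want, tolerance = 1e-9)
})

test_that("duration adjustment: perfect fit, constant duration, orthogonality", {
  # counts exactly proportional to observation length -> constant adjusted
  cohort <- tibble::tibble(subject_id = letters[1:6],
                           n_days_observed = c(7, 10, 14, 20, 25, 30))
  cohort$places_visited <- 3 * cohort$n_days_observed
  cohort$unique_places <- cohort$n_days_observed
  cohort$trajectories <- 2 * cohort$n_days_observed
  adj <- adjust_counts_for_duration(cohort)
  expect_equal(adj$places_visited_adj,
               rep(mean(cohort$places_visited), 6))
  # constant duration -> adjusted equals raw, with a warning
  cohort2 <- cohort
  cohort2$n_days_observed <- 14
  expect_warning(adj2 <- adjust_counts_for_duration(cohort2), "unchanged")
  expect_equal(adj2$places_visited_adj, cohort2$places_visited)
  # random cohort: residuals exactly orthogonal to duration
  set.seed(71)
  cohort3 <- tibble::tibble(
    subject_id = sprintf("s%02d", 1:40),
    n_days_observed = sample(7:30, 40, replace = TRUE))
  cohort3$places_visited <- rpois(40, 3 * cohort3$n_days_observed / 7)
  cohort3$unique_places <- rpois(40, 5)
  cohort3$trajectories <- rpois(40, 2 * cohort3$n_days_observed / 7)
  adj3 <- adjust_counts_for_duration(cohort3)
  for (col in c("places_visited_adj", "unique_places_adj",
                "trajectories_adj")) {
    r <- cor(adj3[[col]] - mean(adj3[[col]]), cohort3$n_days_observed)
    expect_lt(abs(r), 1e-10)
  }
})
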