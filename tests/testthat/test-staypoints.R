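# Haversine geometry and the anchor-sweep stay-point detector.

test_that("haversine distance: identity, known value, symmetry", {
  expect_equal(haversine_m(52.1, 5.12, 52.1, 5.12), 0)
  # one degree of longitude at the equator = 2*pi*R/360
  expect_equal(haversine_m(0, 0, 0, 1), 2 * pi * 6371008.8 / 360,
               tolerance = 1e-9)
  set.seed(11)
  for (k in 1:20) {
    a <- c(runif(1, -80, 80), runif(1, -179, 179))
    b <- c(runif(1, -80, 80), runif(1, -179, 179))
    expect_equal(haversine_m(a[1], a[2], b[1], b[2]),
                 haversine_m(b[1], b[2], a[1], a[2]))
  }
  expect_error(haversine_m(95, 0, 0, 0))
})

test_that("a 60-min dwell at one coordinate yields exactly one stay point (inclusive boundary)", {
  tr <- make_trace(seq(0, 60, by = 5), rep(52.1, 13), rep(5.12, 13))
  det <- detect_staypoints(tr, theta_t_min = 60, theta_d_m = 350)
  expect_equal(nrow(det$staypoints), 1)
  expect_equal(det$staypoints$arrival, tr$points$timestamp[1])
  expect_equal(det$staypoints$departure, tr$points$timestamp[13])
  expect_equal(det$staypoints$n_fixes, 13)
  expect_equal(nrow(det$trajectories), 0)
  expect_true(all(label_states(tr, det$staypoints) == "stationary"))
})

test_that("constant motion yields no stay points and one spanning trajectory", {
  # 20 km/h north, one fix per minute for 2 h
  t <- 0:120
  lat <- 52 + deg_lat(t * 20000 / 60)
  tr <- make_trace(t, lat, rep(5, length(t)))
  det <- detect_staypoints(tr, 60, 350)
  expect_equal(nrow(det$staypoints), 0)
  expect_equal(nrow(det$trajectories), 1)
  expect_equal(det$trajectories$n_fixes, length(t))
  expect_true(all(label_states(tr, det$staypoints) == "non-stationary"))
})

test_that("two dwells joined by a travel run match the hand-traced sweep", {
  # 90 min at A (fixes every 5 min, t = 0..90), 15-min travel run
  # (t = 95, 100, 105 at 500/1000/1500 m), 90 min at B 2 km north
  # (t = 110..200).  Hand trace: anchor 1 extends through fix 19 (all at A),
  # fix 20 at 500 m breaks the window, span 90 >= 60 -> SP over 1..19.
  # Anchors 20..22 fail (spans < 60 within 350 m), anchor 23 (B, t = 110)
  # extends to the end, span 90 -> SP over 23..41.  One trajectory between.
  tA <- seq(0, 90, by = 5)
  tT <- c(95, 100, 105)
  tB <- seq(110, 200, by = 5)
  lat <- 52 + deg_lat(c(rep(0, length(tA)), c(500, 1000, 1500),
                        rep(2000, length(tB))))
  tr <- make_trace(c(tA, tT, tB), lat, rep(5, length(lat)))
  det <- detect_staypoints(tr, 60, 350)
  expect_equal(nrow(det$staypoints), 2)
  expect_equal(det$staypoints$first_idx, c(1, 23))
  expect_equal(det$staypoints$last_idx, c(19, 41))
  expect_equal(det$staypoints$arrival / 60000 - tr$points$timestamp[1] / 60000,
               c(0, 110))
  expect_equal(det$staypoints$departure / 60000 - tr$points$timestamp[1] / 60000,
               c(90, 200))
  expect_equal(nrow(det$trajectories), 1)
  expect_equal(det$trajectories$first_idx, 20)
  expect_equal(det$trajectories$last_idx, 22)
  # trajectory runs from the departure of SP1 to the arrival of SP2
  expect_equal(det$trajectories$start, det$staypoints$departure[1])
  expect_equal(det$trajectories$end, det$staypoints$arrival[2])
  lab <- label_states(tr, det$staypoints)
  expect_equal(lab, c(rep("stationary", 19), rep("non-stationary", 3),
                      rep("stationary", 19)))
})

test_that("detector equals the brute-force window oracle on random segments", {
  set.seed(23)
  for (rep_i in 1:25) {
    n <- sample(5:50, 1)
    t <- cumsum(c(0, sample(2:12, n - 1, replace = TRUE)))  # irregular
    # random walk with occasional jumps, scaled to straddle theta_d
    step <- ifelse(runif(n) < 0.2, 400, 40)
    lat <- 52 + deg_lat(cumsum(step * sample(c(-1, 1), n, replace = TRUE)))
    tr <- make_trace(t, lat, rep(5, n))
    got <- detect_staypoints(tr, theta_t_min = 30, theta_d_m = 350)$staypoints
    want <- oracle_staypoints(tr$points$timestamp, tr$points$lat,
                              tr$points$lon, 30 * 60000, 350)
    expect_equal(nrow(got), length(want))
    if (length(want)) {
      expect_equal(got$first_idx, sapply(want, `[`, 1))
      expect_equal(got$last_idx, sapply(want, `[`, 2))
    }
  }
})

test_that("stay points are time-disjoint, ordered, and labels partition the fixes", {
  set.seed(31)
  s <- simulate_subject(seed = 77, n_days = 3)
  seg <- segment_on_gaps(s$trace, 60)
  det <- detect_staypoints(seg, 60, 350)
  sp <- det$staypoints
  expect_true(all(diff(sp$arrival) >= 0))
  by_seg <- split(sp, sp$segment_id)
  for (g in by_seg) {
    if (nrow(g) > 1) {
      expect_true(all(g$arrival[-1] >= g$departure[-nrow(g)]))
      expect_true(all(g$first_idx[-1] > g$last_idx[-nrow(g)]))
    }
  }
  expect_true(all(sp$duration_min >= 60))
  lab <- label_states(seg, sp)
  expect_equal(length(lab), nrow(seg$points))
  n_stat <- sum(sp$n_fixes)
  expect_equal(sum(lab == "stationary"), n_stat)
  # trajectories cover exactly the complement
  expect_equal(sum(det$trajectories$n_fixes), nrow(seg$points) - n_stat)
})

test_that("raising theta_d never shrinks stationary time; raising theta_t never adds stay points", {
  set.seed(41)
  for (k in 1:5) {
    s <- simulate_subject(seed = 100 + k, n_days = 3)
    seg <- segment_on_gaps(s$trace, 60)
    stat_time <- sapply(c(150, 350, 700), function(td) {
      sp <- detect_staypoints(seg, 60, td)$staypoints
      sum(sp$departure - sp$arrival)
    })
    expect_true(all(diff(stat_time) >= 0))
    n_sp <- sapply(c(30, 60, 120), function(tt) {
      nrow(detect_staypoints(seg, tt, 350)$staypoints)
    })
    expect_true(all(diff(n_sp) <= 0))
  }
})

test_that("label_states rejects stay points from a different trace", {
  tr <- make_trace(seq(0, 60, 5), rep(52.1, 13), rep(5.12, 13))
  det <- detect_staypoints(tr, 60, 350)
  short <- make_trace(0:3, rep(52.1, 4), rep(5.12, 4))
  expect_error(label_states(short, det$staypoints), "match")
})
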