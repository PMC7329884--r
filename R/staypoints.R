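# Stay-point detection: the anchor-sweep algorithm.
#
# From an anchor fix i, the window is extended over fixes j while the
# haversine distance from the anchor stays within theta_d.  When the
# distance is first exceeded (or the segment ends), the window i..j-1
# becomes a stay point if its time span is at least theta_t (inclusive);
# the anchor then jumps to j.  Otherwise the anchor advances by one fix.
# The distance test is against the anchor (first fix of the window), not
# the pairwise diameter; this is the classic form of the algorithm and is
# kept fixed for reproducibility.

#' Detect stay points and trajectories
#'
#' Identifies stationary states (stay points) and the non-stationary runs
#' between them (trajectories) within each gap-free segment of a trace.
#'
#' @param trace A `geo_trace`, segmented with [segment_on_gaps()] (an
#'   unsegmented trace is treated as a single segment).
#' @param theta_t_min Duration threshold, minutes: a window qualifies as a
#'   stay point when its span is `>= theta_t_min` (inclusive). Default 60.
#' @param theta_d_m Distance threshold, meters: every member fix must lie
#'   within `theta_d_m` of the window's anchor fix. Default 350.
#'
#' @return A list with two tibbles.
#'   `staypoints`: one row per stay point with `subject_id`, `segment_id`,
#'   `sp_id`, `centroid_lat`/`centroid_lon` (unweighted mean of member
#'   fixes), `arrival`/`departure` (epoch ms), `first_idx`/`last_idx`
#'   (row indices into the trace points), `n_fixes`, `duration_min`.
#'   `trajectories`: one row per maximal non-stationary fix run with
#'   `start` (departure of the preceding stay point, or the run's first fix
#'   at a segment boundary), `end` (arrival of the following stay point, or
#'   the run's last fix), `first_idx`/`last_idx`, `n_fixes`.
#' @export
detect_staypoints <- function(trace, theta_t_min = 60, theta_d_m = 350) {
  stopifnot(inherits(trace, "geo_trace"), theta_t_min > 0, theta_d_m > 0)
  pts <- trace$points
  if (!"segment_id" %in% names(pts)) pts$segment_id <- 1L

  sp_rows <- list()
  tr_rows <- list()
  for (seg in unique(pts$segment_id)) {
    idx <- which(pts$segment_id == seg)
    res <- sweep_segment(pts$timestamp[idx], pts$lat[idx], pts$lon[idx],
                         theta_t_min * 60000, theta_d_m)
    ts <- pts$timestamp[idx]
    nseg <- length(idx)
    if (length(res)) {
      for (k in seq_along(res)) {
        w <- res[[k]]
        members <- idx[w[1]:w[2]]
        sp_rows[[length(sp_rows) + 1L]] <- tibble::tibble(
          subject_id = trace$subject_id,
          segment_id = seg,
          centroid_lat = mean(pts$lat[members]),
          centroid_lon = mean(pts$lon[members]),
          arrival = ts[w[1]],
          departure = ts[w[2]],
          first_idx = members[1],
          last_idx = members[length(members)],
          n_fixes = length(members)
        )
      }
    }
    # trajectories: maximal runs of fixes not covered by any stay point
    covered <- rep(FALSE, nseg)
    for (w in res) covered[w[1]:w[2]] <- TRUE
    if (any(!covered)) {
      runs <- index_runs(which(!covered))
      sp_starts <- vapply(res, `[`, integer(1), 1)
      sp_ends <- vapply(res, `[`, integer(1), 2)
      for (r in runs) {
        a <- r[1]; b <- r[2]
        prev_sp <- if (length(sp_ends) && any(sp_ends < a)) {
          max(sp_ends[sp_ends < a])
        } else NA_integer_
        next_sp <- if (length(sp_starts) && any(sp_starts > b)) {
          min(sp_starts[sp_starts > b])
        } else NA_integer_
        tr_rows[[length(tr_rows) + 1L]] <- tibble::tibble(
          subject_id = trace$subject_id,
          segment_id = seg,
          start = if (is.na(prev_sp)) ts[a] else ts[prev_sp],
          end = if (is.na(next_sp)) ts[b] else ts[next_sp],
          first_idx = idx[a],
          last_idx = idx[b],
          n_fixes = b - a + 1L
        )
      }
    }
  }
  staypoints <- dplyr::bind_rows(sp_rows)
  if (nrow(staypoints) == 0) {
    staypoints <- tibble::tibble(
      subject_id = character(), segment_id = integer(),
      centroid_lat = double(), centroid_lon = double(),
      arrival = double(), departure = double(),
      first_idx = integer(), last_idx = integer(), n_fixes = integer()
    )
  }
  staypoints <- staypoints[order(staypoints$arrival), , drop = FALSE]
  staypoints$sp_id <- seq_len(nrow(staypoints))
  staypoints$duration_min <- (staypoints$departure - staypoints$arrival) / 60000
  trajectories <- dplyr::bind_rows(tr_rows)
  if (nrow(trajectories) == 0) {
    trajectories <- tibble::tibble(
      subject_id = character(), segment_id = integer(),
      start = double(), end = double(),
      first_idx = integer(), last_idx = integer(), n_fixes = integer()
    )
  }
  trajectories <- trajectories[order(trajectories$start,
                                     trajectories$first_idx), , drop = FALSE]
  trajectories$traj_id <- seq_len(nrow(trajectories))
  list(staypoints = staypoints, trajectories = trajectories)
}

# Core anchor sweep over one time-ordered segment.
# Returns a list of c(first, last) member index windows (1-based, local).
sweep_segment <- function(ts, lat, lon, theta_t_ms, theta_d_m) {
  n <- length(ts)
  out <- list()
  if (n < 2) return(out)
  i <- 1L
  while (i < n) {
    # scan forward in chunks for the first fix beyond theta_d of the anchor
    j <- n + 1L
    k <- i + 1L
    while (k <= n) {
      hi <- min(n, k + 255L)
      d <- haversine_m(lat[i], lon[i], lat[k:hi], lon[k:hi])
      exceed <- which(d > theta_d_m)
      if (length(exceed)) {
        j <- k + exceed[1] - 1L
        break
      }
      k <- hi + 1L
    }
    if (ts[j - 1L] - ts[i] >= theta_t_ms) {
      out[[length(out) + 1L]] <- c(i, j - 1L)
      i <- j
    } else {
      i <- i + 1L
    }
  }
  out
}

# maximal runs of consecutive integers -> list of c(first, last)
index_runs <- function(ix) {
  if (!length(ix)) return(list())
  brk <- c(0, which(diff(ix) > 1), length(ix))
  lapply(seq_len(length(brk) - 1), function(k) {
    c(ix[brk[k] + 1], ix[brk[k + 1]])
  })
}

#' Per-fix stationary / non-stationary labels
#'
#' Every fix receives exactly one label: `"stationary"` if it lies inside a
#' stay point's member range, `"non-stationary"` otherwise.
#'
#' @param trace The `geo_trace` the stay points were detected from.
#' @param staypoints The `staypoints` tibble from [detect_staypoints()].
#' @return A character vector, one label per fix of the trace.
#' @export
label_states <- function(trace, staypoints) {
  stopifnot(inherits(trace, "geo_trace"))
  n <- nrow(trace$points)
  if (nrow(staypoints) > 0 &&
      (max(staypoints$last_idx) > n || min(staypoints$first_idx) < 1)) {
    stop("stay points do not match this trace (member indices out of range)",
         call. = FALSE)
  }
  lab <- rep("non-stationary", n)
  for (k in seq_len(nrow(staypoints))) {
    lab[staypoints$first_idx[k]:staypoints$last_idx[k]] <- "stationary"
  }
  lab
}
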