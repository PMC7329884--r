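# Independent oracles and fixture builders used across the suite.
# Each oracle is a deliberately naive re-derivation of the quantity it
# checks, sharing no code with the package implementation.

# Build a geo_trace from vectors; timestamps in minutes for readability.
make_trace <- function(t_min, lat, lon, confidence_m = NA_real_,
                       subject_id = "T", timezone = "UTC",
                       origin_ms = 1709510400000) {  # 2024-03-04 00:00 UTC
  new_trace(
    tibble::tibble(timestamp = origin_ms + t_min * 60000,
                   lat = lat, lon = lon, confidence_m = confidence_m),
    subject_id = subject_id, timezone = timezone)
}

# degrees of latitude corresponding to a metric offset (on the package's
# reference sphere), for constructing fixtures at known distances
deg_lat <- function(m) m / (pi * 6371008.8 / 180)

# Brute-force greedy stay-point search: from the leftmost remaining fix,
# take the longest contiguous window whose fixes all lie within theta_d of
# the window's first fix; emit it when its span is >= theta_t, else advance
# one fix.  Returns a list of c(first, last) windows (local indices).
oracle_staypoints <- function(ts, lat, lon, theta_t_ms, theta_d_m) {
  hav <- function(i, j) {
    geosphere::distHaversine(c(lon[i], lat[i]), c(lon[j], lat[j]),
                             r = 6371008.8)
  }
  n <- length(ts)
  out <- list()
  i <- 1
  while (i < n) {
    j <- i
    while (j + 1 <= n && hav(i, j + 1) <= theta_d_m) j <- j + 1
    if (ts[j] - ts[i] >= theta_t_ms) {
      out[[length(out) + 1]] <- c(i, j)
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  out
}

# Exhaustive pair-counting ARI: iterate over all unordered item pairs.
oracle_ari <- function(a, b) {
  n <- length(a)
  n11 <- n00 <- n10 <- n01 <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      sa <- a[i] == a[j]
      sb <- b[i] == b[j]
      if (sa && sb) n11 <- n11 + 1
      else if (!sa && !sb) n00 <- n00 + 1
      else if (sa) n10 <- n10 + 1
      else n01 <- n01 + 1
    }
  }
  total <- n11 + n00 + n10 + n01
  expected <- (n11 + n10) * (n11 + n01) / total
  maxidx <- ((n11 + n10) + (n11 + n01)) / 2
  if (maxidx == expected) return(1)
  (n11 - expected) / (maxidx - expected)
}

# Transitive closure of the epsilon-neighborhood graph (DBSCAN with
# min_points = 1): repeated boolean matrix closure, labels canonicalized
# by first member.
oracle_components <- function(lat, lon, eps_m) {
  n <- length(lat)
  A <- outer(seq_len(n), seq_len(n), function(i, j) {
    geosphere::distHaversine(cbind(lon[i], lat[i]), cbind(lon[j], lat[j]),
                             r = 6371008.8) <= eps_m
  })
  repeat {
    A2 <- (A %*% A) > 0 | A
    if (identical(A2, A)) break
    A <- A2
  }
  labels <- integer(n)
  cl <- 0
  for (i in seq_len(n)) {
    if (labels[i] == 0) {
      cl <- cl + 1
      labels[A[i, ]] <- cl
    }
  }
  labels
}

# All set partitions of 1..n (restricted growth strings), for exhaustive
# ARI checks on small item sets.
all_partitions <- function(n) {
  grow <- function(prefix) {
    if (length(prefix) == n) return(list(prefix))
    k <- max(prefix)
    unlist(lapply(seq_len(k + 1), function(v) grow(c(prefix, v))),
           recursive = FALSE)
  }
  grow(1L)
}
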