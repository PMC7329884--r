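# Recurrent-place clustering: DBSCAN over stay-point centroids with a
# haversine metric.  With the default min_points = 1 every stay point is a
# core point, so clusters are exactly the connected components of the
# epsilon-neighborhood graph and no visit is discarded as noise; a place is
# then called recurrent when it has >= 2 visits.

#' Cluster stay points into recurrent places
#'
#' Density-based clustering (DBSCAN) of stay-point centroids with
#' neighborhood radius `epsilon_m` under the haversine distance.  Cluster
#' ids are assigned deterministically in order of each cluster's earliest
#' arrival, so outputs are reproducible across platforms and input
#' orderings.
#'
#' @param staypoints A stay-point tibble from [detect_staypoints()].
#' @param epsilon_m Neighborhood radius, meters. Default 150.
#' @param min_points Minimum neighborhood size (self included) for a core
#'   point. Default 1: singleton visits form their own place and no point
#'   is noise.
#'
#' @return A list with `staypoints` (the input plus a `cluster_id` column;
#'   0 marks noise, only possible when `min_points > 1`) and `clusters`
#'   (one row per cluster: `cluster_id`, `centroid_lat`/`centroid_lon`
#'   (mean of member centroids), `n_visits`, `total_dwell_min`,
#'   `first_arrival`, `is_recurrent`).
#' @export
cluster_staypoints <- function(staypoints, epsilon_m = 150, min_points = 1L) {
  stopifnot(epsilon_m > 0, min_points >= 1)
  if (nrow(staypoints) == 0) {
    staypoints$cluster_id <- integer(0)
    return(list(staypoints = staypoints,
                clusters = tibble::tibble(
                  cluster_id = integer(), centroid_lat = double(),
                  centroid_lon = double(), n_visits = integer(),
                  total_dwell_min = double(), first_arrival = double(),
                  is_recurrent = logical())))
  }
  ord <- order(staypoints$arrival, staypoints$sp_id)
  sp <- staypoints[ord, , drop = FALSE]
  ids <- dbscan_haversine(sp$centroid_lat, sp$centroid_lon,
                          eps_m = epsilon_m, min_pts = as.integer(min_points))
  sp$cluster_id <- ids
  clusters <- dplyr::summarise(
    dplyr::group_by(sp[sp$cluster_id != 0L, , drop = FALSE], .data$cluster_id),
    centroid_lat = mean(.data$centroid_lat),
    centroid_lon = mean(.data$centroid_lon),
    n_visits = dplyr::n(),
    total_dwell_min = sum(.data$duration_min),
    first_arrival = min(.data$arrival),
    .groups = "drop"
  )
  clusters <- clusters[order(clusters$cluster_id), , drop = FALSE]
  clusters$is_recurrent <- clusters$n_visits >= 2L
  sp <- sp[order(sp$sp_id), , drop = FALSE]
  list(staypoints = sp, clusters = clusters)
}

# Plain DBSCAN on a precomputed haversine distance matrix. n is the number
# of stay points of one subject, so quadratic memory is fine.  Seeds are
# expanded in index (arrival) order and clusters are renumbered by their
# earliest member, which makes labels independent of input permutations.
dbscan_haversine <- function(lat, lon, eps_m, min_pts) {
  n <- length(lat)
  if (n == 1L) return(if (min_pts <= 1L) 1L else 0L)
  p <- cbind(lon, lat)
  D <- geosphere::distm(p, p, fun = function(a, b) {
    geosphere::distHaversine(a, b, r = EARTH_RADIUS_M)
  })
  nbrs <- lapply(seq_len(n), function(i) which(D[i, ] <= eps_m))
  core <- vapply(nbrs, length, integer(1)) >= min_pts
  labels <- rep(0L, n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    cl <- cl + 1L
    labels[i] <- cl
    queue <- nbrs[[i]]
    while (length(queue)) {
      q <- queue[1]
      queue <- queue[-1]
      if (labels[q] == 0L) {
        labels[q] <- cl
        if (core[q]) queue <- c(queue, nbrs[[q]][labels[nbrs[[q]]] == 0L])
      }
    }
  }
  # canonical ids by earliest (first-arrival) member
  assigned <- labels != 0L
  if (any(assigned)) {
    firsts <- vapply(split(which(assigned), labels[assigned]), min, numeric(1))
    remap <- integer(max(labels))
    remap[as.integer(names(sort(firsts)))] <- seq_along(firsts)
    labels[assigned] <- remap[labels[assigned]]
  }
  labels
}

#' Tune the clustering radius against labelled stay points
#'
#' For each candidate epsilon, clusters every subject's stay points and
#' scores agreement with that subject's ground-truth place labels by the
#' Adjusted Rand Index; reports the across-subject mean and standard error
#' of the mean per epsilon, and the radius with the highest mean ARI.
#'
#' @param labelled A list with one element per subject: a tibble of stay
#'   points (as from [detect_staypoints()]) carrying an additional
#'   `true_place` column.
#' @param grid Numeric vector of epsilon values (meters) to evaluate.
#' @param min_points Passed to [cluster_staypoints()]. Default 1.
#'
#' @return A list: `curve`, a tibble with `epsilon_m`, `mean_ari`,
#'   `se_ari`, `n_subjects`; and `best_epsilon_m`, the grid value
#'   maximizing the mean ARI (ties resolved toward the smaller radius).
#' @export
tune_epsilon <- function(labelled, grid, min_points = 1L) {
  stopifnot(length(grid) >= 1, all(grid > 0))
  usable <- Filter(function(sp) nrow(sp) >= 2, labelled)
  if (length(usable) < length(labelled)) {
    warning(length(labelled) - length(usable),
            " subject(s) with < 2 stay points excluded from epsilon tuning")
  }
  if (length(usable) == 0) stop("no subject has >= 2 labelled stay points",
                                call. = FALSE)
  ari_mat <- vapply(sort(grid), function(eps) {
    vapply(usable, function(sp) {
      cl <- cluster_staypoints(sp, epsilon_m = eps, min_points = min_points)
      adjusted_rand_index(cl$staypoints$cluster_id,
                          cl$staypoints$true_place)
    }, numeric(1))
  }, numeric(length(usable)))
  ari_mat <- matrix(ari_mat, nrow = length(usable))
  mean_ari <- colMeans(ari_mat)
  se_ari <- apply(ari_mat, 2, stats::sd) / sqrt(length(usable))
  curve <- tibble::tibble(epsilon_m = sort(grid), mean_ari = mean_ari,
                          se_ari = se_ari, n_subjects = length(usable))
  list(curve = curve,
       best_epsilon_m = curve$epsilon_m[which.max(curve$mean_ari)])
}

#' Place-clustering accuracy against ground-truth labels
#'
#' Each cluster is mapped to its majority ground-truth place label (ties
#' broken toward the label visited earliest within the cluster); accuracy
#' is the percentage of stay points whose cluster's majority label equals
#' their own label.
#'
#' @param cluster_ids Integer cluster assignment per stay point.
#' @param true_labels Ground-truth place label per stay point.
#' @param arrival Arrival time per stay point (for the deterministic tie
#'   break); defaults to input order.
#' @return Accuracy as a percentage in \[0, 100\].
#' @export
clustering_accuracy <- function(cluster_ids, true_labels,
                                arrival = seq_along(cluster_ids)) {
  stopifnot(length(cluster_ids) == length(true_labels),
            length(arrival) == length(cluster_ids))
  if (length(cluster_ids) == 0) return(NA_real_)
  majority <- vapply(split(seq_along(cluster_ids), cluster_ids),
                     function(ix) {
    labs <- as.character(true_labels[ix])
    counts <- table(labs)
    top <- names(counts)[counts == max(counts)]
    if (length(top) == 1) return(top)
    # tie: earliest-visited label within the cluster wins
    firsts <- vapply(top, function(l) min(arrival[ix][labs == l]), numeric(1))
    top[which.min(firsts)]
  }, character(1))
  100 * mean(majority[as.character(cluster_ids)] ==
               as.character(true_labels))
}
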