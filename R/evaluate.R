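# Evaluation metrics against simulator ground truth, and the end-to-end
# pipeline / cohort evaluation drivers.

#' Episode-level stay-point detection accuracy
#'
#' A ground-truth dwell episode counts as detected when detected stay
#' points cover at least 50% of its duration; a travel episode is correctly
#' labelled when stay points cover less than 50% of it.  Accuracy is the
#' percentage of all episodes (dwell and travel) whose state is recovered.
#'
#' @param staypoints Detected stay points (tibble with `arrival`,
#'   `departure`).
#' @param truth_episodes Ground-truth episode table (from
#'   [simulate_subject()]): `type`, `start`, `end`.
#' @return Accuracy percentage in \[0, 100\].
#' @export
staypoint_accuracy <- function(staypoints, truth_episodes) {
  stopifnot(nrow(truth_episodes) >= 1)
  ov_frac <- episode_sp_overlap(truth_episodes, staypoints)
  correct <- ifelse(truth_episodes$type == "dwell",
                    ov_frac >= 0.5, ov_frac < 0.5)
  100 * mean(correct)
}

# fraction of each episode's duration covered by (time-disjoint) stay points
episode_sp_overlap <- function(episodes, staypoints) {
  vapply(seq_len(nrow(episodes)), function(i) {
    dur <- episodes$end[i] - episodes$start[i]
    if (dur <= 0) return(0)
    if (nrow(staypoints) == 0) return(0)
    ov <- pmax(0, pmin(episodes$end[i], staypoints$departure) -
                 pmax(episodes$start[i], staypoints$arrival))
    sum(ov) / dur
  }, numeric(1))
}

#' Map detected stay points to ground-truth places
#'
#' Each stay point is assigned the place of the ground-truth dwell episode
#' it overlaps most (by duration); stay points overlapping no dwell episode
#' get `NA`.
#'
#' @param staypoints Detected stay points.
#' @param truth_episodes Ground-truth episode table.
#' @return Integer vector of place ids, one per stay point.
#' @export
map_staypoints_to_places <- function(staypoints, truth_episodes) {
  dw <- truth_episodes[truth_episodes$type == "dwell", , drop = FALSE]
  vapply(seq_len(nrow(staypoints)), function(i) {
    ov <- pmax(0, pmin(staypoints$departure[i], dw$end) -
                 pmax(staypoints$arrival[i], dw$start))
    if (!length(ov) || max(ov) <= 0) return(NA_integer_)
    dw$place_id[which.max(ov)]
  }, integer(1))
}

#' Did home inference recover the ground-truth home?
#'
#' The inferred home cluster is mapped to a ground-truth place by majority
#' vote over its member stay points (via [map_staypoints_to_places()]) and
#' compared with the simulator's designated home.
#'
#' @param clustered The list returned by [cluster_staypoints()].
#' @param home The result of [infer_home()].
#' @param truth A `truth` object from [simulate_subject()].
#' @return `TRUE`/`FALSE`, or `NA` when home is undetermined.
#' @export
home_correct <- function(clustered, home, truth) {
  if (!home$determined) return(NA)
  sp <- clustered$staypoints
  members <- sp[sp$cluster_id == home$home_cluster_id, , drop = FALSE]
  place <- map_staypoints_to_places(members, truth$episodes)
  place <- place[!is.na(place)]
  if (!length(place)) return(FALSE)
  tab <- table(place)
  inferred_place <- as.integer(names(tab)[which.max(tab)])
  inferred_place == truth$home_place_id
}

#' Evaluate the pipeline on a labelled cohort
#'
#' Runs filter, segmentation, stay-point detection, place clustering and
#' home inference on every simulated subject and scores each stage against
#' the ground truth: episode-level stay-point accuracy, place-clustering
#' accuracy (majority-label mapping) and home recovery.
#'
#' @param cohort A list from [simulate_cohort()] (or a list of
#'   [simulate_subject()] results).
#' @param config A [geopheno_config()].
#' @return A list: `per_subject`, a tibble with one row per subject
#'   (`subject_id`, `archetype`, `staypoint_accuracy`,
#'   `clustering_accuracy`, `home_correct`, `n_staypoints`, `n_clusters`,
#'   `confidence_mean_m`) and `summary`, cohort means and SDs in the same
#'   units (percentages in \[0, 100\]).
#' @export
evaluate_cohort <- function(cohort, config = geopheno_config()) {
  rows <- lapply(cohort, function(subj) {
    ctx <- contextualize(subj$trace, config)
    sp_acc <- staypoint_accuracy(ctx$staypoints, subj$truth$episodes)
    true_place <- map_staypoints_to_places(ctx$staypoints,
                                           subj$truth$episodes)
    cl_acc <- if (nrow(ctx$staypoints) && !anyNA(true_place)) {
      clustering_accuracy(ctx$clustered$staypoints$cluster_id, true_place,
                          arrival = ctx$clustered$staypoints$arrival)
    } else NA_real_
    tibble::tibble(
      subject_id = subj$trace$subject_id,
      archetype = if (!is.null(subj$archetype)) subj$archetype else NA,
      staypoint_accuracy = sp_acc,
      clustering_accuracy = cl_acc,
      home_correct = home_correct(ctx$clustered, ctx$home, subj$truth),
      n_staypoints = nrow(ctx$staypoints),
      n_clusters = nrow(ctx$clustered$clusters),
      confidence_mean_m = subj$truth$confidence_mean_m
    )
  })
  per_subject <- dplyr::bind_rows(rows)
  summary <- tibble::tibble(
    n_subjects = nrow(per_subject),
    staypoint_accuracy_mean = mean(per_subject$staypoint_accuracy),
    staypoint_accuracy_sd = stats::sd(per_subject$staypoint_accuracy),
    clustering_accuracy_mean = mean(per_subject$clustering_accuracy,
                                    na.rm = TRUE),
    clustering_accuracy_sd = stats::sd(per_subject$clustering_accuracy,
                                       na.rm = TRUE),
    home_accuracy_pct = 100 * mean(per_subject$home_correct, na.rm = TRUE)
  )
  list(per_subject = per_subject, summary = summary)
}

# shared preprocessing: filter -> segment -> detect -> cluster -> home
contextualize <- function(trace, config) {
  filtered <- filter_by_confidence(trace, config$max_confidence_m,
                                   missing = config$missing_confidence)
  segmented <- segment_on_gaps(filtered, config$max_gap_min)
  det <- detect_staypoints(segmented, config$theta_t_min, config$theta_d_m)
  clustered <- cluster_staypoints(det$staypoints, config$epsilon_m,
                                  config$min_points)
  home <- infer_home(clustered, trace$timezone, config$night_window)
  list(trace = segmented, staypoints = det$staypoints,
       trajectories = det$trajectories, clustered = clustered, home = home)
}

#' Run the full pipeline over a set of traces
#'
#' Executes read, filter, segmentation, stay-point detection, place
#' clustering, home inference and phenotype derivation for every subject,
#' adjusts the window-total count phenotypes for observation length across
#' the cohort, and (optionally) writes all outputs plus a run manifest.
#'
#' @param traces A list of `geo_trace` objects, or a character vector of
#'   CSV paths readable by [read_trace()].
#' @param config A [geopheno_config()].
#' @param out_dir Optional output directory; when given, writes
#'   `staypoints.csv`, `clusters.csv`, `phenotypes_daily.csv`,
#'   `phenotypes_summary.csv` and `manifest.json`.
#'
#' @details Subjects whose processing fails are skipped with a warning; an
#'   error is raised only if every subject fails.  Outputs are
#'   deterministic given inputs and configuration.
#'
#' @return A list: `summary` (one adjusted row per subject), `per_day`,
#'   `staypoints`, `clusters` (all subjects stacked), `failures`
#'   (named list of error messages) and `manifest`.
#' @export
run_pipeline <- function(traces, config = geopheno_config(),
                         out_dir = NULL) {
  if (is.character(traces)) {
    paths <- traces
    traces <- lapply(paths, function(p) {
      read_trace(p, timezone = config$timezone)
    })
  } else {
    paths <- NULL
  }
  results <- list()
  failures <- list()
  for (trace in traces) {
    res <- tryCatch(derive_phenotypes(trace, config), error = function(e) e)
    if (inherits(res, "error")) {
      warning("subject '", trace$subject_id, "' failed: ",
              conditionMessage(res))
      failures[[trace$subject_id]] <- conditionMessage(res)
    } else {
      results[[trace$subject_id]] <- res
    }
  }
  if (!length(results)) stop("all subjects failed", call. = FALSE)
  summary <- dplyr::bind_rows(lapply(results, `[[`, "summary"))
  if (nrow(summary) >= 3 &&
      length(unique(summary$n_days_observed)) > 1) {
    summary <- adjust_counts_for_duration(summary)
  }
  add_sid <- function(field) {
    dplyr::bind_rows(lapply(names(results), function(sid) {
      x <- results[[sid]][[field]]
      if (nrow(x) && !"subject_id" %in% names(x)) {
        x <- tibble::add_column(x, subject_id = sid, .before = 1)
      }
      x
    }))
  }
  per_day <- add_sid("per_day")
  staypoints <- add_sid("staypoints")
  clusters <- add_sid("clusters")
  manifest <- list(
    package = "geopheno",
    version = as.character(utils::packageVersion("geopheno")),
    created = format(Sys.time(), tz = "UTC", usetz = TRUE),
    parameters = unclass(config),
    n_subjects = length(results),
    n_failed = length(failures),
    input_digests = if (!is.null(paths)) {
      as.list(tools::md5sum(paths))
    } else NULL
  )
  out <- list(summary = summary, per_day = per_day, staypoints = staypoints,
              clusters = clusters, failures = failures, manifest = manifest)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(staypoints, file.path(out_dir, "staypoints.csv"),
                     row.names = FALSE)
    utils::write.csv(clusters, file.path(out_dir, "clusters.csv"),
                     row.names = FALSE)
    utils::write.csv(per_day, file.path(out_dir, "phenotypes_daily.csv"),
                     row.names = FALSE)
    utils::write.csv(summary, file.path(out_dir, "phenotypes_summary.csv"),
                     row.names = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}

#' Label detected stay points with ground-truth places
#'
#' Convenience wrapper used for epsilon tuning: detects stay points for
#' each simulated subject and attaches the ground-truth place label of the
#' best-overlapping dwell episode as `true_place`.
#'
#' @param cohort A list from [simulate_cohort()].
#' @param config A [geopheno_config()].
#' @return A list of labelled stay-point tibbles, one per subject, suitable
#'   for [tune_epsilon()]; stay points matching no dwell episode are
#'   dropped.
#' @export
labelled_staypoints <- function(cohort, config = geopheno_config()) {
  lapply(cohort, function(subj) {
    ctx <- contextualize(subj$trace, config)
    sp <- ctx$staypoints
    sp$true_place <- map_staypoints_to_places(sp, subj$truth$episodes)
    sp[!is.na(sp$true_place), , drop = FALSE]
  })
}
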