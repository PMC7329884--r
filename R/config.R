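#' Pipeline configuration
#'
#' Builds the single configuration object that governs every stage of the
#' preprocessing pipeline.  Defaults follow the framework's published
#' operating point: a stay point is a group of fixes that remains within
#' `theta_d_m` = 350 m of its anchor for at least `theta_t_min` = 60 min,
#' and recurrent visits to the same place are merged with a density-based
#' clustering radius of `epsilon_m` = 150 m.
#'
#' @param max_confidence_m Accuracy filter: fixes whose 68%-containment
#'   confidence radius exceeds this many meters are dropped. Default 200 m.
#' @param missing_confidence Policy for fixes with no confidence value:
#'   `"keep"` (default) or `"drop"`.
#' @param max_gap_min Maximum tolerated gap between consecutive fixes within
#'   one segment, minutes. Default 60.
#' @param theta_t_min Stay-point duration threshold, minutes. Default 60.
#' @param theta_d_m Stay-point distance threshold, meters. Default 350.
#' @param epsilon_m Place-clustering neighborhood radius, meters. Default 150.
#' @param min_points Minimum neighborhood size for a core point in the
#'   density clustering. Default 1, so every stay point is assigned to a
#'   place and singleton visits count as places.
#' @param night_window Local clock interval used for home inference, hours
#'   `c(start, end)`. Default `c(0, 6)` (midnight to 06:00).
#' @param grid_interval_min Sampling grid for the diurnal-movement series,
#'   minutes. Default 10.
#' @param period_band_h Period band (hours) over which spectral energy is
#'   summed for the diurnal-movement phenotype. Default `c(23.5, 24.5)`.
#' @param homestay_denominator `"dwell"` (home dwell over total stay-point
#'   dwell, default) or `"elapsed"` (home dwell over the 24-h day).
#' @param timezone IANA timezone used for local-day and night-window logic.
#' @param seed Optional master seed recorded in run manifests.
#'
#' @return A named list of class `geopheno_config`.
#' @export
#' @examples
#' cfg <- geopheno_config(theta_d_m = 350, epsilon_m = 150)
#' cfg$theta_t_min
geopheno_config <- function(max_confidence_m = 200,
                            missing_confidence = c("keep", "drop"),
                            max_gap_min = 60,
                            theta_t_min = 60,
                            theta_d_m = 350,
                            epsilon_m = 150,
                            min_points = 1L,
                            night_window = c(0, 6),
                            grid_interval_min = 10,
                            period_band_h = c(23.5, 24.5),
                            homestay_denominator = c("dwell", "elapsed"),
                            timezone = "UTC",
                            seed = NULL) {
  missing_confidence <- match.arg(missing_confidence)
  homestay_denominator <- match.arg(homestay_denominator)
  cfg <- list(
    max_confidence_m = max_confidence_m,
    missing_confidence = missing_confidence,
    max_gap_min = max_gap_min,
    theta_t_min = theta_t_min,
    theta_d_m = theta_d_m,
    epsilon_m = epsilon_m,
    min_points = as.integer(min_points),
    night_window = night_window,
    grid_interval_min = grid_interval_min,
    period_band_h = period_band_h,
    homestay_denominator = homestay_denominator,
    timezone = timezone,
    seed = seed
  )
  class(cfg) <- "geopheno_config"
  validate_config(cfg)
}

validate_config <- function(cfg) {
  stopifnot(
    cfg$max_confidence_m > 0,
    cfg$max_gap_min > 0,
    cfg$theta_t_min > 0,
    cfg$theta_d_m > 0,
    cfg$epsilon_m > 0,
    cfg$min_points >= 1L,
    length(cfg$night_window) == 2,
    all(cfg$night_window >= 0 & cfg$night_window <= 24),
    cfg$grid_interval_min > 0,
    length(cfg$period_band_h) == 2,
    cfg$period_band_h[1] > 0,
    cfg$period_band_h[1] < cfg$period_band_h[2]
  )
  if (!is_valid_timezone(cfg$timezone)) {
    stop("invalid timezone: '", cfg$timezone, "'", call. = FALSE)
  }
  cfg
}

is_valid_timezone <- function(tz) {
  is.character(tz) && length(tz) == 1 && !is.na(tz) &&
    (tz %in% OlsonNames() || identical(tz, "UTC"))
}

#' Read a pipeline configuration from a YAML file
#'
#' Unknown keys are rejected so that typos in threshold names fail loudly
#' rather than silently falling back to defaults.
#'
#' @param path Path to a YAML file whose keys are a subset of the arguments
#'   of [geopheno_config()].
#' @return A validated `geopheno_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- names(formals(geopheno_config))
  bad <- setdiff(names(raw), known)
  if (length(bad)) {
    stop("unknown config key(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  do.call(geopheno_config, raw)
}

#' @export
print.geopheno_config <- function(x, ...) {
  cat("<geopheno_config>\n")
  for (k in setdiff(names(x), "seed")) {
    cat(sprintf("  %-22s %s\n", k, paste(format(x[[k]]), collapse = ", ")))
  }
  if (!is.null(x$seed)) cat(sprintf("  %-22s %s\n", "seed", x$seed))
  invisible(x)
}
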