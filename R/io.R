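#' Write a pressure series to the columnar CSV format
#'
#' UTF-8 CSV with header `time_s,S1,...,S8`, one row per frame, strictly
#' increasing times. An annotated series also gains a `posture` column
#' (ignored by readers unless requested).
#'
#' @param series a [pressure_series()].
#' @param path output file path.
#' @param annotation include the posture annotation column when present.
#' @return `path`, invisibly.
#' @export
write_pressure_series <- function(series, path, annotation = TRUE) {
  stopifnot(inherits(series, "pressure_series"))
  df <- as.data.frame(series)
  if (annotation && !is.null(series$annotation)) df$posture <- series$annotation
  data.table::fwrite(df, path)
  invisible(path)
}

#' Read a pressure series from the columnar CSV format
#'
#' Expects the dialect of [write_pressure_series()]: header
#' `time_s,S1,...,S8` (optionally `posture`), strictly increasing times at a
#' near-constant rate, non-negative finite values. Parse problems raise
#' typed errors naming the offending line.
#'
#' @param path input file path.
#' @param unit `"kPa"` (calibrated) or `"relcap"` (raw relative capacitance).
#' @return A [pressure_series()].
#' @export
read_pressure_series <- function(path, unit = c("kPa", "relcap")) {
  unit <- match.arg(unit)
  if (!file.exists(path)) stop("no such file: ", path)
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE)
  if (nrow(dt) == 0L) stop("empty series file: ", path)
  need <- c("time_s", paste0("S", 1:8))
  if (!all(need %in% names(dt)))
    stop("malformed header: expected columns ", paste(need, collapse = ","),
         " got ", paste(names(dt), collapse = ","))
  vals <- as.matrix(dt[, paste0("S", 1:8)])
  if (!is.numeric(vals) || anyNA(vals))
    stop("non-numeric or missing value near line ",
         which(rowSums(is.na(dt[, paste0("S", 1:8)])) > 0)[1] + 1L)
  neg <- which(rowSums(vals < 0) > 0)
  if (length(neg)) stop("negative pressure at line ", neg[1] + 1L)
  dt_t <- diff(dt$time_s)
  if (any(dt_t <= 0))
    stop("non-monotone timestamps at line ", which(dt_t <= 0)[1] + 2L)
  rate <- 1 / median(dt_t)
  ann <- if ("posture" %in% names(dt)) dt$posture else NULL
  pressure_series(vals, sample_rate = rate, annotation = ann, unit = unit)
}

#' Persist a window set as a matrix file plus manifest
#'
#' Writes `windows.csv` (one row per window, `8 * window` flattened values,
#' channel-major) and `manifest.csv` (sample id, label, origin start sample)
#' into `dir`.
#'
#' @param windows a `window_set` (see [segment_series()]).
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_windows <- function(windows, dir) {
  stopifnot(inherits(windows, "window_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nw <- dim(windows$x)[3]
  flat <- t(apply(windows$x, 3, as.vector))
  data.table::fwrite(data.table::as.data.table(flat),
                     file.path(dir, "windows.csv"), col.names = FALSE)
  manifest <- data.frame(
    sample_id = seq_len(nw),
    label = if (is.null(windows$labels)) NA_character_ else windows$labels,
    origin_start = windows$starts,
    window = windows$cfg$window, step = windows$cfg$step,
    sample_rate = windows$sample_rate)
  data.table::fwrite(manifest, file.path(dir, "manifest.csv"))
  invisible(dir)
}

#' Load a window set saved by [save_windows()]
#' @param dir directory containing `windows.csv` and `manifest.csv`.
#' @return A `window_set`.
#' @export
load_windows <- function(dir) {
  manifest <- data.table::fread(file.path(dir, "manifest.csv"), data.table = FALSE)
  flat <- as.matrix(data.table::fread(file.path(dir, "windows.csv"),
                                      header = FALSE, data.table = FALSE))
  w <- manifest$window[1]
  x <- array(t(flat), dim = c(8L, w, nrow(manifest)))
  labels <- if (all(is.na(manifest$label))) NULL else as.character(manifest$label)
  structure(list(x = x, labels = labels, starts = manifest$origin_start,
                 cfg = segmentation_config(window = w, step = manifest$step[1]),
                 sample_rate = manifest$sample_rate[1]),
            class = "window_set")
}

#' Default toolkit configuration
#'
#' One nested list holding every tunable: sampling rate, calibration
#' constants, sensor layout, pressure zones, peak-detection and pronation
#' parameters, CNN hyperparameters, alert thresholds and the default seed.
#'
#' @return A nested configuration list.
#' @export
default_config <- function() {
  layout <- default_sensor_layout()
  list(
    sample_rate = 200,
    seed = 2023,
    calibration = list(sensitivity_low = 0.0126, sensitivity_high = 0.0038,
                       breakpoint = 200, detection_limit = 0.4,
                       max_pressure = 500, baseline_capacitance = 1),
    layout = lapply(seq_len(nrow(layout)), function(i) as.list(layout[i, ])),
    zones = list(boundaries = c(50, 200, 400),
                 names = c("LOW", "MEDIUM", "HIGH", "VERY_HIGH")),
    pronation = list(threshold = 0.15, side_convention = "left_over"),
    steps = list(min_height = 100, refractory_s = 0.3),
    segmentation = list(window = 120, step = 30, majority_fraction = 0.5,
                        circular_pad = TRUE),
    cnn = list(filters = c(128, 128, 256, 256), kernel = 7, pool_stride = 2,
               epochs = 200, n_classes = 6, batch_size = 48,
               learning_rate = 1e-3),
    alerts = list(spike_threshold = 500, sustained_threshold = 200,
                  sustained_duration = 30, asymmetry_fraction = 0.45,
                  asymmetry_min_duration = 1, overuse_duration = 1800,
                  fatigue_consecutive = 3)
  )
}

#' Read a YAML configuration file over the defaults
#'
#' @param path YAML file; missing keys fall back to [default_config()].
#'   `NULL` returns the defaults.
#' @return A configuration list.
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  modifyList(cfg, user)
}

#' Write a configuration list as YAML
#' @param config configuration list.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

config_layout <- function(config) {
  validate_sensor_layout(do.call(rbind, lapply(config$layout, as.data.frame)))
}

config_curve <- function(config) {
  do.call(calibration_curve, config$calibration)
}

#' Serialize a report object to JSON
#'
#' @param x an `activity_report`, `zone_stats`, `eval_report` or
#'   `alert_events` object (or any list of numerics).
#' @param path output path; `NULL` returns the JSON string.
#' @return The path (invisibly) or the JSON string.
#' @export
write_report_json <- function(x, path = NULL) {
  payload <- unclass(x)
  if (inherits(x, "eval_report")) payload$confusion <- as.matrix(x$confusion)
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(path)
}
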