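#' User profile
#'
#' @param body_mass body mass in kg.
#' @param stride_length stride length in m.
#' @param foot_length foot length in m.
#' @return An object of class `user_profile`.
#' @export
user_profile <- function(body_mass = 70, stride_length = 0.7, foot_length = 0.26) {
  if (any(c(body_mass, stride_length, foot_length) <= 0))
    stop("user profile values must be strictly positive")
  structure(list(body_mass = body_mass, stride_length = stride_length,
                 foot_length = foot_length), class = "user_profile")
}

# MET multipliers for energy expenditure by activity
met_table <- function() c(WALK = 3.5, RUN = 8, JUMP = 10, STAND = 1.3)

#' Detect foot-strike peaks on the heel channel
#'
#' A foot strike is a local maximum of `max(S7, S8)` above `min_height` with
#' at least `refractory_s` between consecutive strikes.
#'
#' @param series a [pressure_series()] in kPa.
#' @param min_height peak height floor, kPa.
#' @param refractory_s minimum spacing between peaks, seconds.
#' @return Integer vector of peak sample indices, in time order.
#' @export
detect_foot_strikes <- function(series, min_height = 100, refractory_s = 0.3) {
  stopifnot(inherits(series, "pressure_series"))
  heel <- pmax(series$values[, "S7"], series$values[, "S8"])
  pk <- pracma::findpeaks(heel, minpeakheight = min_height,
                          minpeakdistance = max(1L, round(refractory_s * series$sample_rate)))
  if (is.null(pk)) return(integer(0))
  sort(as.integer(pk[, 2]))
}

# expand per-window posture labels to per-sample labels: each sample takes
# the label of the last window that starts at or before it
windows_to_sample_labels <- function(window_labels, n_samples, window = 120L,
                                     step = 30L) {
  starts <- seq(1L, by = step, length.out = length(window_labels))
  idx <- findInterval(seq_len(n_samples), starts)
  idx[idx < 1L] <- 1L
  as.character(window_labels)[idx]
}

#' Daily activity report
#'
#' Counts steps, running steps and jumps from heel-strike peaks attributed to
#' the posture active at each peak; accumulates distance as `(steps +
#' run_steps) * stride_length` and energy with a MET model
#' (`sum(MET(posture) * body_mass * hours) * 1.05`, MET: walk 3.5, run 8,
#' jump 10, stand 1.3). Calories are an estimate, not a measurement.
#'
#' @param series a [pressure_series()] in kPa.
#' @param profile a [user_profile()].
#' @param sample_labels per-sample posture labels (character); defaults to
#'   the series annotation. Use [windows_to_sample_labels()] to expand
#'   classifier output.
#' @param min_height,refractory_s peak detection parameters, see
#'   [detect_foot_strikes()].
#' @return List of class `activity_report`: `steps`, `run_steps`, `jumps`,
#'   `distance_m`, `calories_kcal`, `posture_time_s`.
#' @export
activity_report <- function(series, profile, sample_labels = series$annotation,
                            min_height = 100, refractory_s = 0.3) {
  stopifnot(inherits(series, "pressure_series"))
  if (!inherits(profile, "user_profile")) stop("profile must be a user_profile")
  if (is.null(sample_labels))
    stop("per-sample posture labels are required (annotate or classify first)")
  sample_labels <- as.character(sample_labels)
  if (length(sample_labels) != n_samples(series))
    stop("sample_labels length must equal the number of samples")

  pc <- posture_classes()
  activity <- setNames(pc$activity, pc$name)[sample_labels]
  peaks <- detect_foot_strikes(series, min_height, refractory_s)
  peak_act <- activity[peaks]
  steps <- sum(peak_act == "WALK")
  run_steps <- sum(peak_act == "RUN")
  jumps <- sum(peak_act == "JUMP")

  secs <- table(activity) / series$sample_rate
  met <- met_table()
  kcal <- 1.05 * profile$body_mass *
    sum(met[names(secs)] * as.numeric(secs) / 3600)
  pt <- setNames(as.numeric(table(sample_labels)) / series$sample_rate,
                 names(table(sample_labels)))
  structure(
    list(steps = steps, run_steps = run_steps, jumps = jumps,
         distance_m = (steps + run_steps) * profile$stride_length,
         calories_kcal = kcal, posture_time_s = pt),
    class = "activity_report"
  )
}

#' @export
print.activity_report <- function(x, ...) {
  cat(sprintf("<activity_report> %d steps, %d run steps, %d jumps, %.0f m, %.1f kcal\n",
              x$steps, x$run_steps, x$jumps, x$distance_m, x$calories_kcal))
  invisible(x)
}
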