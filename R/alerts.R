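#' Foot-health alert rules
#'
#' Thresholds for the rule-based warnings: an instantaneous spike above
#' 500 kPa, pressure held above 200 kPa for more than 30 s, a left/right
#' loading difference above 45 % (of the more loaded side) persisting at
#' least 1 s, continuous foot load for more than 30 min, and a fatigued
#' classification persisting for at least 3 consecutive windows.
#'
#' @param spike_threshold instantaneous spike threshold, kPa.
#' @param sustained_threshold sustained-pressure threshold, kPa.
#' @param sustained_duration minimum (strict) duration above the sustained
#'   threshold, seconds.
#' @param asymmetry_fraction left/right difference fraction, of the more
#'   loaded side.
#' @param asymmetry_min_duration persistence required for an asymmetry
#'   event, seconds.
#' @param overuse_duration continuous-use limit, seconds (30 min).
#' @param detection_limit load floor defining "foot in use", kPa.
#' @param fatigue_classes posture classes counted as fatigued.
#' @param fatigue_consecutive consecutive fatigued windows required.
#' @return An object of class `alert_rules`.
#' @export
alert_rules <- function(spike_threshold = 500, sustained_threshold = 200,
                        sustained_duration = 30, asymmetry_fraction = 0.45,
                        asymmetry_min_duration = 1, overuse_duration = 1800,
                        detection_limit = 0.4,
                        fatigue_classes = plantarpress::fatigue_classes(),
                        fatigue_consecutive = 3L) {
  if (sustained_threshold >= spike_threshold)
    stop("sustained_threshold must be below spike_threshold")
  if (asymmetry_fraction <= 0 || asymmetry_fraction >= 1)
    stop("asymmetry_fraction must lie in (0, 1)")
  if (any(c(spike_threshold, sustained_duration, overuse_duration,
            detection_limit, asymmetry_min_duration) <= 0))
    stop("alert thresholds must be positive")
  structure(list(spike_threshold = spike_threshold,
                 sustained_threshold = sustained_threshold,
                 sustained_duration = sustained_duration,
                 asymmetry_fraction = asymmetry_fraction,
                 asymmetry_min_duration = asymmetry_min_duration,
                 overuse_duration = overuse_duration,
                 detection_limit = detection_limit,
                 fatigue_classes = fatigue_classes,
                 fatigue_consecutive = as.integer(fatigue_consecutive)),
            class = "alert_rules")
}

empty_events <- function() {
  data.frame(kind = character(0), onset_s = numeric(0), duration_s = numeric(0),
             channels = character(0), peak_value = numeric(0),
             stringsAsFactors = FALSE)
}

# maximal TRUE runs of a logical vector -> data.frame(start, length)
true_runs <- function(cond) {
  r <- rle(cond)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start = starts[r$values], length = r$lengths[r$values])
}

asymmetry_signal <- function(values, layout) {
  sets <- axis_sensor_sets(layout)
  p_left <- rowMeans(values[, sets$left, drop = FALSE])
  p_right <- rowMeans(values[, sets$right, drop = FALSE])
  m <- pmax(p_left, p_right)
  ifelse(m > 0, abs(p_left - p_right) / m, 0)
}

#' Scan a calibrated series for foot-health alerts
#'
#' Applies every rule of [alert_rules()] offline. One event is emitted per
#' maximal excursion: a spike event per run of frames with any channel above
#' the spike threshold; a sustained event per channel run strictly longer
#' than `sustained_duration` above the sustained threshold (an excursion of
#' exactly 30 s raises nothing); an uneven-pressure event per run of
#' left/right asymmetry above `asymmetry_fraction` lasting at least
#' `asymmetry_min_duration`; an overuse event per run of continuous load
#' longer than `overuse_duration`; and a fatigue event per run of at least
#' `fatigue_consecutive` consecutive fatigued window labels.
#'
#' @param series a calibrated [pressure_series()] (kPa).
#' @param rules an [alert_rules()] set.
#' @param layout sensor layout (left/right sensor sets for asymmetry).
#' @param window_labels optional per-window classifier labels for the
#'   fatigue rule.
#' @param window_step,window_size segmentation geometry of `window_labels`,
#'   samples.
#' @return A data.frame of class `alert_events` with columns `kind`,
#'   `onset_s`, `duration_s`, `channels`, `peak_value`, ordered by onset.
#' @export
scan_alerts <- function(series, rules = alert_rules(),
                        layout = default_sensor_layout(),
                        window_labels = NULL, window_step = 30L,
                        window_size = 120L) {
  stopifnot(inherits(series, "pressure_series"))
  if (series$unit != "kPa")
    stop("alerts require a calibrated series in kPa; run calibrate_series() first")
  v <- series$values
  rate <- series$sample_rate
  ev <- list()

  add <- function(kind, start, len, channels, peak) {
    ev[[length(ev) + 1L]] <<- data.frame(
      kind = kind, onset_s = (start - 1L) / rate, duration_s = len / rate,
      channels = channels, peak_value = peak, stringsAsFactors = FALSE)
  }

  spike_any <- rowSums(v > rules$spike_threshold) > 0
  runs <- true_runs(spike_any)
  for (i in seq_len(nrow(runs))) {
    idx <- runs$start[i] + seq_len(runs$length[i]) - 1L
    block <- v[idx, , drop = FALSE]
    chs <- paste0("S", which(apply(block > rules$spike_threshold, 2, any)))
    add("HIGH_PRESSURE_SPIKE", runs$start[i], runs$length[i],
        paste(chs, collapse = ","), max(block))
  }

  for (ch in seq_len(8L)) {
    runs <- true_runs(v[, ch] > rules$sustained_threshold)
    runs <- runs[runs$length / rate > rules$sustained_duration, , drop = FALSE]
    for (i in seq_len(nrow(runs))) {
      idx <- runs$start[i] + seq_len(runs$length[i]) - 1L
      add("HIGH_PRESSURE_SUSTAINED", runs$start[i], runs$length[i],
          paste0("S", ch), max(v[idx, ch]))
    }
  }

  asym <- asymmetry_signal(v, layout)
  runs <- true_runs(asym > rules$asymmetry_fraction)
  runs <- runs[runs$length / rate >= rules$asymmetry_min_duration, , drop = FALSE]
  for (i in seq_len(nrow(runs))) {
    idx <- runs$start[i] + seq_len(runs$length[i]) - 1L
    add("UNEVEN_PRESSURE", runs$start[i], runs$length[i],
        "S6,S7|S1,S8", max(asym[idx]))
  }

  loaded <- rowSums(v >= rules$detection_limit) > 0
  runs <- true_runs(loaded)
  runs <- runs[runs$length / rate > rules$overuse_duration, , drop = FALSE]
  for (i in seq_len(nrow(runs)))
    add("OVERUSE", runs$start[i], runs$length[i], "all",
        runs$length[i] / rate)

  if (!is.null(window_labels)) {
    fat <- as.character(window_labels) %in% rules$fatigue_classes
    runs <- true_runs(fat)
    runs <- runs[runs$length >= rules$fatigue_consecutive, , drop = FALSE]
    for (i in seq_len(nrow(runs))) {
      start_sample <- (runs$start[i] - 1L) * window_step + 1L
      len_samples <- (runs$length[i] - 1L) * window_step + window_size
      add("FATIGUE", start_sample, len_samples, "all", runs$length[i])
    }
  }

  out <- if (length(ev)) do.call(rbind, ev) else empty_events()
  out <- out[order(out$onset_s, out$kind), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("alert_events", "data.frame")
  out
}

#' Streaming alert monitor
#'
#' Online equivalent of [scan_alerts()] for the four pressure-based rules
#' (spike, sustained, uneven, overuse), with bounded per-frame state: feed
#' frames in chunks of any size and receive events as the excursions that
#' triggered them end. `finalize()` flushes excursions still open at the end
#' of the stream. The event set over a whole series equals
#' [scan_alerts()]'s regardless of chunking.
#'
#' @param rules an [alert_rules()] set.
#' @param sample_rate stream sampling rate, Hz.
#' @param layout sensor layout.
#' @return An object of class `alert_monitor`: environment with functions
#'   `feed(values, times = NULL)` (matrix of frames, optional strictly
#'   increasing timestamps; returns newly completed events) and `finalize()`
#'   (returns remaining events).
#' @examples
#' mon <- alert_monitor(sample_rate = 200)
#' ev1 <- mon$feed(matrix(600, 1, 8))   # spike opens
#' ev2 <- mon$feed(matrix(0, 5, 8))     # spike closes -> event emitted
#' @export
alert_monitor <- function(rules = alert_rules(), sample_rate = 200,
                          layout = default_sensor_layout()) {
  rate <- sample_rate
  n_seen <- 0L
  last_time <- -Inf
  # per-tracker state: active flag, start frame, peak, channel hit set
  trackers <- list(
    spike = list(active = FALSE, start = NA_integer_, peak = -Inf,
                 chs = logical(8)),
    uneven = list(active = FALSE, start = NA_integer_, peak = -Inf),
    overuse = list(active = FALSE, start = NA_integer_),
    sustained = lapply(1:8, function(i)
      list(active = FALSE, start = NA_integer_, peak = -Inf))
  )
  events <- list()

  emit <- function(kind, start, len, channels, peak) {
    events[[length(events) + 1L]] <<- data.frame(
      kind = kind, onset_s = (start - 1L) / rate, duration_s = len / rate,
      channels = channels, peak_value = peak, stringsAsFactors = FALSE)
  }

  close_spike <- function(end_frame) {
    st <- trackers$spike
    emit("HIGH_PRESSURE_SPIKE", st$start, end_frame - st$start + 1L,
         paste(paste0("S", which(st$chs)), collapse = ","), st$peak)
    trackers$spike <<- list(active = FALSE, start = NA_integer_, peak = -Inf,
                            chs = logical(8))
  }
  close_sustained <- function(ch, end_frame) {
    st <- trackers$sustained[[ch]]
    len <- end_frame - st$start + 1L
    if (len / rate > rules$sustained_duration)
      emit("HIGH_PRESSURE_SUSTAINED", st$start, len, paste0("S", ch), st$peak)
    trackers$sustained[[ch]] <<- list(active = FALSE, start = NA_integer_,
                                      peak = -Inf)
  }
  close_uneven <- function(end_frame) {
    st <- trackers$uneven
    len <- end_frame - st$start + 1L
    if (len / rate >= rules$asymmetry_min_duration)
      emit("UNEVEN_PRESSURE", st$start, len, "S6,S7|S1,S8", st$peak)
    trackers$uneven <<- list(active = FALSE, start = NA_integer_, peak = -Inf)
  }
  close_overuse <- function(end_frame) {
    st <- trackers$overuse
    len <- end_frame - st$start + 1L
    if (len / rate > rules$overuse_duration)
      emit("OVERUSE", st$start, len, "all", len / rate)
    trackers$overuse <<- list(active = FALSE, start = NA_integer_)
  }

  feed <- function(values, times = NULL) {
    values <- matrix(values, ncol = 8L,
                     dimnames = list(NULL, paste0("S", 1:8)))
    if (!is.null(times)) {
      if (length(times) != nrow(values)) stop("times must match the frames")
      if (any(diff(c(last_time, times)) <= 0))
        stop("out-of-order timestamp in stream")
      last_time <<- times[length(times)]
    }
    events <<- list()
    asym <- asymmetry_signal(values, layout)
    spike_any <- rowSums(values > rules$spike_threshold) > 0
    loaded <- rowSums(values >= rules$detection_limit) > 0
    for (i in seq_len(nrow(values))) {
      frame_no <- n_seen + i
      if (spike_any[i]) {
        if (!trackers$spike$active)
          trackers$spike <<- modifyList(trackers$spike,
                                        list(active = TRUE, start = frame_no))
        trackers$spike$peak <<- max(trackers$spike$peak, max(values[i, ]))
        trackers$spike$chs <<- trackers$spike$chs |
          (values[i, ] > rules$spike_threshold)
      } else if (trackers$spike$active) close_spike(frame_no - 1L)

      for (ch in seq_len(8L)) {
        if (values[i, ch] > rules$sustained_threshold) {
          if (!trackers$sustained[[ch]]$active)
            trackers$sustained[[ch]] <<- list(active = TRUE, start = frame_no,
                                              peak = -Inf)
          trackers$sustained[[ch]]$peak <<-
            max(trackers$sustained[[ch]]$peak, values[i, ch])
        } else if (trackers$sustained[[ch]]$active)
          close_sustained(ch, frame_no - 1L)
      }

      if (asym[i] > rules$asymmetry_fraction) {
        if (!trackers$uneven$active)
          trackers$uneven <<- list(active = TRUE, start = frame_no, peak = -Inf)
        trackers$uneven$peak <<- max(trackers$uneven$peak, asym[i])
      } else if (trackers$uneven$active) close_uneven(frame_no - 1L)

      if (loaded[i]) {
        if (!trackers$overuse$active)
          trackers$overuse <<- list(active = TRUE, start = frame_no)
      } else if (trackers$overuse$active) close_overuse(frame_no - 1L)
    }
    n_seen <<- n_seen + nrow(values)
    collect()
  }

  finalize <- function() {
    events <<- list()
    if (trackers$spike$active) close_spike(n_seen)
    for (ch in seq_len(8L))
      if (trackers$sustained[[ch]]$active) close_sustained(ch, n_seen)
    if (trackers$uneven$active) close_uneven(n_seen)
    if (trackers$overuse$active) close_overuse(n_seen)
    collect()
  }

  collect <- function() {
    out <- if (length(events)) do.call(rbind, events) else empty_events()
    out <- out[order(out$onset_s, out$kind), , drop = FALSE]
    rownames(out) <- NULL
    class(out) <- c("alert_events", "data.frame")
    out
  }

  structure(list(feed = feed, finalize = finalize), class = "alert_monitor")
}

#' Run a streaming monitor over a whole series in chunks
#'
#' Convenience wrapper used to check online/offline equivalence: feeds a
#' series chunk by chunk and returns all emitted events.
#'
#' @param series a calibrated [pressure_series()].
#' @param rules an [alert_rules()] set.
#' @param chunk chunk size in frames.
#' @param layout sensor layout.
#' @return An `alert_events` data.frame.
#' @export
monitor_series <- function(series, rules = alert_rules(), chunk = 100L,
                           layout = default_sensor_layout()) {
  stopifnot(inherits(series, "pressure_series"))
  if (series$unit != "kPa") stop("monitoring requires a calibrated series in kPa")
  mon <- alert_monitor(rules, series$sample_rate, layout)
  n <- n_samples(series)
  parts <- list()
  for (start in seq(1L, n, by = chunk)) {
    end <- min(start + chunk - 1L, n)
    parts[[length(parts) + 1L]] <-
      mon$feed(series$values[start:end, , drop = FALSE])
  }
  parts[[length(parts) + 1L]] <- mon$finalize()
  out <- do.call(rbind, parts)
  out <- out[order(out$onset_s, out$kind), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("alert_events", "data.frame")
  out
}
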