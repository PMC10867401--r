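#' Plantar pressure zone scheme
#'
#' Four pressure zones used for long-term load statistics: low (0-50 kPa),
#' medium (50-200 kPa), high (200-400 kPa) and very high (>400 kPa).
#' Intervals are half-open on the left boundary (a boundary value belongs to
#' the higher zone) so the zones partition `[0, Inf)` exactly.
#'
#' @param boundaries strictly increasing zone boundaries, kPa.
#' @param zone_names names of the `length(boundaries) + 1` zones.
#' @return An object of class `pressure_zone_scheme`.
#' @export
pressure_zones <- function(boundaries = c(50, 200, 400),
                           zone_names = c("LOW", "MEDIUM", "HIGH", "VERY_HIGH")) {
  if (is.unsorted(boundaries, strictly = TRUE)) stop("boundaries must be strictly increasing")
  if (length(zone_names) != length(boundaries) + 1L)
    stop("need one more zone name than boundaries")
  structure(list(boundaries = boundaries, zone_names = zone_names),
            class = "pressure_zone_scheme")
}

#' Assign pressures to zones
#'
#' @param p non-negative pressures, kPa.
#' @param scheme a [pressure_zones()] scheme.
#' @return Factor of zone names with levels in zone order. A boundary value
#'   falls in the higher zone (50 kPa is MEDIUM, 200 kPa is HIGH).
#' @examples
#' zone_assign(c(30, 200, 450), pressure_zones())
#' @export
zone_assign <- function(p, scheme = pressure_zones()) {
  if (any(p < 0)) stop("pressures must be non-negative")
  idx <- findInterval(p, scheme$boundaries) + 1L
  factor(scheme$zone_names[idx], levels = scheme$zone_names)
}

#' Per-channel time spent in each pressure zone
#'
#' @param series a [pressure_series()] in kPa.
#' @param scheme a [pressure_zones()] scheme.
#' @return Matrix of durations in seconds, 8 channels x zones; each row sums
#'   to the series duration exactly.
#' @export
zone_histogram <- function(series, scheme = pressure_zones()) {
  stopifnot(inherits(series, "pressure_series"))
  nz <- length(scheme$zone_names)
  counts <- vapply(seq_len(8L), function(ch) {
    tabulate(findInterval(series$values[, ch], scheme$boundaries) + 1L, nbins = nz)
  }, numeric(nz))
  t(counts) / series$sample_rate -> times
  dimnames(times) <- list(paste0("S", 1:8), scheme$zone_names)
  times
}

#' Per-channel time under high plantar pressure
#'
#' Total time each channel spends at or above `threshold`. At the default
#' 200 kPa this equals the HIGH + VERY_HIGH zone occupancy of
#' [zone_histogram()] exactly (the zone partition is left-closed, so a
#' reading of exactly 200 kPa counts as high pressure).
#'
#' @param series a [pressure_series()] in kPa.
#' @param threshold high-pressure threshold, kPa.
#' @return Named vector of 8 durations in seconds.
#' @export
high_pressure_time <- function(series, threshold = 200) {
  stopifnot(inherits(series, "pressure_series"))
  if (threshold <= 0) stop("threshold must be positive")
  setNames(colSums(series$values >= threshold) / series$sample_rate,
           paste0("S", 1:8))
}

#' Mean pressure per channel, excluding the low zone
#'
#' Arithmetic mean of each channel over the samples at or above `low_cut`
#' (default 50 kPa), so unloaded phases do not dilute the effective load. A
#' channel with no qualifying samples reports 0 and is flagged.
#'
#' @param series a [pressure_series()] in kPa.
#' @param low_cut exclusion threshold, kPa.
#' @return Named vector of 8 mean pressures (kPa) with attribute
#'   `all_low`: logical vector flagging channels that never reached
#'   `low_cut`.
#' @export
mean_pressure_excluding_low <- function(series, low_cut = 50) {
  stopifnot(inherits(series, "pressure_series"))
  means <- numeric(8L)
  flag <- logical(8L)
  for (ch in seq_len(8L)) {
    v <- series$values[, ch]
    v <- v[v >= low_cut]
    if (length(v) == 0L) flag[ch] <- TRUE else means[ch] <- mean(v)
  }
  names(means) <- paste0("S", 1:8)
  attr(means, "all_low") <- setNames(flag, paste0("S", 1:8))
  means
}

#' Time spent in each annotated posture
#'
#' @param series an annotated [pressure_series()].
#' @return Named vector of seconds per posture (annotated classes only);
#'   sums to the series duration.
#' @export
posture_time <- function(series) {
  stopifnot(inherits(series, "pressure_series"))
  if (is.null(series$annotation))
    stop("series has no posture annotation; classify or annotate it first")
  tab <- table(series$annotation)
  setNames(as.numeric(tab) / series$sample_rate, names(tab))
}

#' Aggregate zone statistics for a series
#'
#' Convenience bundle of [zone_histogram()], [high_pressure_time()] and
#' [mean_pressure_excluding_low()].
#'
#' @param series a [pressure_series()] in kPa.
#' @param scheme a [pressure_zones()] scheme.
#' @param high_threshold threshold for the high-pressure dwell time, kPa.
#' @return List of class `zone_stats` with `zone_time`, `high_pressure_time`,
#'   `mean_pressure_excl_low`.
#' @export
zone_stats <- function(series, scheme = pressure_zones(), high_threshold = 200) {
  structure(
    list(zone_time = zone_histogram(series, scheme),
         high_pressure_time = high_pressure_time(series, high_threshold),
         mean_pressure_excl_low = mean_pressure_excluding_low(
           series, scheme$boundaries[1])),
    class = "zone_stats"
  )
}
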