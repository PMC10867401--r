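#' Multichannel plantar pressure time series
#'
#' Container for a fixed-rate recording from the 8-sensor insole. Values are
#' pressures in kPa (or relative capacitance change when `unit = "relcap"`,
#' before calibration), one column per sensor S1..S8, one row per frame.
#'
#' @param values numeric matrix, `n_samples x 8`, non-negative and finite.
#' @param sample_rate sampling rate in Hz (default 200: the 0.6 s analysis
#'   window corresponds to 120 samples).
#' @param annotation optional per-sample posture annotation: character vector
#'   or factor of posture names (see [posture_classes()]).
#' @param unit `"kPa"` for calibrated pressure or `"relcap"` for raw relative
#'   capacitance change.
#' @return An object of class `pressure_series`.
#' @seealso [generate_posture_series()], [read_pressure_series()]
#' @export
pressure_series <- function(values, sample_rate = 200, annotation = NULL,
                            unit = c("kPa", "relcap")) {
  unit <- match.arg(unit)
  values <- as.matrix(values)
  if (ncol(values) != 8L)
    stop("pressure series must have exactly 8 channels, got ", ncol(values))
  if (nrow(values) < 1L) stop("pressure series must contain at least one sample")
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L || sample_rate <= 0)
    stop("sample_rate must be a single positive number")
  if (anyNA(values) || any(!is.finite(values)))
    stop("pressure values must be finite")
  if (any(values < 0)) stop("pressure values must be non-negative")
  colnames(values) <- paste0("S", 1:8)
  if (!is.null(annotation)) {
    annotation <- as.character(annotation)
    if (length(annotation) != nrow(values))
      stop("annotation length must equal the number of samples")
    bad <- setdiff(unique(annotation), posture_classes()$name)
    if (length(bad)) stop("unknown posture annotation: ", paste(bad, collapse = ", "))
  }
  structure(
    list(values = values, sample_rate = sample_rate, annotation = annotation,
         unit = unit),
    class = "pressure_series"
  )
}

#' @export
print.pressure_series <- function(x, ...) {
  cat(sprintf("<pressure_series> %d samples x 8 channels @ %g Hz (%.2f s), unit %s\n",
              n_samples(x), x$sample_rate, series_duration(x), x$unit))
  if (!is.null(x$annotation)) {
    tab <- table(x$annotation)
    cat("  annotation:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
  rng <- range(x$values)
  cat(sprintf("  value range: [%.2f, %.2f]\n", rng[1], rng[2]))
  invisible(x)
}

#' Number of samples in a pressure series
#' @param series a [pressure_series()].
#' @return Integer sample count.
#' @export
n_samples <- function(series) nrow(series$values)

#' Duration of a pressure series in seconds
#' @param series a [pressure_series()].
#' @return Duration in seconds.
#' @export
series_duration <- function(series) n_samples(series) / series$sample_rate

#' @export
as.data.frame.pressure_series <- function(x, ...) {
  out <- data.frame(time_s = (seq_len(n_samples(x)) - 1) / x$sample_rate, x$values)
  colnames(out) <- c("time_s", paste0("S", 1:8))
  out
}

#' Concatenate pressure series end to end
#' @param ... [pressure_series()] objects with identical sample rates and units.
#' @return A single [pressure_series()]; annotations are kept when every piece
#'   carries one.
#' @export
concat_series <- function(...) {
  pieces <- list(...)
  if (length(pieces) == 1L && is.list(pieces[[1]]) &&
      !inherits(pieces[[1]], "pressure_series")) pieces <- pieces[[1]]
  stopifnot(length(pieces) >= 1L)
  rate <- pieces[[1]]$sample_rate
  unit <- pieces[[1]]$unit
  for (p in pieces) {
    if (!inherits(p, "pressure_series")) stop("all pieces must be pressure_series")
    if (p$sample_rate != rate) stop("sample rates differ")
    if (p$unit != unit) stop("units differ")
  }
  ann <- lapply(pieces, `[[`, "annotation")
  keep_ann <- !any(vapply(ann, is.null, logical(1)))
  pressure_series(do.call(rbind, lapply(pieces, `[[`, "values")),
                  sample_rate = rate,
                  annotation = if (keep_ann) unlist(ann) else NULL,
                  unit = unit)
}
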