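#' Mean cycle waveform per class
#'
#' Averages the windows of each class into one `8 x L` waveform and flattens
#' it to a feature vector, for inter-class similarity analysis.
#'
#' @param windows a `window_set` (see [segment_series()]) or array `8 x L x n`.
#' @param labels per-window class labels.
#' @return Matrix with one row per class (sorted by name), `8 * L` columns.
#' @export
class_mean_waveforms <- function(windows, labels = NULL) {
  x <- if (inherits(windows, "window_set")) windows$x else windows
  if (is.null(labels) && inherits(windows, "window_set")) labels <- windows$labels
  labels <- as.character(labels)
  stopifnot(dim(x)[3] == length(labels))
  classes <- sort(unique(labels))
  out <- t(vapply(classes, function(cl) {
    as.vector(apply(x[, , labels == cl, drop = FALSE], c(1, 2), mean))
  }, numeric(dim(x)[1] * dim(x)[2])))
  rownames(out) <- classes
  out
}

#' Pairwise Pearson correlation between class waveforms
#'
#' Computes the class-by-class Pearson correlation matrix of mean cycle
#' waveforms and flags pairs exceeding the strong-correlation threshold
#' (r > 0.3), which quantifies how similar the raw posture signals are - the
#' motivation for learning features rather than hand-crafting them.
#'
#' @param waveforms matrix with one row per class (e.g. from
#'   [class_mean_waveforms()]).
#' @param strong_threshold correlation above which a pair is flagged.
#' @return An object of class `posture_correlation`: list with `matrix`
#'   (symmetric, unit diagonal) and `strong_pairs` (data.frame: class_a,
#'   class_b, r).
#' @export
posture_correlation <- function(waveforms, strong_threshold = 0.3) {
  if (is.null(dim(waveforms)) || nrow(waveforms) < 2L)
    stop("need at least two class waveforms")
  sds <- apply(waveforms, 1, sd)
  if (any(sds == 0))
    stop("zero-variance waveform for class ",
         paste(rownames(waveforms)[sds == 0], collapse = ", "))
  R <- cor(t(waveforms))
  pairs <- which(upper.tri(R) & R > strong_threshold, arr.ind = TRUE)
  strong <- data.frame(
    class_a = rownames(R)[pairs[, 1]],
    class_b = colnames(R)[pairs[, 2]],
    r = R[pairs],
    stringsAsFactors = FALSE
  )
  structure(list(matrix = R, strong_pairs = strong,
                 strong_threshold = strong_threshold),
            class = "posture_correlation")
}

#' @export
print.posture_correlation <- function(x, ...) {
  cat(sprintf("<posture_correlation> %d classes, %d strongly correlated pairs (r > %g)\n",
              nrow(x$matrix), nrow(x$strong_pairs), x$strong_threshold))
  print(round(x$matrix, 3))
  invisible(x)
}
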