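#' Sliding-window segmentation configuration
#'
#' Defaults follow the analysis pipeline: a 0.6 s window (120 samples at
#' 200 Hz) slid in 0.15 s steps (30 samples), majority labeling at 50 %, and
#' circular padding so that every step offset yields a window (an L-sample
#' series then produces exactly `L / step` windows when `step` divides `L`;
#' 18,000 samples become 600 windows).
#'
#' @param window window length in samples.
#' @param step step in samples, `0 < step <= window`.
#' @param majority_fraction fraction of the window a class must exceed to
#'   label a mixed window.
#' @param circular_pad complete end-of-series windows by wrapping to the
#'   start (`TRUE`, default) or drop them (`FALSE`).
#' @return An object of class `segmentation_config`.
#' @export
segmentation_config <- function(window = 120L, step = 30L,
                                majority_fraction = 0.5, circular_pad = TRUE) {
  window <- as.integer(window); step <- as.integer(step)
  if (step < 1L || step > window) stop("require 0 < step <= window")
  if (majority_fraction <= 0 || majority_fraction >= 1)
    stop("majority_fraction must lie in (0, 1)")
  structure(list(window = window, step = step,
                 majority_fraction = majority_fraction,
                 circular_pad = isTRUE(circular_pad)),
            class = "segmentation_config")
}

#' Majority label of one window
#'
#' A pure window takes its class. A mixed window takes the class occupying
#' more than `majority_fraction` of it. On an exact tie (or when no class
#' exceeds the majority fraction), the modal class occurring latest in the
#' window wins - the most recent evidence.
#'
#' @param annotations character vector of per-sample posture labels covering
#'   the window.
#' @param cfg a [segmentation_config()] (provides `majority_fraction`).
#' @return A single posture label.
#' @examples
#' label_window(c(rep("WALK", 90), rep("RUN", 30)))  # WALK
#' label_window(c(rep("STAND", 60), rep("WALK", 60)))  # WALK (tie-break)
#' @export
label_window <- function(annotations, cfg = segmentation_config()) {
  if (length(annotations) == 0L || anyNA(annotations))
    stop("window must be fully annotated")
  annotations <- as.character(annotations)
  counts <- table(annotations)
  if (length(counts) == 1L) return(names(counts))
  modal <- names(counts)[counts == max(counts)]
  if (length(modal) == 1L && counts[[modal]] > cfg$majority_fraction * length(annotations))
    return(modal)
  # tie or no absolute majority: latest-occurring modal class
  last_seen <- vapply(modal, function(cl) max(which(annotations == cl)), numeric(1))
  modal[which.max(last_seen)]
}

#' Segment a pressure series into fixed-length windows
#'
#' Windows start at every multiple of `step`; with circular padding, windows
#' overrunning the series end wrap around to the start, otherwise they are
#' dropped. Annotated series get per-window majority labels via
#' [label_window()].
#'
#' @param series a [pressure_series()] at least one window long.
#' @param cfg a [segmentation_config()].
#' @return An object of class `window_set`: list with `x` (array `8 x window
#'   x n_windows`), `labels` (character or `NULL`), `starts` (1-based start
#'   sample of each window), `cfg`, `sample_rate`.
#' @examples
#' s <- generate_posture_series("WALK", n_cycles = 5, seed = 1)
#' w <- segment_series(s)
#' dim(w$x)  # 8 120 20
#' @export
segment_series <- function(series, cfg = segmentation_config()) {
  stopifnot(inherits(series, "pressure_series"))
  n <- n_samples(series)
  if (n < cfg$window)
    stop("series (", n, " samples) shorter than one window (", cfg$window, ")")
  starts <- if (cfg$circular_pad) seq(1L, n, by = cfg$step)
            else seq(1L, n - cfg$window + 1L, by = cfg$step)
  nw <- length(starts)
  x <- array(NA_real_, dim = c(8L, cfg$window, nw))
  labels <- if (is.null(series$annotation)) NULL else character(nw)
  tv <- t(series$values)   # 8 x n
  for (w in seq_len(nw)) {
    idx <- ((starts[w] - 1L + 0:(cfg$window - 1L)) %% n) + 1L
    x[, , w] <- tv[, idx]
    if (!is.null(labels))
      labels[w] <- label_window(series$annotation[idx], cfg)
  }
  structure(list(x = x, labels = labels, starts = starts, cfg = cfg,
                 sample_rate = series$sample_rate),
            class = "window_set")
}

#' @export
print.window_set <- function(x, ...) {
  cat(sprintf("<window_set> %d windows of %d samples x 8 channels\n",
              dim(x$x)[3], dim(x$x)[2]))
  if (!is.null(x$labels)) {
    tab <- table(x$labels)
    cat("  labels:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Combine window sets
#' @param ... `window_set` objects with identical window geometry.
#' @return A single `window_set`.
#' @export
combine_windows <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && is.list(sets[[1]]) && !inherits(sets[[1]], "window_set"))
    sets <- sets[[1]]
  w <- sets[[1]]$cfg$window
  stopifnot(all(vapply(sets, function(s) s$cfg$window == w, logical(1))))
  x <- array(unlist(lapply(sets, `[[`, "x")), dim = c(8L, w,
             sum(vapply(sets, function(s) dim(s$x)[3], numeric(1)))))
  labels <- lapply(sets, `[[`, "labels")
  keep <- !any(vapply(labels, is.null, logical(1)))
  structure(list(x = x, labels = if (keep) unlist(labels) else NULL,
                 starts = unlist(lapply(sets, `[[`, "starts")),
                 cfg = sets[[1]]$cfg, sample_rate = sets[[1]]$sample_rate),
            class = "window_set")
}

#' Stratified train/test split with cross-validation folds
#'
#' Splits window indices 80/20 per class (deterministically for a given
#' seed) and partitions the training portion into `n_folds` stratified folds
#' of equal size (+-1) for cross-validation. With 600 windows per class the
#' default yields 480 training and 120 test windows per class and five folds
#' of 96 per class.
#'
#' @param labels per-window class labels (character or factor).
#' @param train_fraction training fraction (default 0.8).
#' @param n_folds number of cross-validation folds (default 5).
#' @param seed integer seed for the per-class permutations.
#' @return An object of class `dataset_split`: list with `train`, `test`
#'   (integer index vectors), `folds` (list of `n_folds` disjoint index
#'   vectors partitioning `train`), `seed`.
#' @export
make_split <- function(labels, train_fraction = 0.8, n_folds = 5L, seed = 2023L) {
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  train <- integer(0); test <- integer(0)
  folds <- vector("list", n_folds)
  for (f in seq_len(n_folds)) folds[[f]] <- integer(0)
  perm_all <- withr::with_seed(seed, {
    lapply(classes, function(cl) sample(which(labels == cl)))
  })
  for (ci in seq_along(classes)) {
    idx <- perm_all[[ci]]
    n_tr <- round(train_fraction * length(idx))
    if (n_tr < n_folds)
      stop("class ", classes[ci], " has fewer than ", n_folds, " training samples")
    tr <- idx[seq_len(n_tr)]
    te <- idx[-seq_len(n_tr)]
    train <- c(train, tr)
    test <- c(test, te)
    fold_of <- rep(seq_len(n_folds), length.out = n_tr)
    for (f in seq_len(n_folds)) folds[[f]] <- c(folds[[f]], tr[fold_of == f])
  }
  structure(list(train = sort(train), test = sort(test),
                 folds = lapply(folds, sort), seed = seed),
            class = "dataset_split")
}

#' @export
print.dataset_split <- function(x, ...) {
  cat(sprintf("<dataset_split> %d train / %d test, %d folds of %s (seed %d)\n",
              length(x$train), length(x$test), length(x$folds),
              paste(unique(lengths(x$folds)), collapse = "/"), x$seed))
  invisible(x)
}
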