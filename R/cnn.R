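#' 1D-CNN hyperparameter specification
#'
#' The optimized posture/fatigue network: four same-padding convolutional
#' layers (kernel 7; filter counts 128, 128, 256, 256) with ReLU
#' activations, a stride-2 max-pooling stage after each convolution pair, a
#' flattening layer and a softmax output over the six classes. Trained with
#' Adam under a cosine-decaying learning rate and categorical cross-entropy.
#'
#' @param filters filter counts of the four convolutional layers.
#' @param kernel odd convolution kernel size.
#' @param pool_stride pooling stride (2).
#' @param epochs training epochs (the reference schedule uses 200; 50 is
#'   plenty for the synthetic task).
#' @param n_classes number of output classes.
#' @param batch_size minibatch size.
#' @param learning_rate initial Adam learning rate (cosine-decayed to 0).
#' @param seed default seed for weight initialization and shuffling.
#' @return An object of class `cnn_spec`.
#' @export
cnn_spec <- function(filters = c(128L, 128L, 256L, 256L), kernel = 7L,
                     pool_stride = 2L, epochs = 200L, n_classes = 6L,
                     batch_size = 48L, learning_rate = 1e-3, seed = 2023L) {
  filters <- as.integer(filters)
  if (length(filters) != 4L || any(filters < 1L))
    stop("filters must give four positive layer widths")
  kernel <- as.integer(kernel)
  if (kernel %% 2L != 1L) stop("kernel size must be odd")
  if (pool_stride != 2L) stop("only pool_stride = 2 is supported")
  if (epochs < 1L) stop("epochs must be at least 1")
  structure(list(filters = filters, kernel = kernel, pool_stride = 2L,
                 epochs = as.integer(epochs), n_classes = as.integer(n_classes),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, seed = as.integer(seed)),
            class = "cnn_spec")
}

#' Describe the network a spec builds for a given input shape
#'
#' Lays out the layer sequence conv-conv-pool-conv-conv-pool-flatten-dense
#' for an `input_channels x input_length` window and reports per-layer output
#' shapes and trainable parameter counts.
#'
#' @param spec a [cnn_spec()].
#' @param input_channels input feature maps (8 sensors).
#' @param input_length window length in samples (must be divisible by 4 and
#'   at least the kernel size).
#' @return An object of class `cnn_model_description`: list with `layers`
#'   (data.frame: layer, output shape, parameters) and `n_parameters`.
#' @examples
#' build_model(cnn_spec())
#' @export
build_model <- function(spec = cnn_spec(), input_channels = 8L, input_length = 120L) {
  stopifnot(inherits(spec, "cnn_spec"))
  if (input_length < spec$kernel) stop("input length shorter than the kernel")
  if (input_length %% 4L != 0L)
    stop("input length must be divisible by 4 (two stride-2 pooling stages)")
  f <- spec$filters; k <- spec$kernel
  L <- input_length
  layers <- list()
  cin <- input_channels
  shape_after <- c(L, L, L / 2, L / 2, L / 2, L / 4)
  conv_pos <- c(1, 2, 4, 5)
  li <- 1
  for (stage in 1:6) {
    if (stage %in% conv_pos) {
      ci <- match(stage, conv_pos)
      params <- f[ci] * (cin * k) + f[ci]
      layers[[li]] <- data.frame(
        layer = sprintf("conv%d (k=%d, relu)", ci, k),
        output = sprintf("%d x %d", f[ci], shape_after[stage]),
        parameters = params)
      cin <- f[ci]
    } else {
      layers[[li]] <- data.frame(
        layer = sprintf("maxpool (stride %d)", spec$pool_stride),
        output = sprintf("%d x %d", cin, shape_after[stage]),
        parameters = 0)
    }
    li <- li + 1
  }
  flat <- f[4] * (L / 4)
  layers[[li]] <- data.frame(layer = "flatten", output = as.character(flat),
                             parameters = 0)
  layers[[li + 1]] <- data.frame(
    layer = sprintf("dense (softmax, %d classes)", spec$n_classes),
    output = as.character(spec$n_classes),
    parameters = spec$n_classes * flat + spec$n_classes)
  layers <- do.call(rbind, layers)
  structure(list(spec = spec, input_channels = input_channels,
                 input_length = input_length, layers = layers,
                 n_parameters = sum(layers$parameters)),
            class = "cnn_model_description")
}

#' @export
print.cnn_model_description <- function(x, ...) {
  cat(sprintf("<cnn_model_description> input %d x %d\n",
              x$input_channels, x$input_length))
  print(x$layers, row.names = FALSE)
  cat(sprintf("total trainable parameters: %d\n", x$n_parameters))
  invisible(x)
}

standardize_windows <- function(x, center, scale) {
  for (ch in seq_len(dim(x)[1]))
    x[ch, , ] <- (x[ch, , ] - center[ch]) / scale[ch]
  x
}

#' Train the posture/fatigue CNN
#'
#' Trains the [cnn_spec()] network on labelled windows. Channels are
#' standardized with per-channel mean and standard deviation computed from
#' the training windows only (the same statistics are stored in the model
#' and applied at prediction time). Training is deterministic for a fixed
#' seed on single-threaded BLAS.
#'
#' @param windows a `window_set` (see [segment_series()]) or an array
#'   `8 x L x n`.
#' @param labels per-window class labels; defaults to the window set's
#'   labels. Must be classifier classes (see [classifier_classes()]).
#' @param split optional [make_split()]; when given, only `split$train`
#'   windows are used for training (and for the standardization statistics).
#' @param spec a [cnn_spec()].
#' @param seed seed for initialization and shuffling; defaults to the spec's.
#' @param standardize apply per-channel z-scoring (default `TRUE`).
#' @return An object of class `posture_cnn`: list with `weights`, `history`
#'   (per-epoch data.frame: loss, accuracy, learning_rate), `spec`,
#'   `classes`, `center`, `scale`.
#' @export
train_posture_cnn <- function(windows, labels = NULL, split = NULL,
                              spec = cnn_spec(), seed = spec$seed,
                              standardize = TRUE) {
  x <- if (inherits(windows, "window_set")) windows$x else windows
  if (is.null(labels) && inherits(windows, "window_set")) labels <- windows$labels
  if (is.null(labels)) stop("labels are required")
  stopifnot(length(dim(x)) == 3L, dim(x)[3] == length(labels))
  classes <- classifier_classes()[seq_len(spec$n_classes)]
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), classes)
  if (length(bad)) stop("labels outside the class set: ", paste(bad, collapse = ", "))
  y <- match(labels, classes) - 1L

  tr <- if (is.null(split)) seq_len(dim(x)[3]) else split$train
  if (length(tr) == 0L) stop("training set is empty")
  xtr <- x[, , tr, drop = FALSE]
  if (standardize) {
    center <- apply(xtr, 1, mean)
    scale <- apply(xtr, 1, sd)
    scale[scale < 1e-8] <- 1
    xtr <- standardize_windows(xtr, center, scale)
  } else {
    center <- rep(0, dim(x)[1]); scale <- rep(1, dim(x)[1])
  }
  fit <- .cnn_train_cpp(xtr, y[tr], spec$filters, spec$kernel, spec$n_classes,
                        spec$epochs, spec$batch_size, spec$learning_rate,
                        as.integer(seed))
  structure(
    list(weights = fit$weights,
         history = data.frame(epoch = seq_len(spec$epochs), loss = fit$loss,
                              accuracy = fit$accuracy,
                              learning_rate = fit$learning_rate),
         spec = spec, classes = classes, center = center, scale = scale),
    class = "posture_cnn"
  )
}

#' @export
print.posture_cnn <- function(x, ...) {
  h <- tail(x$history, 1)
  cat(sprintf("<posture_cnn> %d classes, %d epochs trained, final loss %.4f, train accuracy %.3f\n",
              length(x$classes), nrow(x$history), h$loss, h$accuracy))
  invisible(x)
}

#' @param object a trained `posture_cnn`.
#' @param windows a `window_set` or array `8 x L x n`.
#' @param type `"class"` for labels, `"prob"` for the softmax matrix.
#' @param ... unused.
#' @rdname train_posture_cnn
#' @export
predict.posture_cnn <- function(object, windows, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  x <- if (inherits(windows, "window_set")) windows$x else windows
  x <- standardize_windows(x, object$center, object$scale)
  probs <- .cnn_predict_cpp(object$weights, x, object$spec$kernel,
                            object$spec$n_classes, 256L)
  rownames(probs) <- object$classes
  if (type == "prob") return(t(probs))
  object$classes[max.col(t(probs))]
}

#' Evaluate a trained classifier on labelled windows
#'
#' @param model a trained `posture_cnn`.
#' @param windows a `window_set` or array of evaluation windows.
#' @param labels true labels of the evaluation windows.
#' @return An object of class `eval_report`: `accuracy`,
#'   `per_class_accuracy`, `confusion` (true class in rows), `n`.
#' @export
evaluate_model <- function(model, windows, labels = NULL) {
  if (is.null(labels) && inherits(windows, "window_set")) labels <- windows$labels
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), model$classes)
  if (length(bad)) stop("labels outside the class set: ", paste(bad, collapse = ", "))
  pred <- predict(model, windows)
  confusion_report(pred, labels, model$classes)
}

confusion_report <- function(pred, truth, classes) {
  confusion <- table(factor(truth, levels = classes),
                     factor(pred, levels = classes))
  names(dimnames(confusion)) <- c("true", "predicted")
  acc <- sum(diag(confusion)) / sum(confusion)
  per_class <- diag(confusion) / pmax(rowSums(confusion), 1)
  structure(list(accuracy = acc, per_class_accuracy = per_class,
                 confusion = confusion, n = sum(confusion)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> accuracy %.3f on %d windows\n", x$accuracy, x$n))
  print(x$confusion)
  invisible(x)
}

#' k-fold cross-validation of the CNN
#'
#' Trains on all but one fold of the training portion of a [make_split()]
#' and evaluates on the held-out fold, once per fold.
#'
#' @param windows a `window_set` or array.
#' @param labels per-window labels.
#' @param split a [make_split()] with folds.
#' @param spec a [cnn_spec()].
#' @param seed base seed; fold `i` trains with `seed + i`.
#' @return List with `fold_accuracy` (numeric vector) and `mean_accuracy`.
#' @export
crossvalidate_cnn <- function(windows, labels = NULL, split, spec = cnn_spec(),
                              seed = spec$seed) {
  x <- if (inherits(windows, "window_set")) windows$x else windows
  if (is.null(labels) && inherits(windows, "window_set")) labels <- windows$labels
  labels <- as.character(labels)
  accs <- vapply(seq_along(split$folds), function(f) {
    hold <- split$folds[[f]]
    tr <- setdiff(split$train, hold)
    sub <- list(train = seq_along(tr))
    model <- train_posture_cnn(x[, , tr, drop = FALSE], labels[tr],
                               split = NULL, spec = spec, seed = seed + f)
    evaluate_model(model, x[, , hold, drop = FALSE], labels[hold])$accuracy
  }, numeric(1))
  list(fold_accuracy = accs, mean_accuracy = mean(accs))
}
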