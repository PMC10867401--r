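test_that("model description reproduces the layer arithmetic and parameter count", {
  desc <- build_model(cnn_spec())
  # independent layer-wise oracle: conv params = out * (in * k) + out
  k <- 7
  expected <- (128 * (8 * k) + 128) + (128 * (128 * k) + 128) +
    (256 * (128 * k) + 256) + (256 * (256 * k) + 256) +
    (6 * (256 * 30) + 6)
  expect_equal(desc$n_parameters, expected)
  # two stride-2 pooling stages on length 120 leave 30 positions
  expect_match(desc$layers$output[nrow(desc$layers) - 1], "^7680$")
  expect_match(desc$layers$output[nrow(desc$layers)], "^6$")
  expect_error(build_model(cnn_spec(), input_length = 4), "kernel|divisible")
  expect_error(cnn_spec(kernel = 6), "odd")
  expect_error(cnn_spec(filters = c(8, 8)), "four")
})

test_that("training is seeded-deterministic and records a full history", {
  w <- small_six_class_windows(cycles_per_class = 8, seed = 40)
  spec <- tiny_cnn_spec(epochs = 3)
  m1 <- train_posture_cnn(w, spec = spec, seed = 9)
  m2 <- train_posture_cnn(w, spec = spec, seed = 9)
  expect_equal(nrow(m1$history), 3)
  expect_identical(m1$history$loss, m2$history$loss)
  expect_identical(m1$weights$dense$W, m2$weights$dense$W)
  m3 <- train_posture_cnn(w, spec = spec, seed = 10)
  expect_false(identical(m1$history$loss, m3$history$loss))
  # learning rate follows a decaying schedule
  expect_true(all(diff(m1$history$learning_rate) < 0))
})

test_that("training loss decreases on a separable noise-free fixture", {
  sets <- lapply(c("WALK", "RUN", "JUMP"), function(p) {
    segment_series(clean_series(p, 10))
  })
  w <- combine_windows(sets)
  spec <- cnn_spec(filters = c(8L, 8L, 16L, 16L), epochs = 10, batch_size = 16L,
                   n_classes = 6L)
  m <- train_posture_cnn(w, spec = spec, seed = 1)
  expect_lt(mean(tail(m$history$loss, 3)), mean(head(m$history$loss, 3)))
  expect_gt(tail(m$history$accuracy, 1), 0.9)
})

test_that("one-epoch training completes with a single history row", {
  w <- small_six_class_windows(cycles_per_class = 5, seed = 60)
  m <- train_posture_cnn(w, spec = tiny_cnn_spec(epochs = 1), seed = 2)
  expect_equal(nrow(m$history), 1)
})

test_that("prediction and evaluation are consistent with the confusion matrix", {
  w <- small_six_class_windows(cycles_per_class = 12, seed = 70)
  split <- make_split(w$labels, seed = 3)
  m <- train_posture_cnn(w, split = split, spec = tiny_cnn_spec(epochs = 8))
  rep <- evaluate_model(m, w$x[, , split$test, drop = FALSE],
                        w$labels[split$test])
  expect_equal(sum(rep$confusion), length(split$test))
  expect_equal(rep$accuracy, sum(diag(rep$confusion)) / sum(rep$confusion))
  expect_equal(as.numeric(rowSums(rep$confusion)),
               as.numeric(table(factor(w$labels[split$test], levels = m$classes))))
  probs <- predict(m, w$x[, , split$test, drop = FALSE], type = "prob")
  expect_equal(unname(rowSums(probs)), rep(1, nrow(probs)), tolerance = 1e-5)
  expect_error(evaluate_model(m, w$x[, , 1:2], c("WALK", "SWIM")), "class set")
})

test_that("accuracy bookkeeping matches hand-built predictions", {
  # perfect and constant predictors on a synthetic label set
  classes <- classifier_classes()
  truth <- rep(classes, each = 10)
  perfect <- plantarpress:::confusion_report(truth, truth, classes)
  expect_equal(perfect$accuracy, 1)
  expect_true(all(diag(perfect$confusion) == 10))
  constant <- plantarpress:::confusion_report(rep(classes[1], 60), truth, classes)
  expect_equal(constant$accuracy, 1 / 6)
})

test_that("cross-validation trains one model per fold", {
  w <- small_six_class_windows(cycles_per_class = 10, seed = 80)
  split <- make_split(w$labels, n_folds = 3, seed = 5)
  cv <- crossvalidate_cnn(w, split = split, spec = tiny_cnn_spec(epochs = 5))
  expect_length(cv$fold_accuracy, 3)
  expect_true(all(cv$fold_accuracy >= 0 & cv$fold_accuracy <= 1))
  expect_equal(cv$mean_accuracy, mean(cv$fold_accuracy))
})

test_that("labels outside the classifier set are rejected", {
  w <- small_six_class_windows(cycles_per_class = 5, seed = 90)
  labs <- w$labels
  labs[1] <- "STAND"
  expect_error(train_posture_cnn(w$x, labs, spec = tiny_cnn_spec()), "class set")
})
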