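test_that("circular segmentation yields n/step windows, strict mode drops the tail", {
  s <- generate_posture_series("WALK", 150, seed = 7)   # 18000 samples
  w <- segment_series(s)
  expect_equal(dim(w$x), c(8, 120, 600))
  expect_true(all(w$labels == "WALK"))

  strict <- segment_series(s, segmentation_config(circular_pad = FALSE))
  expect_equal(dim(strict$x)[3], 597)

  one <- segment_series(pressure_series(matrix(10, 120, 8)),
                        segmentation_config(window = 120, step = 120))
  expect_equal(dim(one$x)[3], 1)

  expect_error(segment_series(pressure_series(matrix(10, 60, 8))), "shorter")
})

test_that("the circular window-count law holds across lengths and steps", {
  for (L in c(240, 360, 1200)) {
    for (st in c(10, 30, 60, 120)) {
      s <- pressure_series(matrix(runif(L * 8), L, 8))
      w <- segment_series(s, segmentation_config(window = 120, step = st))
      if (L %% st == 0) expect_equal(dim(w$x)[3], L / st)
      expect_equal(dim(w$x)[3], ceiling(L / st))
    }
  }
})

test_that("wrapped windows reuse the start of the series", {
  s <- pressure_series(matrix(seq_len(150 * 8), 150, 8))
  w <- segment_series(s, segmentation_config(window = 120, step = 100))
  expect_equal(dim(w$x)[3], 2)
  # second window starts at sample 101 and wraps to samples 1..70
  expect_equal(w$x[1, , 2], c(s$values[101:150, 1], s$values[1:70, 1]))
})

test_that("window labels follow the majority rule with the late tie-break", {
  expect_equal(label_window(c(rep("WALK", 90), rep("RUN", 30))), "WALK")
  expect_equal(label_window(rep("JUMP", 120)), "JUMP")
  expect_equal(label_window(c(rep("STAND", 60), rep("WALK", 60))), "WALK")
  expect_equal(label_window(c(rep("WALK", 60), rep("STAND", 60))), "STAND")
  # three-way with no absolute majority: latest modal class wins
  expect_equal(label_window(c(rep("WALK", 50), rep("RUN", 50), rep("STAND", 20))),
               "RUN")
  expect_error(label_window(character(0)), "annotated")
  # every emitted label existed in the window
  set.seed(3)
  for (i in 1:20) {
    ann <- sample(c("WALK", "RUN", "STAND"), 120, replace = TRUE)
    expect_true(label_window(ann) %in% ann)
  }
})

test_that("segment labels of a mixed session come from the majority rule", {
  sched <- data.frame(posture = c("STAND", "WALK"), duration_s = c(0.75, 0.75))
  s <- generate_mixed_session(sched, seed = 6)   # 300 samples
  w <- segment_series(s)    # starts 1, 31, ..., 291 (wrapping)
  expect_equal(dim(w$x)[3], 10)
  expect_true(all(w$labels %in% c("STAND", "WALK")))
  expect_equal(w$labels[1], "STAND")
  expect_equal(w$labels[4], "WALK")   # window 91..210: 60/60 tie -> later class
})

test_that("stratified splits preserve class ratios and fold sizes", {
  labels <- rep(classifier_classes(), each = 600)
  sp <- make_split(labels, seed = 2023)
  expect_length(sp$train, 2880)
  expect_length(sp$test, 720)
  for (cl in classifier_classes()) {
    expect_equal(sum(labels[sp$train] == cl), 480)
    expect_equal(sum(labels[sp$test] == cl), 120)
  }
  expect_equal(sort(unlist(sp$folds)), sp$train)
  for (f in sp$folds) {
    expect_length(f, 576)
    for (cl in classifier_classes()) expect_equal(sum(labels[f] == cl), 96)
  }
  expect_equal(length(intersect(sp$train, sp$test)), 0)

  sp2 <- make_split(labels, seed = 1)
  expect_false(identical(sp$test, sp2$test))
  expect_length(sp2$test, 720)

  expect_error(make_split(rep(c("WALK", "RUN"), c(100, 4))), "fewer than")
})
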