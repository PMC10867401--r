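test_that("posture series have the requested geometry and annotation", {
  s <- generate_posture_series("WALK", n_cycles = 150, seed = 7)
  expect_equal(n_samples(s), 18000)
  expect_equal(ncol(s$values), 8)
  expect_true(all(s$annotation == "WALK"))
  expect_equal(series_duration(s), 90)
})

test_that("generation is deterministic for a fixed seed", {
  a <- generate_posture_series("RUN", 3, seed = 1)
  b <- generate_posture_series("RUN", 3, seed = 1)
  expect_identical(a$values, b$values)
  c <- generate_posture_series("RUN", 3, seed = 2)
  expect_false(identical(a$values, c$values))
})

test_that("zero-noise standing yields identical frames equal to the template", {
  tpl <- gait_template("STAND", noise_sd = 0)
  s <- generate_posture_series("STAND", 1, template = tpl)
  expect_equal(n_samples(s), 120)
  expect_equal(unname(s$values), unname(tpl$waveform))
  expect_equal(nrow(unique(s$values)), 1)
})

test_that("generator rejects invalid inputs", {
  expect_error(generate_posture_series("SWIM", 10), "unknown posture")
  expect_error(generate_posture_series("WALK", 0), "positive")
  expect_error(generate_posture_series("WALK", 5, template = gait_template("RUN")),
               "does not match")
  expect_error(generate_mixed_session(data.frame()), "non-empty")
})

test_that("templates respect the regional loading pattern and pressure range", {
  for (p in posture_classes()$name) {
    tpl <- gait_template(p)
    peaks <- apply(tpl$waveform, 2, max)
    expect_true(all(tpl$waveform >= 0) && all(tpl$waveform <= 500))
    expect_true(min(peaks[c(1, 3, 6)]) > max(peaks[c(2, 4, 5)]),
                label = paste(p, "metatarsal > midfoot/toe"))
    expect_true(min(peaks[c(7, 8)]) > max(peaks[c(2, 4, 5)]),
                label = paste(p, "heel > midfoot/toe"))
  }
})

test_that("fatigued variants are weaker and more variable than rested ones", {
  for (act in c("WALK", "RUN", "JUMP")) {
    normal <- gait_template(act)
    fat <- gait_template(paste0(act, "_FATIGUED"))
    expect_lt(max(fat$waveform), max(normal$waveform))
    expect_gt(fat$phase_jitter, normal$phase_jitter)
  }
})

test_that("mixed sessions concatenate annotated segments of the scheduled size", {
  sched <- data.frame(posture = c("STAND", "WALK"), duration_s = c(1, 2))
  s <- generate_mixed_session(sched, seed = 1)
  expect_equal(n_samples(s), 600)
  expect_equal(s$annotation[1:200], rep("STAND", 200))
  expect_equal(s$annotation[201:600], rep("WALK", 400))

  # annotation conservation on a mixed schedule with fractional durations
  sched2 <- data.frame(posture = c("WALK", "RUN", "JUMP", "STAND"),
                       duration_s = c(1.51, 2.3, 0.72, 3.1))
  s2 <- generate_mixed_session(sched2, seed = 4)
  expect_equal(n_samples(s2), sum(round(sched2$duration_s * 200)))
  expect_equal(as.numeric(table(s2$annotation)[sched2$posture]),
               round(sched2$duration_s * 200))
})

test_that("a forty-minute four-posture session has the expected sample count", {
  sched <- data.frame(posture = c("STAND", "WALK", "RUN", "JUMP"),
                      duration_s = c(900, 900, 300, 300))
  expect_equal(sum(round(sched$duration_s * 200)), 480000)
  s <- generate_mixed_session(head(sched, 2), seed = 1,
                              templates = list(STAND = gait_template("STAND"),
                                               WALK = gait_template("WALK")))
  expect_equal(n_samples(s), 360000)
})

test_that("generated pressures are non-negative even with heavy noise", {
  s <- generate_posture_series("WALK", 20, seed = 3,
                               template = gait_template("WALK", noise_sd = 80))
  expect_true(all(s$values >= 0))
})

test_that("within-class cycle waveforms correlate more than between-class ones", {
  classes <- classifier_classes()
  cycles_per_class <- 5
  vecs <- list()
  labs <- character(0)
  for (i in seq_along(classes)) {
    s <- generate_posture_series(classes[i], cycles_per_class, seed = 50 + i)
    for (cyc in seq_len(cycles_per_class)) {
      rows <- ((cyc - 1) * 120 + 1):(cyc * 120)
      vecs[[length(vecs) + 1]] <- as.vector(s$values[rows, ])
      labs <- c(labs, classes[i])
    }
  }
  V <- do.call(cbind, vecs)
  R <- cor(V)
  same <- outer(labs, labs, "==") & upper.tri(R)
  diff <- outer(labs, labs, "!=") & upper.tri(R)
  expect_gt(mean(R[same]), mean(R[diff]))
})

test_that("event injection produces the advertised anomalies", {
  s <- quiet_series(60, seed = 2)
  si <- inject_event(s, "SUSTAINED_200", at_s = 10, duration_s = 35, channel = "S3")
  run <- si$values[, "S3"] > 200
  expect_equal(sum(run), 7000)
  expect_true(all(si$values[2001:9000, "S3"] == 210))

  sp <- inject_event(s, "SPIKE_500", at_s = 5)
  expect_equal(sum(sp$values > 500), 1)

  expect_identical(inject_event(s, "SUSTAINED_200", at_s = 1, duration_s = 0)$values,
                   s$values)
  expect_error(inject_event(s, "SUSTAINED_200", at_s = 50, duration_s = 20),
               "outside")

  sa <- inject_event(s, "ASYMMETRY_45", at_s = 0, duration_s = 60)
  asym <- plantarpress:::asymmetry_signal(sa$values, default_sensor_layout())
  expect_true(mean(asym > 0.45) > 0.99)
})
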