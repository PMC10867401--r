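test_that("a sustained injection raises exactly one event with its duration", {
  s <- quiet_series(60, seed = 2)
  si <- inject_event(s, "SUSTAINED_200", at_s = 10, duration_s = 35, channel = "S3")
  ev <- scan_alerts(si)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$kind, "HIGH_PRESSURE_SUSTAINED")
  expect_equal(ev$duration_s, 35)
  expect_equal(ev$onset_s, 10)
  expect_equal(ev$channels, "S3")
})

test_that("an excursion of exactly 30 s raises no sustained alert", {
  s <- quiet_series(45, seed = 3)
  s30 <- inject_event(s, "SUSTAINED_200", at_s = 5, duration_s = 30, channel = "S1")
  expect_equal(nrow(scan_alerts(s30)), 0)
  # one extra frame tips it over the strict boundary
  s30p <- inject_event(s, "SUSTAINED_200", at_s = 5, duration_s = 30.005,
                       channel = "S1")
  ev <- scan_alerts(s30p)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$kind, "HIGH_PRESSURE_SUSTAINED")
})

test_that("spikes are detected only above 500 kPa", {
  s <- quiet_series(10, seed = 4)
  ev0 <- scan_alerts(inject_event(s, "SPIKE_500", at_s = 3, level = 499))
  expect_false("HIGH_PRESSURE_SPIKE" %in% ev0$kind)
  ev1 <- scan_alerts(inject_event(s, "SPIKE_500", at_s = 3, level = 501))
  expect_equal(sum(ev1$kind == "HIGH_PRESSURE_SPIKE"), 1)
  spike <- ev1[ev1$kind == "HIGH_PRESSURE_SPIKE", ]
  expect_equal(spike$channels, "S1")
  expect_equal(spike$peak_value, 501)
  expect_equal(spike$duration_s, 1 / 200)
})

test_that("persistent left/right asymmetry raises an uneven-pressure event", {
  s <- quiet_series(20, seed = 5)
  expect_equal(sum(scan_alerts(s)$kind == "UNEVEN_PRESSURE"), 0)
  sa <- inject_event(s, "ASYMMETRY_45", at_s = 5, duration_s = 4)
  ev <- scan_alerts(sa)
  expect_equal(sum(ev$kind == "UNEVEN_PRESSURE"), 1)
  un <- ev[ev$kind == "UNEVEN_PRESSURE", ]
  expect_gte(un$duration_s, 4 - 0.01)
  # sub-second flicker is ignored
  sf <- inject_event(s, "ASYMMETRY_45", at_s = 5, duration_s = 0.5)
  expect_equal(sum(scan_alerts(sf)$kind == "UNEVEN_PRESSURE"), 0)
})

test_that("continuous load beyond the overuse limit raises one event", {
  rules <- alert_rules(overuse_duration = 10)   # scaled-down limit
  s <- quiet_series(15, seed = 6)
  ev <- scan_alerts(s, rules)
  expect_equal(sum(ev$kind == "OVERUSE"), 1)
  # an unloaded gap splits the run below the limit
  v <- s$values
  v[1400:1600, ] <- 0
  s2 <- pressure_series(v)
  expect_equal(sum(scan_alerts(s2, rules)$kind == "OVERUSE"), 0)
})

test_that("an all-zero series raises nothing", {
  z <- pressure_series(matrix(0, 400, 8))
  expect_equal(nrow(scan_alerts(z)), 0)
  expect_equal(nrow(monitor_series(z)), 0)
})

test_that("uncalibrated series are rejected", {
  raw <- pressure_series(matrix(0.5, 100, 8), unit = "relcap")
  expect_error(scan_alerts(raw), "calibrat")
  expect_error(monitor_series(raw), "calibrat")
})

test_that("fatigued window labels raise a fatigue event after three windows", {
  s <- quiet_series(6, seed = 7)
  labels <- c("WALK", "WALK", "RUN_FATIGUED", "RUN_FATIGUED", "RUN_FATIGUED",
              "WALK")
  ev <- scan_alerts(s, window_labels = labels)
  expect_equal(sum(ev$kind == "FATIGUE"), 1)
  fat <- ev[ev$kind == "FATIGUE", ]
  expect_equal(fat$onset_s, (2 * 30) / 200)
  ev2 <- scan_alerts(s, window_labels = c("WALK", "RUN_FATIGUED",
                                          "RUN_FATIGUED", "WALK"))
  expect_equal(sum(ev2$kind == "FATIGUE"), 0)
})

test_that("online monitoring equals offline scanning on seeded event fixtures", {
  # scaled-down rule durations so short fixtures can contain real events
  rules <- alert_rules(sustained_duration = 1, overuse_duration = 3,
                       asymmetry_min_duration = 0.5)
  set.seed(99)
  for (i in 1:100) {
    s <- quiet_series(6, seed = 200 + i, noise_sd = 5)
    if (i %% 2 == 0)
      s <- inject_event(s, "SUSTAINED_200", at_s = runif(1, 0, 2),
                        duration_s = runif(1, 0.5, 3),
                        channel = sample(paste0("S", 1:8), 1))
    if (i %% 3 == 0)
      s <- inject_event(s, "SPIKE_500", at_s = runif(1, 0, 5))
    if (i %% 5 == 0)
      s <- inject_event(s, "ASYMMETRY_45", at_s = runif(1, 0, 3),
                        duration_s = runif(1, 0.3, 2))
    offline <- scan_alerts(s, rules)
    online <- monitor_series(s, rules, chunk = 100)
    expect_events_equal(offline, online)
  }
})

test_that("monitor event sets are invariant to stream chunking", {
  rules <- alert_rules(sustained_duration = 1, overuse_duration = 3,
                       asymmetry_min_duration = 0.5)
  s <- quiet_series(5, seed = 123, noise_sd = 5)
  s <- inject_event(s, "SUSTAINED_200", at_s = 1, duration_s = 1.8, channel = "S5")
  s <- inject_event(s, "SPIKE_500", at_s = 4)
  ref <- scan_alerts(s, rules)
  for (chunk in c(1, 7, 100, 1000)) {
    expect_events_equal(ref, monitor_series(s, rules, chunk = chunk))
  }
})

test_that("streams with non-increasing timestamps are rejected", {
  mon <- alert_monitor(sample_rate = 200)
  mon$feed(matrix(10, 3, 8), times = c(0, 0.005, 0.01))
  expect_error(mon$feed(matrix(10, 2, 8), times = c(0.009, 0.02)),
               "out-of-order")
})

test_that("a single frame above 500 kPa yields one spike on finalize", {
  mon <- alert_monitor(sample_rate = 200)
  ev_open <- mon$feed(matrix(600, 1, 8))
  expect_equal(nrow(ev_open), 0)     # run still open
  ev <- mon$finalize()
  expect_equal(sum(ev$kind == "HIGH_PRESSURE_SPIKE"), 1)
})
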