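test_that("zone assignment partitions pressures with left-closed boundaries", {
  expect_equal(as.character(zone_assign(c(0, 30, 49.9))), rep("LOW", 3))
  expect_equal(as.character(zone_assign(c(50, 100, 199.9))), rep("MEDIUM", 3))
  expect_equal(as.character(zone_assign(c(200, 399))), rep("HIGH", 2))
  expect_equal(as.character(zone_assign(c(400, 450, 1000))), rep("VERY_HIGH", 3))
  expect_error(zone_assign(-1), "non-negative")
})

test_that("zone occupancy times are conserved per channel", {
  const <- pressure_series(matrix(100, nrow = 2000, ncol = 8))  # 10 s
  zh <- zone_histogram(const)
  expect_equal(unname(zh[, "MEDIUM"]), rep(10, 8))
  expect_equal(sum(zh[, c("LOW", "HIGH", "VERY_HIGH")]), 0)

  half <- pressure_series(rbind(matrix(30, 1000, 8), matrix(250, 1000, 8)))
  zh2 <- zone_histogram(half)
  expect_equal(unname(zh2[, "LOW"]), rep(5, 8))
  expect_equal(unname(zh2[, "HIGH"]), rep(5, 8))

  s <- generate_posture_series("RUN", 20, seed = 9)
  zh3 <- zone_histogram(s)
  expect_equal(unname(rowSums(zh3)), rep(series_duration(s), 8))
})

test_that("high-pressure dwell equals the HIGH + VERY_HIGH zone occupancy", {
  s <- generate_posture_series("JUMP", 30, seed = 4)
  hp <- high_pressure_time(s, 200)
  zh <- zone_histogram(s)
  expect_equal(hp, zh[, "HIGH"] + zh[, "VERY_HIGH"])

  const <- pressure_series(matrix(210, nrow = 12000, ncol = 8))  # 60 s
  expect_equal(unname(high_pressure_time(const)), rep(60, 8))
  low <- pressure_series(matrix(150, nrow = 100, ncol = 8))
  expect_equal(unname(high_pressure_time(low)), rep(0, 8))
})

test_that("mean pressure excludes the low zone and flags all-low channels", {
  v <- matrix(10, nrow = 100, ncol = 8)
  v[seq(1, 99, by = 2), 1] <- 100          # S1 alternates low/100
  v[, 2] <- 80                             # S2 constant 80
  s <- pressure_series(v)
  m <- mean_pressure_excluding_low(s)
  expect_equal(unname(m[1]), 100)
  expect_equal(unname(m[2]), 80)
  expect_equal(unname(m[3]), 0)
  flags <- attr(m, "all_low")
  expect_false(flags[["S1"]])
  expect_true(all(flags[3:8]))
})

test_that("posture time accounts for every annotated sample", {
  sched <- data.frame(posture = c("STAND", "WALK"), duration_s = c(3, 3))
  s <- generate_mixed_session(sched, seed = 2)
  pt <- posture_time(s)
  expect_equal(unname(pt[c("STAND", "WALK")]), c(3, 3))
  expect_equal(sum(pt), series_duration(s))
  bare <- pressure_series(matrix(10, 10, 8))
  expect_error(posture_time(bare), "annotation")
})

test_that("step counting recovers the generated cycle count", {
  s <- clean_series("WALK", 20)
  rep <- activity_report(s, user_profile())
  expect_equal(rep$steps, 20)
  expect_equal(rep$run_steps, 0)
  expect_equal(rep$jumps, 0)
  # default noise: within +-2 %
  sn <- generate_posture_series("WALK", 150, seed = 5)
  repn <- activity_report(sn, user_profile())
  expect_lte(abs(repn$steps - 150) / 150, 0.02)
})

test_that("activity reports scale with the user profile", {
  s <- clean_series("RUN", 10)
  p1 <- user_profile(stride_length = 0.7)
  p2 <- user_profile(stride_length = 1.4)
  r1 <- activity_report(s, p1)
  r2 <- activity_report(s, p2)
  expect_equal(r1$run_steps, 10)
  expect_equal(2 * r1$distance_m, r2$distance_m)

  stand <- quiet_series(5)
  r0 <- activity_report(stand, p1)
  expect_equal(r0$steps + r0$run_steps + r0$jumps, 0)
  expect_equal(r0$distance_m, 0)
  expect_gt(r0$calories_kcal, 0)

  expect_error(activity_report(s, list(body_mass = 70)), "user_profile")
  expect_error(user_profile(body_mass = -1), "positive")
})
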