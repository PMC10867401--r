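# Shared fixtures: everything is generated in code at test time.

# a quiet standing baseline of the given duration (seconds) at 200 Hz
quiet_series <- function(duration_s, seed = 1, noise_sd = 2) {
  n_cycles <- ceiling(duration_s * 200 / 120)
  s <- generate_posture_series("STAND", n_cycles, seed = seed,
                               template = gait_template("STAND", noise_sd = noise_sd))
  pressure_series(s$values[seq_len(round(duration_s * 200)), , drop = FALSE],
                  sample_rate = 200,
                  annotation = rep("STAND", round(duration_s * 200)))
}

# noise-free single-posture series (deterministic waveform repetition)
clean_series <- function(posture, n_cycles, seed = 1) {
  generate_posture_series(posture, n_cycles, seed = seed,
                          template = gait_template(posture, amplitude_jitter = 0,
                                                   phase_jitter = 0, noise_sd = 0))
}

# small six-class labelled window set for classifier tests
small_six_class_windows <- function(cycles_per_class = 30, seed = 100) {
  sets <- lapply(seq_along(classifier_classes()), function(i)
    segment_series(generate_posture_series(classifier_classes()[i],
                                           cycles_per_class, seed = seed + i)))
  combine_windows(sets)
}

# quick CNN spec for smoke tests (same architecture family, narrow layers)
tiny_cnn_spec <- function(epochs = 8) {
  cnn_spec(filters = c(16L, 16L, 32L, 32L), epochs = epochs, batch_size = 32L,
           seed = 7L)
}

expect_events_equal <- function(a, b) {
  expect_equal(nrow(a), nrow(b))
  if (nrow(a)) {
    expect_equal(a$kind, b$kind)
    expect_equal(a$onset_s, b$onset_s)
    expect_equal(a$duration_s, b$duration_s)
    expect_equal(a$channels, b$channels)
    expect_equal(a$peak_value, b$peak_value)
  }
}
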