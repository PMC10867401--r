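# Synthetic 8-channel gait generator. Templates are half-sine loading pulses
# phase-shifted along the stance (heel strike -> midfoot -> metatarsal push-off
# -> toe-off); fatigue lowers peak load, slows/widens the pulses and raises
# cycle-to-cycle timing variability.

# one half-sine pulse on the cyclic axis [0, 1), sampled at n points
half_sine_pulse <- function(n, center, width, amplitude) {
  t <- (seq_len(n) - 1) / n
  d <- t - center
  d <- d - round(d)             # wrap to (-0.5, 0.5]
  inside <- abs(d) <= width / 2
  out <- numeric(n)
  out[inside] <- amplitude * cos(pi * d[inside] / width)^2
  out
}

# per-channel pulse parameters for one posture: peak kPa, pulse centre and
# width as fractions of the gait cycle
template_params <- function(posture) {
  base <- switch(posture,
    WALK = list(
      peak   = c(230, 90, 250, 60, 80, 210, 260, 240),
      center = c(0.55, 0.72, 0.55, 0.40, 0.72, 0.56, 0.18, 0.20),
      width  = c(0.35, 0.25, 0.35, 0.30, 0.25, 0.35, 0.35, 0.35)),
    RUN = list(
      peak   = c(320, 120, 340, 70, 100, 300, 300, 280),
      center = c(0.42, 0.55, 0.42, 0.30, 0.55, 0.43, 0.15, 0.16),
      width  = c(0.25, 0.20, 0.25, 0.20, 0.20, 0.25, 0.22, 0.22)),
    JUMP = list(
      peak   = c(350, 140, 370, 80, 120, 330, 380, 360),
      center = c(0.60, 0.70, 0.60, 0.58, 0.70, 0.61, 0.55, 0.56),
      width  = c(0.22, 0.15, 0.22, 0.20, 0.15, 0.22, 0.20, 0.20)),
    stop("no dynamic template for posture ", posture)
  )
  base
}

build_waveform <- function(posture, cycle_length) {
  pc <- posture_classes()
  row <- pc[pc$name == posture, ]
  if (row$activity == "STAND") {
    # static load: heel-dominant constant pattern
    level <- c(90, 30, 85, 40, 28, 70, 110, 105)
    return(matrix(rep(level, each = cycle_length), ncol = 8,
                  dimnames = list(NULL, paste0("S", 1:8))))
  }
  par <- template_params(row$activity)
  if (row$fatigued) {
    # fatigue: lower peaks, longer flatter contact, delayed push-off
    par$peak <- par$peak * 0.8
    par$width <- pmin(par$width * 1.3, 0.9)
    par$center <- par$center + 0.05
  }
  w <- vapply(1:8, function(ch) {
    half_sine_pulse(cycle_length, par$center[ch], par$width[ch], par$peak[ch])
  }, numeric(cycle_length))
  colnames(w) <- paste0("S", 1:8)
  w
}

#' Gait waveform template for one posture
#'
#' A template holds the noise-free per-channel loading waveform of one gait
#' cycle (`cycle_length` samples, default 120) plus the stochastic generator
#' parameters. Default templates concentrate peak load in the metatarsal
#' (S1, S3, S6) and heel (S7, S8) regions, with lighter loading of the
#' midfoot contour sensor (S4) and the toe sensors (S2, S5). Fatigued
#' variants have 0.8x peak amplitude, wider (slower) pulses and 1.5x phase
#' jitter. The STAND template is a constant heel-dominant load with no cycle
#' structure and no jitter.
#'
#' @param posture posture name, see [posture_classes()].
#' @param cycle_length samples per gait cycle (default 120).
#' @param amplitude_jitter per-cycle multiplicative amplitude jitter (sd of a
#'   unit-mean Gaussian factor).
#' @param phase_jitter per-cycle timing jitter, sd as a fraction of the cycle.
#' @param noise_sd additive Gaussian sensor noise, kPa.
#' @return An object of class `gait_template` with fields `posture`,
#'   `cycle_length`, `waveform` (`cycle_length x 8`), `amplitude_jitter`,
#'   `phase_jitter`, `noise_sd`.
#' @examples
#' tpl <- gait_template("WALK")
#' matplot(tpl$waveform, type = "l")
#' @export
gait_template <- function(posture, cycle_length = 120L,
                          amplitude_jitter = NULL, phase_jitter = NULL,
                          noise_sd = 5) {
  assert_posture(posture)
  cycle_length <- as.integer(cycle_length)
  stopifnot(cycle_length >= 4L)
  pc <- posture_classes()
  row <- pc[pc$name == posture, ]
  static <- row$activity == "STAND"
  if (is.null(amplitude_jitter)) amplitude_jitter <- if (static) 0 else 0.05
  if (is.null(phase_jitter))
    phase_jitter <- if (static) 0 else if (row$fatigued) 0.03 else 0.02
  wf <- build_waveform(posture, cycle_length)
  stopifnot(all(wf >= 0), all(wf <= 500))
  structure(
    list(posture = posture, cycle_length = cycle_length, waveform = wf,
         amplitude_jitter = amplitude_jitter, phase_jitter = phase_jitter,
         noise_sd = noise_sd),
    class = "gait_template"
  )
}

# draw n_cycles of one posture; assumes the RNG state is already set
draw_cycles <- function(template, n_cycles) {
  cl <- template$cycle_length
  out <- matrix(0, nrow = n_cycles * cl, ncol = 8)
  for (i in seq_len(n_cycles)) {
    amp <- 1 + rnorm(1L, 0, template$amplitude_jitter)
    shift <- round(rnorm(1L, 0, template$phase_jitter) * cl)
    idx <- ((seq_len(cl) - 1 + shift) %% cl) + 1
    cyc <- template$waveform[idx, , drop = FALSE] * amp
    if (template$noise_sd > 0)
      cyc <- cyc + matrix(rnorm(cl * 8L, 0, template$noise_sd), ncol = 8)
    out[((i - 1) * cl + 1):(i * cl), ] <- cyc
  }
  pmax(out, 0)
}

#' Generate a single-posture synthetic pressure series
#'
#' Draws `n_cycles` gait cycles of the given posture from its template, with
#' per-cycle amplitude and phase jitter and additive Gaussian sensor noise,
#' clipped at 0 kPa. Deterministic for a fixed seed.
#'
#' @param posture posture name, see [posture_classes()].
#' @param n_cycles number of gait cycles (default 150).
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @param template a [gait_template()]; defaults to the posture's template.
#' @param sample_rate sampling rate in Hz (default 200).
#' @return A [pressure_series()] of `n_cycles * cycle_length` samples with
#'   per-sample posture annotation.
#' @examples
#' s <- generate_posture_series("WALK", n_cycles = 3, seed = 1)
#' n_samples(s)  # 360
#' @export
generate_posture_series <- function(posture, n_cycles = 150L, seed = NULL,
                                    template = gait_template(posture),
                                    sample_rate = 200) {
  assert_posture(posture)
  if (!is.numeric(n_cycles) || length(n_cycles) != 1L || n_cycles < 1)
    stop("n_cycles must be a positive integer")
  n_cycles <- as.integer(n_cycles)
  if (template$posture != posture)
    stop("template posture (", template$posture, ") does not match ", posture)
  vals <- if (is.null(seed)) draw_cycles(template, n_cycles) else
    withr::with_seed(seed, draw_cycles(template, n_cycles))
  pressure_series(vals, sample_rate = sample_rate,
                  annotation = rep(posture, nrow(vals)))
}

#' Generate a mixed-posture session
#'
#' Concatenates per-posture segments according to a schedule, emulating a
#' long recording of daily activity (e.g. a 40-min mixture of standing,
#' walking, running and jumping). Each segment lasts `round(duration_s *
#' sample_rate)` samples and is annotated with its posture.
#'
#' @param schedule data.frame with columns `posture` and `duration_s`, or a
#'   list of `c(posture, duration)` pairs.
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @param sample_rate sampling rate in Hz.
#' @param templates optional named list of [gait_template()] overrides.
#' @return An annotated [pressure_series()].
#' @examples
#' sched <- data.frame(posture = c("STAND", "WALK"), duration_s = c(1, 2))
#' s <- generate_mixed_session(sched, seed = 1)
#' n_samples(s)  # 600
#' @export
generate_mixed_session <- function(schedule, seed = NULL, sample_rate = 200,
                                   templates = list()) {
  if (is.list(schedule) && !is.data.frame(schedule))
    schedule <- data.frame(
      posture = vapply(schedule, function(x) as.character(x[[1]]), character(1)),
      duration_s = vapply(schedule, function(x) as.numeric(x[[2]]), numeric(1)))
  if (!is.data.frame(schedule) || nrow(schedule) == 0L)
    stop("schedule must be a non-empty data.frame(posture, duration_s)")
  if (any(schedule$duration_s <= 0)) stop("schedule durations must be positive")
  vapply(schedule$posture, assert_posture, character(1))

  gen <- function() {
    parts <- vector("list", nrow(schedule))
    for (i in seq_len(nrow(schedule))) {
      pst <- schedule$posture[i]
      tpl <- templates[[pst]]
      if (is.null(tpl)) tpl <- gait_template(pst)
      n <- round(schedule$duration_s[i] * sample_rate)
      vals <- draw_cycles(tpl, ceiling(n / tpl$cycle_length))[seq_len(n), , drop = FALSE]
      parts[[i]] <- list(values = vals, posture = pst)
    }
    parts
  }
  parts <- if (is.null(seed)) gen() else withr::with_seed(seed, gen())
  vals <- do.call(rbind, lapply(parts, `[[`, "values"))
  ann <- unlist(lapply(parts, function(p) rep(p$posture, nrow(p$values))))
  pressure_series(vals, sample_rate = sample_rate, annotation = ann)
}

#' Inject a synthetic abnormal-pressure event into a series
#'
#' Fixture helper for exercising the alert engine: overwrites part of a
#' series with a pressure spike, a sustained high-pressure episode, or a
#' left/right loading asymmetry.
#'
#' @param series a [pressure_series()].
#' @param event one of `"SPIKE_500"` (one frame of one channel raised above
#'   500 kPa), `"SUSTAINED_200"` (one channel held above 200 kPa for
#'   `duration_s`), `"ASYMMETRY_45"` (left-side channels S6, S7 scaled so the
#'   left/right difference exceeds 45 %).
#' @param at_s event onset, seconds.
#' @param duration_s event duration, seconds (ignored for `SPIKE_500`).
#' @param channel channel name for the spike / sustained events.
#' @param level pressure level used for the injected samples, kPa.
#' @param factor scaling factor applied to S6 and S7 for `ASYMMETRY_45`.
#' @return The modified [pressure_series()].
#' @export
inject_event <- function(series, event = c("SPIKE_500", "SUSTAINED_200", "ASYMMETRY_45"),
                         at_s, duration_s = 0, channel = "S1",
                         level = switch(event, SPIKE_500 = 520, 210),
                         factor = 3) {
  event <- match.arg(event)
  stopifnot(inherits(series, "pressure_series"))
  rate <- series$sample_rate
  n <- n_samples(series)
  i0 <- floor(at_s * rate) + 1L
  n_ev <- if (event == "SPIKE_500") 1L else round(duration_s * rate)
  if (n_ev == 0L) return(series)
  if (i0 < 1L || i0 + n_ev - 1L > n)
    stop("event window [", at_s, ", ", at_s + duration_s, "] s outside the series extent")
  idx <- i0:(i0 + n_ev - 1L)
  vals <- series$values
  if (event == "SPIKE_500") {
    vals[idx, channel] <- level
  } else if (event == "SUSTAINED_200") {
    vals[idx, channel] <- level
  } else {
    vals[idx, c("S6", "S7")] <- vals[idx, c("S6", "S7")] * factor
  }
  pressure_series(vals, sample_rate = rate, annotation = series$annotation,
                  unit = series$unit)
}
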