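# Synthetic raw-actigraphy generator. Emulates wrist recordings with the
# acquisition characteristics of a 10 Hz, +/-8 g, 16 mg MEMS actigraph:
# a gravity-bearing triaxial signal with circadian rest-activity
# alternation, Poisson movement bouts while awake, posture changes during
# sleep, sensor noise, quantization and clipping -- plus ground-truth sleep
# annotations so downstream stages can be tested without real data.

#' Configuration for the synthetic-recording generator
#'
#' Defaults state the emulated acquisition and a typical adult free-living
#' schedule: 10-day recordings at 10 Hz, +/-8 g range, 16 mg resolution,
#' sleep from 23:30 to 07:00 with per-day jitter.
#'
#' @param n_days number of days (>= 1)
#' @param rate sampling rate, samples/second
#' @param sleep_onset,sleep_offset nominal clock times ("HH:MM" or seconds
#'   since midnight) of sleep start/end; the window may wrap midnight
#' @param schedule_jitter_sd per-day SD of onset/offset jitter, minutes
#' @param wake_bout_rate expected movement bouts per minute while awake;
#'   each bout also reorients the wrist, as daytime arm use does
#' @param bout_amplitude g-scale of movement bursts
#' @param bout_duration mean bout duration, seconds
#' @param night_posture_changes expected reorientations per full night
#' @param noise_sd per-axis white sensor noise SD, g
#' @param quantization_step sensor resolution, g (default 16 mg)
#' @param clip dynamic range, g (default +/-8 g)
#' @param timestamp_jitter_sd SD of timestamp perturbation, ms (0 = exact
#'   grid; used to exercise [regularize_timestamps()])
#' @param start_ms recording start, ms since epoch; default is a midnight
#' @param subject_id subject label
#' @param seed RNG seed
#' @return an object of class `synthetic_config`
#' @export
synthetic_config <- function(n_days = 10, rate = 10,
                             sleep_onset = "23:30", sleep_offset = "07:00",
                             schedule_jitter_sd = 15,
                             wake_bout_rate = 5, bout_amplitude = 0.25,
                             bout_duration = 5,
                             night_posture_changes = 4,
                             noise_sd = 0.01,
                             quantization_step = 0.016, clip = 8.0,
                             timestamp_jitter_sd = 0,
                             start_ms = 0, subject_id = "synthetic",
                             seed = 1L) {
  cfg <- list(n_days = n_days, rate = rate,
              sleep_onset = parse_clock(sleep_onset),
              sleep_offset = parse_clock(sleep_offset),
              schedule_jitter_sd = schedule_jitter_sd,
              wake_bout_rate = wake_bout_rate,
              bout_amplitude = bout_amplitude,
              bout_duration = bout_duration,
              night_posture_changes = night_posture_changes,
              noise_sd = noise_sd,
              quantization_step = quantization_step, clip = clip,
              timestamp_jitter_sd = timestamp_jitter_sd,
              start_ms = start_ms, subject_id = subject_id,
              seed = as.integer(seed))
  validate_synthetic_config(cfg)
  structure(cfg, class = "synthetic_config")
}

validate_synthetic_config <- function(cfg) {
  if (!is.numeric(cfg$n_days) || cfg$n_days < 1) {
    stop_config("n_days must be >= 1")
  }
  if (!is.numeric(cfg$rate) || cfg$rate <= 0) stop_config("rate must be > 0")
  if (cfg$quantization_step <= 0 || cfg$quantization_step >= cfg$clip) {
    stop_config("need 0 < quantization_step < clip")
  }
  rates <- c(cfg$wake_bout_rate, cfg$night_posture_changes,
             cfg$noise_sd, cfg$schedule_jitter_sd, cfg$bout_duration)
  if (any(rates < 0)) stop_config("rates and noise parameters must be >= 0")
  invisible(cfg)
}

random_unit_vector <- function(n = 1) {
  m <- matrix(rnorm(3 * n), ncol = 3)
  m / sqrt(rowSums(m^2))
}

#' Generate one synthetic raw recording with ground truth
#'
#' Awake segments carry Poisson-arriving bouts of band-limited (0.3--3 Hz)
#' Gaussian movement superposed on a gravity vector; sleep segments are
#' near-motionless except at posture events, where the gravity orientation
#' jumps to a new random direction. Samples are quantized to
#' `quantization_step` and clipped at `clip`. Identical config (including
#' seed) gives bit-identical output.
#'
#' @param config a [synthetic_config()]
#' @return list with `recording` (a `triaxial_recording`) and `truth`
#'   (sleep windows, posture events, schedule-implied L5/M10 onsets)
#' @export
generate_recording <- function(config) {
  validate_synthetic_config(config)
  with_seed(config$seed, generate_recording_impl(config))
}

# schedule + posture draws (the RNG prefix shared by full generation and
# truth-only generation; draw order must not change between the two)
synth_schedule <- function(cfg) {
  rate <- cfg$rate
  n <- round(cfg$n_days * 86400 * rate)
  step_ms <- 1000 / rate
  span_ms <- n * step_ms
  dur_s <- (cfg$sleep_offset - cfg$sleep_onset) %% 86400
  jit <- function() rnorm(1, 0, cfg$schedule_jitter_sd * 60)
  windows <- list()
  # initial partial night: subject wakes on day 0 at sleep_offset
  first_off <- (cfg$sleep_offset + jit()) * 1000
  if (first_off > 0) windows[[length(windows) + 1]] <- c(0, first_off)
  for (d in seq_len(cfg$n_days) - 1) {
    on <- (d * 86400 + cfg$sleep_onset + jit()) * 1000
    off <- on + (dur_s + jit()) * 1000
    windows[[length(windows) + 1]] <- c(max(on, 0), min(off, span_ms))
  }
  sw <- normalize_intervals(do.call(rbind, windows))
  sw <- sw[sw[, 1] < span_ms, , drop = FALSE]

  posture <- numeric(0)
  if (cfg$night_posture_changes > 0 && nrow(sw) > 0) {
    for (i in seq_len(nrow(sw))) {
      lam <- cfg$night_posture_changes * (sw[i, 2] - sw[i, 1]) /
        (dur_s * 1000)
      k <- rpois(1, lam)
      if (k > 0) posture <- c(posture, sort(runif(k, sw[i, 1], sw[i, 2])))
    }
  }
  list(n = n, step_ms = step_ms, span_ms = span_ms, dur_s = dur_s,
       sw = sw, posture = posture)
}

synth_truth <- function(cfg, sch) {
  sleep_mid <- (cfg$sleep_onset + sch$dur_s / 2) %% 86400
  wake_mid <- (cfg$sleep_offset + (86400 - sch$dur_s) / 2) %% 86400
  list(sleep_windows = sch$sw + cfg$start_ms,
       posture_events = sch$posture + cfg$start_ms,
       true_L5_onset = (sleep_mid - 2.5 * 3600) %% 86400,
       true_M10_onset = (wake_mid - 5 * 3600) %% 86400,
       sleep_onset = cfg$sleep_onset, sleep_offset = cfg$sleep_offset)
}

# ground truth only (no signal synthesis); same RNG prefix as the full
# generator, so truths agree with generate_recording for the same config
generate_truth_only <- function(cfg) {
  validate_synthetic_config(cfg)
  with_seed(cfg$seed, synth_truth(cfg, synth_schedule(cfg)))
}

generate_recording_impl <- function(cfg) {
  rate <- cfg$rate
  sch <- synth_schedule(cfg)
  n <- sch$n; step_ms <- sch$step_ms; span_ms <- sch$span_ms
  sw <- sch$sw; posture <- sch$posture
  t_rel <- (seq_len(n) - 1) * step_ms          # ms from start

  asleep <- rep(FALSE, n)
  for (i in seq_len(nrow(sw))) {
    i0 <- floor(sw[i, 1] / step_ms) + 1
    i1 <- min(ceiling(sw[i, 2] / step_ms), n)
    if (i1 >= i0) asleep[i0:i1] <- TRUE
  }

  # --- wake movement bouts -------------------------------------------------
  env <- numeric(n)
  bout_start_ms <- numeric(0)
  wake_idx <- which(!asleep)
  if (cfg$wake_bout_rate > 0 && length(wake_idx) > 0) {
    wake_minutes <- length(wake_idx) / (rate * 60)
    n_bouts <- rpois(1, cfg$wake_bout_rate * wake_minutes)
    if (n_bouts > 0) {
      starts <- sample(wake_idx, n_bouts, replace = TRUE)
      durs <- pmin(pmax(rexp(n_bouts, 1 / cfg$bout_duration), 1), 30)
      amps <- cfg$bout_amplitude * runif(n_bouts, 0.5, 1.5)
      lens <- pmax(round(durs * rate), 1)
      for (b in seq_len(n_bouts)) {
        i1 <- min(starts[b] + lens[b] - 1, n)
        idx <- starts[b]:i1
        env[idx] <- pmax(env[idx], amps[b])
      }
      env[asleep] <- 0   # bouts never spill into sleep
      bout_start_ms <- (starts - 1) * step_ms
    }
  }

  # orientation is piecewise constant: it changes at night posture events,
  # at every sleep/wake boundary, and at each wake bout (daytime arm use
  # reorients the wrist near-continuously)
  breaks_ms <- sort(unique(c(posture, as.vector(sw), bout_start_ms)))
  breaks_ms <- breaks_ms[breaks_ms > 0 & breaks_ms < span_ms]
  n_seg <- length(breaks_ms) + 1
  gvec <- random_unit_vector(n_seg)
  seg <- findInterval(t_rel, breaks_ms) + 1
  gx <- gvec[seg, 1]; gy <- gvec[seg, 2]; gz <- gvec[seg, 3]

  movement <- function() {
    if (all(env == 0)) return(numeric(n))
    bp_hi <- min(3, rate / 2 * 0.9)
    w <- if (bp_hi > 0.35) {
      # band-limit to the 0.3-3 Hz wrist-movement band
      apply_filter(butter_coeffs(2, low = 0.3, high = bp_hi, fs = rate),
                   rnorm(n))
    } else {
      rnorm(n)        # rate too low to band-limit (degenerate grids)
    }
    s <- sd(w)
    if (s > 0) w <- w / s
    w * env
  }

  noise <- function() if (cfg$noise_sd > 0) rnorm(n, 0, cfg$noise_sd) else 0

  q <- cfg$quantization_step
  finish <- function(v) pmin(pmax(round(v / q) * q, -cfg$clip), cfg$clip)
  x <- finish(gx + movement() + noise())
  y <- finish(gy + movement() + noise())
  z <- finish(gz + movement() + noise())

  time_ms <- cfg$start_ms + t_rel
  if (cfg$timestamp_jitter_sd > 0) {
    j <- rnorm(n, 0, cfg$timestamp_jitter_sd)
    j <- pmin(pmax(j, -0.45 * step_ms), 0.45 * step_ms)
    time_ms <- time_ms + round(j)
  }

  rec <- new_recording(cfg$subject_id, time_ms, x, y, z, rate)
  list(recording = rec, truth = synth_truth(cfg, sch))
}

#' Generate a cohort of synthetic recordings
#'
#' Each subject gets a derived seed plus subject-level jitter of the sleep
#' schedule and movement propensity, so cohorts show realistic
#' between-subject variability while remaining deterministic under the
#' cohort seed.
#'
#' @param base_config a [synthetic_config()]; per-subject configs are
#'   derived from it
#' @param n_subjects number of subjects (>= 1)
#' @param seed cohort seed
#' @return list of `list(recording, truth, config)` of length `n_subjects`
#' @export
generate_cohort <- function(base_config, n_subjects, seed = 1L) {
  cfgs <- cohort_configs(base_config, n_subjects, seed)
  lapply(cfgs, function(cfg) {
    out <- generate_recording(cfg)
    out$config <- cfg
    out
  })
}

#' Per-subject configs of a synthetic cohort
#'
#' The deterministic derivation behind [generate_cohort()]: per-subject
#' seeds plus subject-level jitter of the sleep schedule and movement
#' propensity. Exposed so cohorts can be (re)generated one subject at a
#' time without holding the whole cohort in memory.
#'
#' @inheritParams generate_cohort
#' @return list of `synthetic_config`s of length `n_subjects`
#' @export
cohort_configs <- function(base_config, n_subjects, seed = 1L) {
  if (n_subjects < 1) stop_config("n_subjects must be >= 1")
  validate_synthetic_config(base_config)
  subj_params <- with_seed(seed, {
    lapply(seq_len(n_subjects), function(i) {
      list(onset_shift = rnorm(1, 0, 20 * 60),     # s
           dur_shift = rnorm(1, 0, 15 * 60),       # s
           bout_mult = runif(1, 0.75, 1.3))
    })
  })
  lapply(seq_len(n_subjects), function(i) {
    p <- subj_params[[i]]
    cfg <- base_config
    cfg$seed <- derive_seed(seed, i)
    cfg$subject_id <- sprintf("S%02d", i)
    cfg$sleep_onset <- (cfg$sleep_onset + p$onset_shift) %% 86400
    cfg$sleep_offset <- (cfg$sleep_offset + p$onset_shift + p$dur_shift) %%
      86400
    cfg$wake_bout_rate <- cfg$wake_bout_rate * p$bout_mult
    class(cfg) <- "synthetic_config"
    cfg
  })
}
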