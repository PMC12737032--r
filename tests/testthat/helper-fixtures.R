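# Shared fixtures. Heavy objects (multi-day recordings, the mechanism
# cohort) are built once per test run and memoised in this environment.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

# a 2-day default-config recording with truth (several tests share it)
fix_recording <- function() {
  fixture("rec2d", function() {
    generate_recording(synthetic_config(n_days = 2, seed = 42))
  })
}

# the 10-subject x 3-day cohort study behind the mechanism and recovery
# acceptance checks (single computation, ~2-3 min)
fix_cohort_study <- function() {
  fixture("cohort_study", function() {
    run_study(study_config(synthetic = list(n_days = 3), n_subjects = 10,
                           seed = 7))
  })
}

# build a recording directly from sample values (regular 10 Hz grid)
make_recording <- function(x, y, z, rate = 10, start_ms = 0,
                           subject_id = "fix") {
  n <- length(x)
  new_recording(subject_id, start_ms + (seq_len(n) - 1) * 1000 / rate,
                x, y, z, rate)
}

# constant-orientation gravity recording of given duration (seconds)
gravity_recording <- function(secs, g = c(0, 0, 1), rate = 10,
                              start_ms = 0) {
  n <- secs * rate
  make_recording(rep(g[1], n), rep(g[2], n), rep(g[3], n), rate = rate,
                 start_ms = start_ms)
}

# wrap a plain numeric vector as a single-channel preprocessed signal on
# a regular grid, for metric-level tests
make_signal <- function(values, scheme = "ENMO", rate = 10, start_ms = 0) {
  sig <- preprocess(gravity_recording(1), scheme)   # template
  n <- length(values)
  sig$values <- values
  sig$time_ms <- start_ms + (seq_len(n) - 1) * 1000 / rate
  sig$rate <- rate
  sig
}

# hourly activity series spanning whole days, values given per hour
hourly_series <- function(values_by_hour, method = "test") {
  n <- length(values_by_hour)
  new_activity_series(method, (seq_len(n) - 1) * 3600000,
                      values_by_hour, epoch_length = 3600)
}

# minute activity series from per-epoch values starting at midnight
minute_series <- function(values, method = "test", start_ms = 0) {
  new_activity_series(method, start_ms + (seq_along(values) - 1) * 60000,
                      values, epoch_length = 60)
}
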