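# Sleep scoring: trend-threshold behaviour on forced activity patterns,
# rescoring properties, z-angle scorer contracts, and TST bookkeeping.

test_that("constant activity yields zero sleep; a night/day square wave
          recovers the nights", {
  const <- minute_series(rep(5, 1440 * 2))
  sc <- masda_score(const)
  expect_equal(total_sleep_time(sc), 0)
  expect_equal(nrow(sc$segments), 0)

  # 8 h of 0 activity at night, 16 h of A by day, 3 days
  A <- 4
  day_pattern <- c(rep(0, 480), rep(A, 960))
  sq <- masda_score(minute_series(rep(day_pattern, 3)))
  # trend ~ (16/24) A, threshold 0.25 trend ~ 0.67 > 0: nights are sleep
  segs <- sq$segments
  expect_equal(nrow(segs), 3)
  for (d in 0:2) {
    expect_lte(abs(segs[d + 1, "start"] - d * 86400000), 60000)
    expect_lte(abs(segs[d + 1, "end"] - (d * 86400000 + 480 * 60000)),
               60000)
  }
  expect_error(masda_score(minute_series(rep(1, 100))), "24 h",
               class = "actisig_config_error")
})

test_that("rescoring is idempotent and lowering the threshold never adds
          raw sleep", {
  set.seed(55)
  v <- rep(c(rep(0.02, 480), rexp(960, 1 / 4)), 2)
  a <- minute_series(v)
  sc1 <- masda_score(a)
  # feed the scored labels back through scoring stages via a second call
  # on an activity series that reproduces the same raw labels
  rt <- run_table(sc1$labels)
  relabeled <- masda_score(a)   # identical input -> identical output
  expect_identical(relabeled$labels, sc1$labels)

  # idempotence of the two-stage rescoring itself
  raw <- sc1$labels
  once <- actisig:::drop_short_sleep(actisig:::bridge_short_wake(raw, 30),
                                     30)
  twice <- actisig:::drop_short_sleep(actisig:::bridge_short_wake(once, 30),
                                      30)
  expect_identical(once, twice)

  # monotonicity of the raw classification in the threshold
  half <- 720
  trend <- actisig:::rolling_mean_trunc(v, half)
  raw_lo <- v < 0.15 * trend
  raw_hi <- v < 0.25 * trend
  expect_true(all(raw_hi | !raw_lo))    # lower frac => subset of sleep
  expect_lte(sum(raw_lo), sum(raw_hi))
})

test_that("segments reconstruct labels exactly", {
  set.seed(66)
  v <- rexp(1440 * 2) * rep(c(0.01, 1), 1440)
  sc <- masda_score(minute_series(v))
  lab2 <- rep(FALSE, length(sc$labels))
  for (i in seq_len(nrow(sc$segments))) {
    sel <- sc$epoch_start_ms >= sc$segments[i, "start"] &
      sc$epoch_start_ms < sc$segments[i, "end"]
    lab2[sel] <- TRUE
  }
  expect_identical(lab2, sc$labels)
})

test_that("z-angle scorer: motionless input is one long inactivity bout;
          continuous rotation yields no sleep", {
  still <- gravity_recording(86400 * 1.5, g = c(0.1, 0.3,
                                                sqrt(1 - 0.1)))
  sc <- vanhees_score(still)
  expect_gt(total_sleep_time(sc), 30)   # nearly the whole span

  # device rotating fast enough that block-angle changes exceed 5 deg
  t <- seq(0, 86400 * 1.5 - 0.1, by = 0.1)
  th <- 2 * pi * t / 60                 # full revolution per minute
  rot <- new_recording("rot", t * 1000, cos(th), rep(0, length(t)),
                       sin(th), 10)
  sc2 <- vanhees_score(rot)
  expect_equal(total_sleep_time(sc2), 0)

  expect_error(vanhees_score(gravity_recording(3600)), "noon",
               class = "actisig_config_error")
})

test_that("threshold-metric activity scores more sleep than integration
          on the same cohort", {
  # threshold metrics zero out quiet night epochs, so the trend scorer
  # keeps them asleep; integration (PIM) leaves small nonzero values that
  # clip the scored night short
  res <- fix_cohort_study()
  tsts <- colMeans(res$tst)
  for (pipe in c("ZCM(FMpre)", "TAT(FMpre)", "AC", "MW")) {
    expect_gt(tsts[[pipe]], tsts[["PIM(FMpre)"]])
  }
})

test_that("total sleep time sums segment durations", {
  sc <- structure(list(segments = cbind(start = c(0, 10 * 3600000),
                                        end = c(6 * 3600000,
                                                12 * 3600000))),
                  class = "sleep_score")
  expect_equal(total_sleep_time(sc), 8)
  empty <- structure(list(segments = cbind(start = numeric(0),
                                           end = numeric(0))),
                     class = "sleep_score")
  expect_equal(total_sleep_time(empty), 0)

  all_sleep <- new_activity_series("t", (0:(1440 * 10 - 1)) * 60000,
                                   rep(0, 14400), 60)
  # constant zero activity has zero trend -> no epoch below threshold;
  # force labels directly instead to check the 10-day bookkeeping
  sc10 <- actisig:::new_sleep_score(all_sleep$epoch_start_ms,
                                    rep(TRUE, 14400), 60, "manual",
                                    list())
  expect_equal(total_sleep_time(sc10), 240)
})
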