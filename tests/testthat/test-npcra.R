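# Circadian indicators: profile averaging, window search vs exhaustive
# oracle, closed forms for IS/IV, scale invariance, scheme admissibility.

test_that("mean profile averages complete days only and matches a
          brute-force day-slice mean", {
  one_day <- sin(2 * pi * (0:1439) / 1440)^2
  two <- minute_series(c(one_day, one_day))
  p <- mean_profile(two)
  expect_equal(p$bins, one_day)
  expect_equal(p$n_days_used, 2)

  lohi <- minute_series(c(rep(0, 1440), rep(2, 1440)))
  expect_equal(mean_profile(lohi)$bins, rep(1, 1440))

  # trailing partial day must not enter
  part <- minute_series(c(one_day, one_day, rep(99, 100)))
  expect_equal(mean_profile(part)$n_days_used, 2)
  expect_equal(mean_profile(part)$bins, one_day)

  # brute-force oracle on random multi-day data
  set.seed(23)
  vals <- matrix(rexp(1440 * 4), nrow = 1440)
  p4 <- mean_profile(minute_series(as.vector(vals)))
  expect_equal(p4$bins, rowMeans(vals))

  expect_error(mean_profile(minute_series(rep(1, 100))),
               "complete", class = "actisig_config_error")
})

test_that("L5/M10 location: forced profiles and the exhaustive-search
          oracle", {
  # zero block 01:00-06:00, 10 elsewhere
  prof <- rep(10, 1440); prof[61:360] <- 0
  w <- locate_l5_m10(structure(list(bins = prof, bin_length = 60,
                                    n_days_used = 1, label = "t"),
                               class = "daily_profile"))
  expect_equal(w$L5$onset_s, 3600)
  expect_equal(w$L5$mean_value, 0)

  # activity 10 on 09:00-19:00, 0 elsewhere
  prof2 <- rep(0, 1440); prof2[541:1140] <- 10
  w2 <- locate_l5_m10(structure(list(bins = prof2, bin_length = 60,
                                     n_days_used = 1, label = "t"),
                                class = "daily_profile"))
  expect_equal(w2$M10$onset_s, 9 * 3600)
  expect_equal(w2$M10$mean_value, 10)

  # exhaustive oracle incl. circular wrap, random profiles
  oracle <- function(p, hours) {
    W <- hours * 60
    means <- vapply(0:1439, function(on) {
      mean(p[((on + seq_len(W) - 1) %% 1440) + 1])
    }, numeric(1))
    list(min_on = (which.min(means) - 1) * 60, min_val = min(means),
         max_on = (which.max(means) - 1) * 60, max_val = max(means))
  }
  set.seed(41)
  for (rep in 1:5) {
    p <- rexp(1440)
    w <- locate_l5_m10(structure(list(bins = p, bin_length = 60,
                                      n_days_used = 1, label = "t"),
                                 class = "daily_profile"))
    o5 <- oracle(p, 5); o10 <- oracle(p, 10)
    expect_equal(w$L5$onset_s, o5$min_on)
    expect_equal(w$L5$mean_value, o5$min_val)
    expect_equal(w$M10$onset_s, o10$max_on)
    expect_equal(w$M10$mean_value, o10$max_val)
  }

  # degenerate all-equal profile: onset 0 for both
  flat <- locate_l5_m10(structure(list(bins = rep(2, 1440),
                                       bin_length = 60, n_days_used = 1,
                                       label = "t"),
                                  class = "daily_profile"))
  expect_equal(flat$L5$onset_s, 0)
  expect_equal(flat$M10$onset_s, 0)
  expect_equal(flat$L5$mean_value, flat$M10$mean_value)
})

test_that("relative amplitude arithmetic and degeneracies", {
  expect_equal(relative_amplitude(10, 0), 1)
  expect_equal(relative_amplitude(5, 5), 0)
  expect_equal(relative_amplitude(3, 1), 0.5)
  expect_error(relative_amplitude(0, 0), class = "actisig_config_error")
  expect_error(relative_amplitude(1, 2), class = "actisig_config_error")
})

test_that("IS and IV closed forms: periodicity, sinusoid, iid noise", {
  # exactly periodic 24 h pattern over 6 days: IS = 1
  pat <- rexp(24) + 0.1
  per <- hourly_series(rep(pat, 6))
  expect_equal(interdaily_stability(per), 1)

  # hourly sinusoid: IV -> 2 (1 - cos(2 pi / 24))
  D <- 50
  x <- sin(2 * pi * (0:(24 * D - 1)) / 24)
  iv <- intradaily_variability(hourly_series(x + 2))
  expect_equal(iv, 2 * (1 - cos(2 * pi / 24)), tolerance = 0.01)

  # iid noise: IS ~ 1/D, IV ~ 2 (Monte Carlo at D = 100)
  set.seed(99)
  D <- 100
  noise <- hourly_series(rexp(24 * D))
  expect_equal(interdaily_stability(noise), 1 / D, tolerance = 0.6)
  expect_lt(interdaily_stability(noise), 3 / D)
  expect_equal(intradaily_variability(noise), 2, tolerance = 0.1)

  expect_error(interdaily_stability(hourly_series(rep(1, 48))),
               "zero-variance", class = "actisig_config_error")
  expect_error(intradaily_variability(hourly_series(rep(1, 48))),
               "zero-variance", class = "actisig_config_error")
})

test_that("scheme admissibility: UFM rejected, signed schemes need
          rectification, activity always admissible", {
  rec <- fix_recording()$recording
  expect_error(npcra_from_signal(preprocess(rec, "UFM")),
               "gravitational", class = "actisig_config_error")
  expect_error(npcra_from_signal(preprocess(rec, "FMpost")),
               "rectified", class = "actisig_config_error")
  ok <- npcra_from_signal(rectify(preprocess(rec, "FMpost")))
  expect_s3_class(ok, "npcra_result")
  expect_error(npcra_from_signal(preprocess(rec, "UFXYZ")),
               class = "actisig_config_error")
})

test_that("RA, IS, IV and normalized window values are invariant under
          positive rescaling", {
  set.seed(6)
  v <- rexp(1440 * 3) * rep(rep(c(0.05, 1), c(450, 990)), 3)
  a <- minute_series(v)
  b <- minute_series(137.5 * v)
  ra <- npcra_from_signal(a, normalize = TRUE)
  rb <- npcra_from_signal(b, normalize = TRUE)
  expect_equal(rb$L5$mean_value, ra$L5$mean_value)
  expect_equal(rb$M10$mean_value, ra$M10$mean_value)
  expect_equal(rb$L5$onset_s, ra$L5$onset_s)
  expect_equal(rb$RA, ra$RA)
  expect_equal(rb$IS, ra$IS)
  expect_equal(rb$IV, ra$IV)
  # RA/IS/IV are scale-free even without normalization
  ra2 <- npcra_from_signal(a, normalize = FALSE)
  rb2 <- npcra_from_signal(b, normalize = FALSE)
  expect_equal(rb2$RA, ra2$RA)
  expect_equal(rb2$IS, ra2$IS)
  expect_equal(rb2$IV, ra2$IV)
})

test_that("acceleration-based NPCRA (1 s profile) agrees with epoch
          activity NPCRA on IS for the same preprocessing", {
  rec <- fix_recording()$recording
  enmo <- preprocess(rec, "ENMO")
  acc <- npcra_from_signal(enmo)
  act <- npcra_from_signal(compute_activity(enmo, "PIM"))
  expect_equal(acc$L5$length_h, 5)
  smape <- abs(acc$IS - act$IS) / ((acc$IS + act$IS) / 2) * 100
  expect_lt(smape, 5)
})
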