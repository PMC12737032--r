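# Activity metrics: forced constants, counting oracles, the SD threshold
# rule, the 35-method roster, and the scale/threshold properties behind
# the metric families.

test_that("threshold rule: SD of pooled samples, plus 1 g for UFM", {
  set.seed(4)
  noise <- rnorm(60000, 0, 0.02)
  ufm <- make_signal(1 + noise, scheme = "UFM")
  thr <- compute_threshold(ufm)
  expect_equal(thr$level, 1 + sd(1 + noise))
  expect_equal(thr$level, 1.02, tolerance = 0.005)

  enmo <- make_signal(abs(rnorm(5000, 0, 0.05)), scheme = "ENMO")
  expect_equal(compute_threshold(enmo)$level, sd(enmo$values))

  # pooled level sits between the two per-recording levels and matches
  # the direct SD of the concatenated samples (variance pooling)
  a <- make_signal(rnorm(4000, 0.1, 0.03))
  b <- make_signal(rnorm(6000, 0.3, 0.08))
  pooled <- compute_threshold(list(a, b))$level
  la <- compute_threshold(a)$level; lb <- compute_threshold(b)$level
  expect_equal(pooled, sd(c(a$values, b$values)))
  expect_gt(pooled, min(la, lb))

  expect_error(compute_threshold(list()), class = "actisig_config_error")
  expect_error(compute_threshold(list(a, make_signal(1:5, scheme = "UFNM"))),
               "mixed", class = "actisig_config_error")
})

test_that("metrics on forced inputs: constants, square wave, MAD, AI", {
  const <- make_signal(rep(0.1, 1200))                  # 2 min @ 10 Hz
  thr <- threshold_spec(0.05, "ENMO")
  expect_equal(compute_activity(const, "PIM")$values, c(6, 6))
  expect_equal(compute_activity(const, "MAD")$values, c(0, 0))
  expect_equal(compute_activity(const, "TAT", threshold = thr)$values,
               c(60, 60))
  expect_equal(compute_activity(const, "ZCM", threshold = thr)$values,
               c(0, 0))

  # 1 Hz square wave alternating 0 / 0.2 g, threshold 0.1 g
  sq <- make_signal(rep(c(rep(0, 5), rep(0.2, 5)), 120))
  thr2 <- threshold_spec(0.1, "ENMO")
  expect_equal(compute_activity(sq, "ZCM", threshold = thr2)$values,
               c(60, 60))
  expect_equal(compute_activity(sq, "TAT", threshold = thr2)$values,
               c(30, 30))

  # MAD of alternating 0 / 0.2
  alt <- make_signal(rep(c(0, 0.2), 300))
  expect_equal(compute_activity(alt, "MAD")$values, 0.1)

  # AI of a noiseless constant triaxial epoch is 0
  bundle <- preprocess(gravity_recording(120, g = c(0.6, 0, 0.8)), "UFXYZ")
  expect_equal(compute_activity(bundle, "AI")$values, c(0, 0))

  # HFEN is the epoch mean of HFMpre
  hf <- preprocess(gravity_recording(120), "HFMpre")
  expect_equal(compute_activity(hf, "HFEN")$values,
               colMeans(matrix(hf$values, nrow = 600)))
})

test_that("ZCM matches a brute-force sample loop on random epochs", {
  set.seed(77)
  for (rep in 1:5) {
    v <- abs(rnorm(1800, 0.05, 0.08))                   # 3 epochs
    sig <- make_signal(v)
    thr <- threshold_spec(stats::quantile(v, 0.6), "ENMO")
    got <- compute_activity(sig, "ZCM", threshold = thr)$values
    want <- vapply(0:2, function(e) {
      w <- v[(e * 600 + 1):((e + 1) * 600)]
      cnt <- 0
      for (j in 2:length(w)) {
        if (w[j - 1] <= thr$level && w[j] > thr$level) cnt <- cnt + 1
      }
      cnt
    }, numeric(1))
    expect_equal(got, want)
  }
})

test_that("metric preconditions are enforced", {
  sig <- make_signal(runif(600))
  expect_error(compute_activity(sig, "ZCM"), "threshold",
               class = "actisig_config_error")
  expect_error(compute_activity(sig, "HFEN"), "HFMpre",
               class = "actisig_config_error")
  bundle <- preprocess(gravity_recording(60), "UFXYZ")
  expect_error(compute_activity(bundle, "PIM"), "single-channel",
               class = "actisig_config_error")
  expect_error(compute_activity(sig, "AI"), "bundle",
               class = "actisig_config_error")
})

test_that("the roster enumerates exactly the 35 valid combinations", {
  vc <- valid_combinations()
  expect_equal(nrow(vc), 35)
  expect_equal(anyDuplicated(vc$label), 0)
  expect_true("PIM(UFNM)" %in% vc$label)
  expect_false("HFEN(FMpre)" %in% vc$label)
  expect_false("HFEN(UFM)" %in% vc$label)
  # structure: 4 metrics x 8 single-channel schemes + 2 AI + 1 HFEN
  expect_equal(sum(vc$metric %in% c("PIM", "ZCM", "TAT", "MAD")), 32)
  expect_equal(sum(vc$metric == "AI"), 2)
  expect_equal(vc$label[vc$metric == "HFEN"], "HFEN(HFMpre)")
  expect_setequal(unique(vc$family),
                  c("unfiltered_magnitude", "filtered_axes",
                    "filtered_axes_magnitude", "filtered_magnitude",
                    "raw_axes"))
  expect_true(all(vc$threshold_based == (vc$metric %in% c("ZCM", "TAT"))))
})

test_that("scale covariance: PIM/MAD scale with the signal, ZCM/TAT are
          invariant when the threshold is recomputed", {
  set.seed(15)
  v <- abs(rnorm(3000, 0.1, 0.1))
  sig <- make_signal(v); sig3 <- make_signal(3 * v)
  expect_equal(compute_activity(sig3, "PIM")$values,
               3 * compute_activity(sig, "PIM")$values)
  expect_equal(compute_activity(sig3, "MAD")$values,
               3 * compute_activity(sig, "MAD")$values)
  t1 <- compute_threshold(sig); t3 <- compute_threshold(sig3)
  expect_equal(t3$level, 3 * t1$level)
  expect_equal(compute_activity(sig3, "ZCM", threshold = t3)$values,
               compute_activity(sig, "ZCM", threshold = t1)$values)
  expect_equal(compute_activity(sig3, "TAT", threshold = t3)$values,
               compute_activity(sig, "TAT", threshold = t1)$values)
})

test_that("threshold metrics zero out far more night epochs than PIM on
          the same FMpre signal", {
  rec <- fix_recording()$recording
  sw <- fix_recording()$truth$sleep_windows
  fm <- preprocess(rec, "FMpre")
  thr <- compute_threshold(fm, basis = "per_recording")
  pim <- compute_activity(fm, "PIM")
  zcm <- compute_activity(fm, "ZCM", threshold = thr)
  tat <- compute_activity(fm, "TAT", threshold = thr)
  night <- rep(FALSE, length(pim$values))
  for (i in seq_len(nrow(sw))) {
    night <- night | (pim$epoch_start_ms >= sw[i, 1] &
                        pim$epoch_start_ms + 60000 <= sw[i, 2])
  }
  fz <- function(a) mean(a$values[night] == 0)
  expect_gt(fz(zcm), fz(pim))
  expect_gt(fz(tat), fz(pim))
})
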