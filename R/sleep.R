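# Sleep-wake scoring. Two scorers are implemented from their published
# descriptions: a trend-threshold algorithm for epoch activity data
# (centered 24 h moving-average trend, fractional threshold, two-stage
# rescoring -- the Munich actimetry approach) and a z-angle algorithm for
# raw acceleration (sustained inactivity bouts intersected with a single
# nightly sleep-period-time window). Both emit labels on a 60 s epoch
# grid so their segments are directly comparable.

new_sleep_score <- function(epoch_start_ms, labels, epoch_length,
                            algorithm, parameters) {
  segments <- labels_to_segments(epoch_start_ms, labels, epoch_length)
  structure(list(epoch_start_ms = epoch_start_ms, labels = labels,
                 epoch_length = epoch_length, segments = segments,
                 algorithm = algorithm, parameters = parameters),
            class = "sleep_score")
}

labels_to_segments <- function(starts, labels, epoch_length) {
  rt <- run_table(labels)
  rt <- rt[rt$value, , drop = FALSE]
  if (nrow(rt) == 0) {
    return(matrix(numeric(0), ncol = 2,
                  dimnames = list(NULL, c("start", "end"))))
  }
  cbind(start = starts[rt$start],
        end = starts[rt$end] + epoch_length * 1000)
}

#' @export
print.sleep_score <- function(x, ...) {
  cat(sprintf("<sleep_score> %s: %d epochs, %d segments, TST %.2f h\n",
              x$algorithm, length(x$labels), nrow(x$segments),
              total_sleep_time(x)))
  invisible(x)
}

# relabel wake runs shorter than gap_epochs that are flanked by sleep
bridge_short_wake <- function(labels, gap_epochs) {
  rt <- run_table(labels)
  for (i in seq_len(nrow(rt))) {
    if (!rt$value[i] && rt$length[i] < gap_epochs &&
        i > 1 && i < nrow(rt)) {
      labels[rt$start[i]:rt$end[i]] <- TRUE
    }
  }
  labels
}

# relabel sleep runs shorter than bout_epochs as wake
drop_short_sleep <- function(labels, bout_epochs) {
  rt <- run_table(labels)
  for (i in seq_len(nrow(rt))) {
    if (rt$value[i] && rt$length[i] < bout_epochs) {
      labels[rt$start[i]:rt$end[i]] <- FALSE
    }
  }
  labels
}

#' Trend-threshold (MASDA-style) sleep scoring of activity data
#'
#' The activity trend is a centered 24 h moving average (window truncated
#' at the series edges, never below 12 h); an epoch is provisionally
#' sleep when its value falls below `threshold_frac` of the trend. The
#' raw classification is then consolidated in two stages: wake runs
#' shorter than `gap_min` minutes flanked by sleep become sleep, then
#' sleep runs shorter than `bout_min` minutes become wake.
#'
#' @param activity an `activity_series` spanning at least 24 h
#' @param threshold_frac fraction of the trend (default 0.25, the upper
#'   end of the recommended 15--25% range)
#' @param gap_min stage-1 wake-gap bridging, minutes
#' @param bout_min stage-2 minimum sleep bout, minutes
#' @return a `sleep_score`
#' @export
masda_score <- function(activity, threshold_frac = 0.25, gap_min = 30,
                        bout_min = 30) {
  el <- activity$epoch_length
  n <- length(activity$values)
  if (n * el < 86400) stop_config("activity series must span >= 24 h")
  half <- round(12 * 3600 / el)
  trend <- rolling_mean_trunc(activity$values, half)
  raw <- activity$values < threshold_frac * trend
  lab <- bridge_short_wake(raw, round(gap_min * 60 / el))
  lab <- drop_short_sleep(lab, round(bout_min * 60 / el))
  new_sleep_score(activity$epoch_start_ms, lab, el, "masda",
                  list(threshold_frac = threshold_frac, gap_min = gap_min,
                       bout_min = bout_min, source = activity$method))
}

#' Z-angle (van Hees-style) sleep scoring of raw acceleration
#'
#' The wrist angle is atan(z / sqrt(x^2 + y^2)) in degrees on per-axis
#' 5 s rolling medians, averaged per consecutive 5 s block. Sustained
#' inactivity bouts (SIBs) are runs where successive block-angle changes
#' stay below 5 degrees for at least 5 min. Per noon-to-noon day, the
#' sleep period time (SPT) window is found from the 5-min rolling median
#' of absolute successive angle changes: blocks below `spt_threshold`
#' lasting >= 30 min are kept, gaps < 60 min between kept blocks are
#' bridged, and the longest resulting block is that day's single
#' contiguous SPT. Sleep is the intersection SIB and SPT, emitted on a
#' 60 s epoch grid (an epoch is sleep when most of its blocks are).
#'
#' @param rec a regularized `triaxial_recording` spanning >= 1
#'   noon-to-noon day
#' @param spt_threshold z-angle-change threshold of the SPT heuristic,
#'   degrees (fixed constant 0.4)
#' @param sib_angle SIB angle tolerance, degrees
#' @param sib_min_min minimum SIB duration, minutes
#' @return a `sleep_score`
#' @export
vanhees_score <- function(rec, spt_threshold = 0.4, sib_angle = 5,
                          sib_min_min = 5) {
  block_ms <- 5000
  span <- rec$time_ms[length(rec$time_ms)] - rec$time_ms[1]
  noon0 <- floor((rec$time_ms[1] - MS_PER_DAY / 2) / MS_PER_DAY)
  noon1 <- floor((rec$time_ms[length(rec$time_ms)] - MS_PER_DAY / 2) /
                   MS_PER_DAY)
  if (noon1 <= noon0) {
    stop_config("recording must span at least one noon-to-noon day")
  }
  k <- round(5 * rec$rate)
  if (k %% 2 == 0) k <- k + 1                  # runmed needs odd window
  mx <- runmed(rec$x, k); my <- runmed(rec$y, k); mz <- runmed(rec$z, k)
  ang <- atan2(mz, sqrt(mx^2 + my^2)) * 180 / pi
  blk <- floor(rec$time_ms / block_ms)
  dtb <- data.table::data.table(blk = blk, a = ang)
  bl <- dtb[, list(a = mean(a)), by = "blk"]
  nb <- nrow(bl)
  d <- c(0, abs(diff(bl$a)))                   # per-block angle change

  # SIBs: runs of small changes lasting >= sib_min_min
  quiet <- d < sib_angle
  min_blocks <- sib_min_min * 60 * 1000 / block_ms
  rt <- run_table(quiet)
  sib <- rep(FALSE, nb)
  for (i in seq_len(nrow(rt))) {
    if (rt$value[i] && rt$length[i] >= min_blocks) {
      sib[rt$start[i]:rt$end[i]] <- TRUE
    }
  }

  # SPT per noon-to-noon day
  med_k <- 5 * 60 * 1000 / block_ms            # 5 min of blocks
  if (med_k %% 2 == 0) med_k <- med_k + 1
  rolled <- runmed(d, med_k)
  below <- rolled < spt_threshold
  day <- floor((bl$blk * block_ms - MS_PER_DAY / 2) / MS_PER_DAY)
  spt <- rep(FALSE, nb)
  keep_blocks <- 30 * 60 * 1000 / block_ms     # 30 min
  gap_blocks <- 60 * 60 * 1000 / block_ms      # 60 min
  for (dd in unique(day)) {
    sel <- which(day == dd)
    bb <- below[sel]
    rt <- run_table(bb)
    kept <- rep(FALSE, length(bb))
    for (i in seq_len(nrow(rt))) {
      if (rt$value[i] && rt$length[i] >= keep_blocks) {
        kept[rt$start[i]:rt$end[i]] <- TRUE
      }
    }
    if (!any(kept)) next
    kept <- bridge_short_wake(kept, gap_blocks)  # bridge < 60 min gaps
    rt <- run_table(kept)
    rt <- rt[rt$value, , drop = FALSE]
    best <- rt[which.max(rt$length), ]
    spt[sel[best$start:best$end]] <- TRUE
  }

  sleep_blk <- sib & spt
  # emit on the 60 s epoch grid: majority of blocks
  ep <- floor(bl$blk * block_ms / 60000)
  dts <- data.table::data.table(ep = ep, s = sleep_blk)
  epl <- dts[, list(frac = mean(s), n = .N), by = "ep"]
  epl <- epl[epl$n == 60000 / block_ms, ]      # complete epochs only
  new_sleep_score(epl$ep * 60000, epl$frac > 0.5, 60, "vanhees",
                  list(spt_threshold = spt_threshold,
                       sib_angle = sib_angle, sib_min_min = sib_min_min))
}

#' Total sleep time
#'
#' @param score a `sleep_score`
#' @return summed duration of sleep segments, hours
#' @export
total_sleep_time <- function(score) {
  if (nrow(score$segments) == 0) return(0)
  sum(score$segments[, "end"] - score$segments[, "start"]) / MS_PER_HOUR
}
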