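# Nonparametric circadian rhythm analysis: the 24 h mean profile, the
# least-active 5 h (L5) and most-active 10 h (M10) circular windows, and
# the relative amplitude (RA), interdaily stability (IS) and intradaily
# variability (IV) indicators. Works on epoch-level activity series
# (60 s profile bins) and, where admissible, directly on preprocessed
# acceleration signals (1 s profile bins).

series_points <- function(x) {
  if (inherits(x, "activity_series")) {
    list(time_ms = x$epoch_start_ms, v = x$values, label = x$method)
  } else if (inherits(x, "preprocessed_signal")) {
    if (is.matrix(x$values)) {
      stop_config("profiles need a single-channel signal, not a bundle")
    }
    list(time_ms = x$time_ms, v = as.numeric(x$values), label = x$scheme)
  } else if (is.list(x) && !is.null(x$time_ms) && !is.null(x$v)) {
    list(time_ms = x$time_ms, v = x$v, label = x$label %||% "series")
  } else {
    stop_config("unsupported series type")
  }
}

# per-(day, bin) means restricted to complete midnight-to-midnight days
daily_bin_means <- function(time_ms, v, bin_s) {
  bin_ms <- bin_s * 1000
  day <- floor(time_ms / MS_PER_DAY)
  tod <- floor((time_ms %% MS_PER_DAY) / bin_ms)
  dt <- data.table::data.table(day = day, tod = tod, v = v)
  per_bin <- dt[, list(m = mean(v)), by = c("day", "tod")]
  n_bins <- 86400 / bin_s
  counts <- per_bin[, list(nb = .N), by = "day"]
  complete <- counts$day[counts$nb == n_bins]
  list(bins = per_bin[per_bin$day %in% complete, ],
       complete_days = sort(complete), n_bins = n_bins)
}

#' 24 h mean profile of a series
#'
#' Averages each time-of-day bin across all complete
#' midnight-to-midnight days. Activity series use 60 s bins by default;
#' acceleration signals 1 s bins, reflecting their higher resolution.
#'
#' @param x an `activity_series`, a single-channel
#'   `preprocessed_signal`, or a `list(time_ms, v)`
#' @param bin_length bin length in seconds; must divide 86400
#' @return object of class `daily_profile`: `bins` (mean values, length
#'   86400/bin_length), `bin_length`, `n_days_used`
#' @export
mean_profile <- function(x, bin_length = NULL) {
  p <- series_points(x)
  bin_length <- bin_length %||%
    (if (inherits(x, "preprocessed_signal")) 1 else 60)
  if (86400 %% bin_length != 0) {
    stop_config("bin_length must divide 86400")
  }
  db <- daily_bin_means(p$time_ms, p$v, bin_length)
  if (length(db$complete_days) == 0) {
    stop_config("no complete midnight-to-midnight day in series")
  }
  prof <- db$bins[, list(m = mean(m)), by = "tod"]
  bins <- numeric(db$n_bins)
  bins[prof$tod + 1] <- prof$m
  structure(list(bins = bins, bin_length = bin_length,
                 n_days_used = length(db$complete_days), label = p$label),
            class = "daily_profile")
}

#' Locate the L5 and M10 windows on a 24 h profile
#'
#' Slides 5 h and 10 h windows circularly across the profile in
#' `step` second steps (60 s regardless of bin resolution, matching
#' minute-step window placement) and designates the window with minimal
#' (L5) and maximal (M10) mean. Ties take the earliest onset.
#'
#' @param profile a `daily_profile`
#' @param step onset step in seconds (default 60)
#' @return list with `L5` and `M10`, each a window designation
#'   `list(onset_s, length_h, mean_value)`
#' @export
locate_l5_m10 <- function(profile, step = 60) {
  bl <- profile$bin_length
  if (step %% bl != 0) stop_config("step must be a multiple of bin_length")
  p <- profile$bins
  B <- length(p)
  cs <- cumsum(c(0, p, p))            # doubled for circular windows
  window_means <- function(hours) {
    W <- hours * 3600 / bl
    onsets <- seq(0, B - 1, by = step / bl)
    (cs[onsets + W + 1] - cs[onsets + 1]) / W
  }
  designate <- function(hours, which_fun) {
    mm <- window_means(hours)
    i <- which_fun(mm)                 # which.min/max take earliest tie
    onsets <- seq(0, B - 1, by = step / bl)
    list(onset_s = onsets[i] * bl, length_h = hours, mean_value = mm[i])
  }
  list(L5 = designate(5, which.min), M10 = designate(10, which.max))
}

#' Relative amplitude
#'
#' RA = (M10val - L5val) / (M10val + L5val), in [0, 1].
#' @param m10val,l5val window mean values, `m10val >= l5val >= 0`
#' @return RA
#' @export
relative_amplitude <- function(m10val, l5val) {
  if (m10val + l5val == 0) {
    stop_config("RA undefined: M10val and L5val are both zero")
  }
  if (l5val < 0 || m10val < l5val) {
    stop_config("need m10val >= l5val >= 0")
  }
  (m10val - l5val) / (m10val + l5val)
}

# hourly means on clock hours over complete days; returns the sequence
# x_i (chronological) and the 24-bin hourly profile
hourly_decomposition <- function(x) {
  p <- series_points(x)
  db <- daily_bin_means(p$time_ms, p$v, 3600)
  if (length(db$complete_days) == 0) {
    stop_config("no complete midnight-to-midnight day in series")
  }
  b <- db$bins[order(db$bins$day, db$bins$tod), ]
  list(xi = b$m, hourly_profile = b[, list(m = mean(m)), by = "tod"]$m,
       n_days = length(db$complete_days))
}

#' Interdaily stability
#'
#' IS = (sum_h (xbar_h - x_m)^2 / 24) / (sum_i (x_i - x_m)^2 / N) on
#' clock-hour means over complete days; 1 for a perfectly repeating daily
#' pattern, ~1/D for structureless noise over D days.
#'
#' @param x an `activity_series`, single-channel signal, or
#'   `list(time_ms, v)`
#' @return IS in [0, 1]
#' @export
interdaily_stability <- function(x) {
  h <- hourly_decomposition(x)
  xm <- mean(h$xi)
  denom <- mean((h$xi - xm)^2)
  if (denom == 0) stop_config("IS undefined: zero-variance series")
  mean((h$hourly_profile - xm)^2) / denom
}

#' Intradaily variability
#'
#' IV = (sum_{i>=2} (x_i - x_{i-1})^2 / (N - 1)) /
#' (sum_i (x_i - x_m)^2 / N) on hourly means; near 0 for a smooth
#' sinusoidal rhythm, ~2 for structureless noise.
#'
#' @inheritParams interdaily_stability
#' @return IV in [0, 2] (asymptotically)
#' @export
intradaily_variability <- function(x) {
  h <- hourly_decomposition(x)
  xm <- mean(h$xi)
  denom <- mean((h$xi - xm)^2)
  if (denom == 0) stop_config("IV undefined: zero-variance series")
  sum(diff(h$xi)^2) / (length(h$xi) - 1) / denom
}

NPCRA_SIGNAL_SCHEMES <- c("FMpre", "HFMpre", "UFNM", "ENMO")

#' Full NPCRA result for one signal or activity series
#'
#' For acceleration input the scheme must have the gravitational
#' component removed: FMpre, HFMpre, UFNM and ENMO are admissible
#' directly; FX, FY, FZ and FMpost only after [rectify()]; UFM is
#' rejected because its mean converges to Earth's gravitational constant
#' (1 g), degenerating every mean-based indicator. With
#' `normalize = TRUE` the series is divided by its grand mean before the
#' profile is built, removing value-range differences between pipelines
#' (RA, IS and IV are scale-invariant either way).
#'
#' @param x an `activity_series` or admissible `preprocessed_signal`
#' @param normalize divide by the grand mean first (default TRUE)
#' @param step L5/M10 onset step in seconds (default 60)
#' @return object of class `npcra_result`: `L5`, `M10` (window
#'   designations), `RA`, `IS`, `IV`, `method`, `normalized`,
#'   `n_days_used`
#' @export
npcra_from_signal <- function(x, normalize = TRUE, step = 60) {
  if (inherits(x, "preprocessed_signal")) {
    if (x$scheme == "UFM") {
      stop_config("NPCRA rejected for UFM: its mean converges to Earth's ",
                  "gravitational constant (1 g), so mean-based indicators ",
                  "degenerate")
    }
    if (x$scheme %in% c("FX", "FY", "FZ", "FMpost") && !isTRUE(x$rectified)) {
      stop_config(x$scheme, " must be rectified before NPCRA")
    }
    if (!x$scheme %in% c(NPCRA_SIGNAL_SCHEMES, "FX", "FY", "FZ", "FMpost")) {
      stop_config("NPCRA not applicable to scheme ", x$scheme)
    }
  }
  p <- series_points(x)
  if (normalize) {
    gm <- mean(p$v)
    if (gm == 0) stop_config("cannot normalize a zero-mean series")
    p$v <- p$v / gm
  }
  bl <- if (inherits(x, "preprocessed_signal")) 1 else 60
  prof <- mean_profile(list(time_ms = p$time_ms, v = p$v, label = p$label),
                       bin_length = bl)
  w <- locate_l5_m10(prof, step = step)
  structure(list(
    L5 = w$L5, M10 = w$M10,
    RA = relative_amplitude(w$M10$mean_value, w$L5$mean_value),
    IS = interdaily_stability(p),
    IV = intradaily_variability(p),
    method = p$label, normalized = normalize,
    n_days_used = prof$n_days_used), class = "npcra_result")
}

#' @export
print.npcra_result <- function(x, ...) {
  fmt_t <- function(s) sprintf("%02d:%02d", s %/% 3600, (s %% 3600) %/% 60)
  cat(sprintf(
    paste0("<npcra_result> %s (%d days%s)\n",
           "  L5  onset %s  val %.4g\n  M10 onset %s  val %.4g\n",
           "  RA %.3f  IS %.3f  IV %.3f\n"),
    x$method, x$n_days_used, if (x$normalized) ", normalized" else "",
    fmt_t(x$L5$onset_s), x$L5$mean_value,
    fmt_t(x$M10$onset_s), x$M10$mean_value, x$RA, x$IS, x$IV))
  invisible(x)
}
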