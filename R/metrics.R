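# Activity metrics: compress a preprocessed acceleration signal into one
# nonnegative value per fixed-length epoch. PIM integrates |a|, ZCM counts
# upward threshold crossings, TAT accumulates time above threshold, MAD is
# the mean absolute deviation about the epoch mean, AI pools per-axis
# epoch variances, HFEN averages the high-pass-filtered magnitude.
# The ZCM/TAT threshold follows the SD rule: the standard deviation of all
# preprocessed samples (plus 1 g for the gravity-bearing UFM scheme).

ACTIVITY_METRICS <- c("PIM", "ZCM", "TAT", "MAD", "AI", "HFEN")

#' Construct an epoch-level activity series
#'
#' @param method method label, e.g. `"PIM(FMpre)"` or a device name
#' @param epoch_start_ms epoch start timestamps (ms), contiguous grid
#' @param values nonnegative activity values
#' @param epoch_length epoch length, seconds
#' @return object of class `activity_series`
#' @export
new_activity_series <- function(method, epoch_start_ms, values,
                                epoch_length = 60) {
  if (any(values < 0)) stop_format("activity values must be >= 0")
  structure(list(method = method, epoch_start_ms = as.numeric(epoch_start_ms),
                 values = as.numeric(values), epoch_length = epoch_length),
            class = "activity_series")
}

#' @export
print.activity_series <- function(x, ...) {
  cat(sprintf("<activity_series> %s: %d epochs of %g s\n",
              x$method, length(x$values), x$epoch_length))
  invisible(x)
}

# epoch assignment: anchored at the first timestamp rounded up to a whole
# clock minute; returns epoch ids (NA outside complete epochs) and starts.
# Samples within a complete epoch are contiguous and exactly `per` many,
# so aggregation reshapes to a per x n_epochs matrix (fast column sums).
epoch_assign <- function(time_ms, rate, epoch_length) {
  ep_ms <- epoch_length * 1000
  t0 <- ceiling(time_ms[1] / 60000) * 60000
  e <- floor((time_ms - t0) / ep_ms)
  e[e < 0] <- NA
  per <- round(epoch_length * rate)
  cnt <- tabulate(e + 1L)
  full <- which(cnt == per)            # complete epochs only
  e[!(e + 1L) %in% full] <- NA
  list(epoch = e, t0 = t0, ep_ms = ep_ms, per = per,
       ok = !is.na(e), ids = sort(unique(e[!is.na(e)])))
}

epoch_aggregate <- function(v, ea) {
  colSums(matrix(v[ea$ok], nrow = ea$per))
}

#' Compute the intersection-based threshold level
#'
#' The threshold for ZCM/TAT is the standard deviation of all the
#' preprocessed acceleration samples, pooled across the provided signals;
#' for the gravity-bearing UFM scheme, 1 g is added to account for the
#' gravitational baseline.
#'
#' @param signals a `preprocessed_signal` or list of them, all one scheme
#' @param basis `"pooled"` (SD over all samples of all signals) or
#'   `"per_recording"` (signals must then be a single recording's signal)
#' @return object of class `threshold_spec` with fields `level`, `basis`,
#'   `scheme`
#' @export
compute_threshold <- function(signals, basis = c("pooled",
                                                 "per_recording")) {
  basis <- match.arg(basis)
  if (inherits(signals, "preprocessed_signal")) signals <- list(signals)
  if (length(signals) == 0) stop_config("no signals supplied")
  schemes <- unique(vapply(signals, function(s) s$scheme, character(1)))
  if (length(schemes) != 1) {
    stop_config("mixed schemes: ", paste(schemes, collapse = ", "))
  }
  if (basis == "per_recording" && length(signals) != 1) {
    stop_config("per_recording basis takes a single signal")
  }
  v <- unlist(lapply(signals, function(s) as.numeric(s$values)))
  level <- sd(v)
  if (schemes == "UFM") level <- 1 + level
  structure(list(level = level, basis = basis, scheme = schemes),
            class = "threshold_spec")
}

#' Make a threshold spec from a known level
#' @param level threshold level, g
#' @param scheme scheme it applies to
#' @param basis provenance label
#' @return a `threshold_spec`
#' @export
threshold_spec <- function(level, scheme, basis = "fixed") {
  if (level <= 0) stop_config("threshold level must be > 0")
  structure(list(level = level, basis = basis, scheme = scheme),
            class = "threshold_spec")
}

#' Aggregate a preprocessed signal into epoch-level activity
#'
#' Epochs are anchored at the first timestamp rounded up to a whole
#' minute; partial leading/trailing epochs are dropped. Per epoch:
#' PIM = sum(|v|) * dt (g s); ZCM = count of upward crossings of the
#' threshold level; TAT = time with v > threshold (s); MAD = mean |v -
#' epoch mean| (g); AI = sqrt(mean over axes of max(axis variance -
#' sigma0^2, 0)) (g, needs a 3-channel bundle); HFEN = epoch mean (g,
#' `HFMpre` scheme only).
#'
#' @param sig a `preprocessed_signal`
#' @param metric one of `r paste(ACTIVITY_METRICS, collapse = ", ")`
#' @param epoch_length epoch length, seconds (default 60)
#' @param threshold a `threshold_spec`; required for ZCM/TAT
#' @param sigma0 AI device-noise SD, g (default 0)
#' @return an `activity_series` labelled `"METRIC(SCHEME)"`
#' @export
compute_activity <- function(sig, metric, epoch_length = 60,
                             threshold = NULL, sigma0 = 0) {
  if (!metric %in% ACTIVITY_METRICS) {
    stop_config("unknown metric '", metric, "'")
  }
  if (metric %in% c("ZCM", "TAT") && is.null(threshold)) {
    stop_config(metric, " requires a threshold")
  }
  if (metric == "HFEN" && sig$scheme != "HFMpre") {
    stop_config("HFEN requires the HFMpre scheme, not ", sig$scheme)
  }
  if (metric == "AI" && !is.matrix(sig$values)) {
    stop_config("AI requires a triaxial bundle (UFXYZ or FXYZ)")
  }
  if (metric != "AI" && is.matrix(sig$values)) {
    stop_config(metric, " requires a single-channel signal")
  }
  ea <- epoch_assign(sig$time_ms, sig$rate, epoch_length)
  if (length(ea$ids) == 0) stop_config("no complete epoch in signal")
  dt <- 1 / sig$rate
  per <- round(epoch_length * sig$rate)
  vals <- switch(metric,
    PIM = epoch_aggregate(abs(sig$values), ea) * dt,
    TAT = epoch_aggregate(as.numeric(sig$values > threshold$level), ea) * dt,
    ZCM = {
      v <- sig$values
      n <- length(v)
      up <- c(FALSE, v[-1] > threshold$level & v[-n] <= threshold$level)
      same <- c(FALSE, !is.na(ea$epoch[-1]) & !is.na(ea$epoch[-n]) &
                  ea$epoch[-1] == ea$epoch[-n])
      epoch_aggregate(as.numeric(up & same), ea)
    },
    MAD = {
      m <- matrix(sig$values[ea$ok], nrow = per)
      mu <- colMeans(m)
      colMeans(abs(m - rep(mu, each = per)))
    },
    AI = {
      vs <- vapply(1:3, function(ax) {
        v <- sig$values[, ax]
        s1 <- epoch_aggregate(v, ea)
        s2 <- epoch_aggregate(v^2, ea)
        (s2 - s1^2 / per) / (per - 1)           # per-axis epoch variance
      }, numeric(length(ea$ids)))
      if (is.null(dim(vs))) vs <- matrix(vs, nrow = 1)
      sqrt(rowMeans(pmax(vs - sigma0^2, 0)))
    },
    HFEN = epoch_aggregate(sig$values, ea) / per)
  starts <- ea$t0 + ea$ids * ea$ep_ms
  method <- paste0(metric, "(", sig$scheme, ")")
  new_activity_series(method, starts, pmax(vals, 0), epoch_length)
}

#' The roster of valid metric-scheme combinations
#'
#' Thirty-five activity determination methods arise from properly pairing
#' the six metrics with the preprocessing schemes: PIM/ZCM/TAT/MAD apply
#' to every single-channel scheme without a constant mean (UFM, UFNM,
#' ENMO, FMpre, FMpost, FX, FY, FZ), AI applies to the two axis bundles,
#' and HFEN only to HFMpre. Each entry carries its preprocessing-family
#' group and whether the metric is threshold-based.
#'
#' @return data.frame with columns `label`, `metric`, `scheme`, `family`,
#'   `threshold_based`
#' @export
valid_combinations <- function() {
  family_of <- function(scheme) {
    switch(scheme,
      UFM = , UFNM = , ENMO = "unfiltered_magnitude",
      FX = , FY = , FZ = , FXYZ = "filtered_axes",
      FMpre = , HFMpre = "filtered_axes_magnitude",
      FMpost = "filtered_magnitude",
      UFXYZ = "raw_axes")
  }
  rows <- list()
  add <- function(metric, scheme) {
    rows[[length(rows) + 1]] <<- data.frame(
      label = paste0(metric, "(", scheme, ")"), metric = metric,
      scheme = scheme, family = family_of(scheme),
      threshold_based = metric %in% c("ZCM", "TAT"))
  }
  for (m in c("PIM", "ZCM", "TAT", "MAD")) {
    for (s in c("UFM", "UFNM", "ENMO", "FMpre", "FMpost")) add(m, s)
    for (s in c("FX", "FY", "FZ")) add(m, s)
  }
  add("AI", "UFXYZ"); add("AI", "FXYZ")
  add("HFEN", "HFMpre")
  do.call(rbind, rows)
}
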