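# Preprocessing schemes: how raw triaxial acceleration is turned into a
# single (or bundled) series before epoch aggregation. Naming follows the
# generalized activity-determination framework: UF* = unfiltered,
# F* = band-pass filtered (0.25-2.5 Hz, 3rd-order Butterworth),
# HF* = high-pass filtered (0.2 Hz, 4th-order Butterworth);
# M = magnitude, "pre"/"post" = filter applied before/after the magnitude.

PREPROCESS_SCHEMES <- c("UFX", "UFY", "UFZ", "UFXYZ", "UFM", "UFNM", "ENMO",
                        "FX", "FY", "FZ", "FXYZ", "FMpre", "FMpost",
                        "HFMpre")

BAND_LOW <- 0.25   # Hz, generalized band-pass
BAND_HIGH <- 2.5
BAND_ORDER <- 3
HP_CUT <- 0.2      # Hz, high-pass used by HFEN preprocessing
HP_ORDER <- 4

new_signal <- function(scheme, time_ms, values, rate,
                       gravity_present = FALSE, rectified = FALSE) {
  structure(list(scheme = scheme, time_ms = time_ms, values = values,
                 rate = rate, gravity_present = gravity_present,
                 rectified = rectified),
            class = "preprocessed_signal")
}

#' @export
print.preprocessed_signal <- function(x, ...) {
  nch <- if (is.matrix(x$values)) ncol(x$values) else 1
  cat(sprintf("<preprocessed_signal> %s%s: %d samples @ %g Hz, %d channel(s)\n",
              x$scheme, if (x$rectified) " (rectified)" else "",
              NROW(x$values), x$rate, nch))
  invisible(x)
}

band_filter <- function(rate) {
  butter_coeffs(BAND_ORDER, low = BAND_LOW, high = BAND_HIGH, fs = rate)
}

high_filter <- function(rate) {
  butter_coeffs(HP_ORDER, high = HP_CUT, fs = rate, type = "highpass")
}

#' Preprocess a recording into one of the generalized signal types
#'
#' Schemes: `UFX/UFY/UFZ` raw axes, `UFXYZ` the raw axis bundle (for AI),
#' `UFM` the Euclidean norm (gravity-bearing), `UFNM` = |UFM - 1|,
#' `ENMO` = max(UFM - 1, 0), `FX/FY/FZ` band-passed axes (`FXYZ` bundle),
#' `FMpre` = norm of the band-passed axes, `FMpost` = band-pass of UFM,
#' `HFMpre` = norm of the high-passed axes. Filters are applied causally
#' (single pass, zero initial state), emulating on-device real-time
#' processing; the initial transient is retained.
#'
#' @param rec a regularized `triaxial_recording`
#' @param scheme one of the scheme names above
#' @param zero_phase if `TRUE`, apply each filter forward and backward
#'   (zero-phase, squared magnitude response) instead of causally
#' @return a `preprocessed_signal`; `values` is a 3-column matrix for the
#'   `UFXYZ`/`FXYZ` bundles, a vector otherwise
#' @export
preprocess <- function(rec, scheme, zero_phase = FALSE) {
  if (!scheme %in% PREPROCESS_SCHEMES) {
    stop_config("unknown preprocessing scheme '", scheme, "'")
  }
  # filters start from rest relative to the first sample: both designs
  # have zero DC gain, so subtracting v[1] leaves the response unchanged
  # at steady state but removes the artificial turn-on step transient
  filt <- function(coefs, v) {
    v <- v - v[1]
    if (zero_phase) rev(apply_filter(coefs, rev(apply_filter(coefs, v))))
    else apply_filter(coefs, v)
  }
  t <- rec$time_ms; rate <- rec$rate
  ufm <- function() sqrt(rec$x^2 + rec$y^2 + rec$z^2)
  faxes <- function(coefs) cbind(filt(coefs, rec$x), filt(coefs, rec$y),
                                 filt(coefs, rec$z))
  sig <- switch(scheme,
    UFX = new_signal("UFX", t, rec$x, rate, gravity_present = TRUE),
    UFY = new_signal("UFY", t, rec$y, rate, gravity_present = TRUE),
    UFZ = new_signal("UFZ", t, rec$z, rate, gravity_present = TRUE),
    UFXYZ = new_signal("UFXYZ", t, cbind(rec$x, rec$y, rec$z), rate,
                       gravity_present = TRUE),
    UFM = new_signal("UFM", t, ufm(), rate, gravity_present = TRUE),
    UFNM = new_signal("UFNM", t, abs(ufm() - 1), rate),
    ENMO = new_signal("ENMO", t, pmax(ufm() - 1, 0), rate),
    FX = new_signal("FX", t, filt(band_filter(rate), rec$x), rate),
    FY = new_signal("FY", t, filt(band_filter(rate), rec$y), rate),
    FZ = new_signal("FZ", t, filt(band_filter(rate), rec$z), rate),
    FXYZ = new_signal("FXYZ", t, faxes(band_filter(rate)), rate),
    FMpre = {
      m <- faxes(band_filter(rate))
      new_signal("FMpre", t, sqrt(rowSums(m^2)), rate)
    },
    FMpost = new_signal("FMpost", t, filt(band_filter(rate), ufm()), rate),
    HFMpre = {
      m <- faxes(high_filter(rate))
      new_signal("HFMpre", t, sqrt(rowSums(m^2)), rate)
    })
  sig
}

#' Rectify a signed preprocessed signal
#'
#' Only `FX`, `FY`, `FZ` and `FMpost` are near-symmetric around 0 g and
#' need rectification before mean-based analyses (e.g. circadian
#' profiles); calling this on any other scheme is an error so that
#' already-nonnegative signals are never silently double-processed.
#'
#' @param sig a `preprocessed_signal`
#' @return the signal with `values = |values|` and `rectified = TRUE`
#' @export
rectify <- function(sig) {
  if (!sig$scheme %in% c("FX", "FY", "FZ", "FMpost")) {
    stop_config("rectify() applies only to FX/FY/FZ/FMpost, not ",
                sig$scheme)
  }
  if (isTRUE(sig$rectified)) stop_config("signal already rectified")
  sig$values <- abs(sig$values)
  sig$rectified <- TRUE
  sig
}
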