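# Raw/activity CSV I/O, timestamp regularization, and a sphere-fit
# auto-calibration substitute for full deterministic-error correction
# (scale and offset only; orthogonality is out of scope).

#' Construct a triaxial recording
#'
#' @param subject_id subject label
#' @param time_ms timestamps in ms since epoch, nondecreasing
#' @param x,y,z per-axis acceleration, g
#' @param rate nominal sampling rate, samples/second
#' @return object of class `triaxial_recording`
#' @export
new_recording <- function(subject_id, time_ms, x, y, z, rate) {
  n <- length(time_ms)
  if (length(x) != n || length(y) != n || length(z) != n) {
    stop_format("timestamps and axes must have equal length")
  }
  if (n == 0) stop_format("empty recording")
  if (any(!is.finite(time_ms)) || any(!is.finite(x)) ||
      any(!is.finite(y)) || any(!is.finite(z))) {
    stop_format("non-finite values in recording")
  }
  if (is.unsorted(time_ms)) stop_format("timestamps must be nondecreasing")
  structure(list(subject_id = subject_id,
                 time_ms = as.numeric(time_ms),
                 x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
                 rate = rate),
            class = "triaxial_recording")
}

#' @export
print.triaxial_recording <- function(x, ...) {
  cat(sprintf("<triaxial_recording> %s: %d samples @ %g Hz, %.2f days\n",
              x$subject_id, length(x$time_ms), x$rate,
              diff(range(x$time_ms)) / MS_PER_DAY))
  invisible(x)
}

#' Read a raw acceleration CSV
#'
#' Expects header columns `timestamp_ms,x,y,z` with a numeric body.
#'
#' @param path file path
#' @param subject_id subject label; default the file name sans extension
#' @param rate nominal rate, Hz
#' @return a `triaxial_recording`
#' @export
read_raw <- function(path, subject_id = NULL, rate = 10) {
  if (!file.exists(path)) stop_format("no such file: ", path)
  dt <- tryCatch(data.table::fread(path, header = TRUE),
                 error = function(e) stop_format("cannot parse ", path, ": ",
                                                 conditionMessage(e)))
  need <- c("timestamp_ms", "x", "y", "z")
  miss <- setdiff(need, names(dt))
  if (length(miss)) {
    stop_format("missing column(s) ", paste(miss, collapse = ", "),
                " in ", path)
  }
  if (nrow(dt) == 0) stop_format("empty file: ", path)
  for (col in need) {
    v <- dt[[col]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))))[1]
      stop_format("non-numeric value in column ", col, " at data line ",
                  if (is.na(bad)) "?" else bad, " of ", path)
    }
  }
  new_recording(subject_id %||% sub("\\.[^.]*$", "", basename(path)),
                dt$timestamp_ms, dt$x, dt$y, dt$z, rate)
}

#' Write a raw acceleration CSV
#'
#' @param rec a `triaxial_recording`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_raw <- function(rec, path) {
  data.table::fwrite(data.table::data.table(
    timestamp_ms = rec$time_ms, x = rec$x, y = rec$y, z = rec$z), path)
  invisible(path)
}

#' Read / write an epoch-level activity CSV
#'
#' Columns `epoch_start_ms,value,method`; one activity series per file.
#' @param path file path
#' @return an `activity_series`
#' @export
read_activity <- function(path) {
  dt <- data.table::fread(path, header = TRUE)
  need <- c("epoch_start_ms", "value", "method")
  miss <- setdiff(need, names(dt))
  if (length(miss)) {
    stop_format("missing column(s) ", paste(miss, collapse = ", "),
                " in ", path)
  }
  if (nrow(dt) == 0) stop_format("empty file: ", path)
  starts <- dt$epoch_start_ms
  el <- if (nrow(dt) > 1) min(diff(starts)) / 1000 else 60
  new_activity_series(dt$method[1], starts, dt$value, el)
}

#' @rdname read_activity
#' @param series an `activity_series`
#' @export
write_activity <- function(series, path) {
  data.table::fwrite(data.table::data.table(
    epoch_start_ms = series$epoch_start_ms, value = series$values,
    method = series$method), path)
  invisible(path)
}

#' Snap timestamps to an exact sampling grid
#'
#' Grid slots of 1000/rate ms are anchored at the first sample; each slot
#' takes the nearest input sample (earlier sample wins when two snap to the
#' same slot); slots left empty by gaps are filled by repeating the
#' previous sample and reported.
#'
#' @param rec a `triaxial_recording`
#' @param rate target rate, Hz (default the recording's nominal rate)
#' @return a `triaxial_recording` with attribute `"gap_report"`:
#'   `data.frame(start_ms, n_slots)` of fill events
#' @export
regularize_timestamps <- function(rec, rate = rec$rate) {
  if (rate <= 0) stop_config("rate must be > 0")
  t <- rec$time_ms
  if (length(t) == 0) stop_format("empty recording")
  step <- 1000 / rate
  t0 <- t[1]
  slot <- round((t - t0) / step)          # 0-based grid index per sample
  keep <- !duplicated(slot)               # earlier sample wins
  slot <- slot[keep]
  n_slots <- slot[length(slot)] + 1
  src <- rep(NA_integer_, n_slots)
  src[slot + 1] <- which(keep)
  missing <- is.na(src)
  # forward-fill with previous sample
  idx <- cummax(ifelse(missing, 0L, seq_len(n_slots)))
  src <- ifelse(idx == 0L, NA_integer_, src[idx])
  filled <- which(missing)
  gaps <- if (length(filled)) {
    rt <- run_table(seq_len(n_slots) %in% filled)
    rt <- rt[rt$value, , drop = FALSE]
    data.frame(start_ms = t0 + (rt$start - 1) * step, n_slots = rt$length)
  } else {
    data.frame(start_ms = numeric(0), n_slots = integer(0))
  }
  out <- new_recording(rec$subject_id, t0 + (seq_len(n_slots) - 1) * step,
                       rec$x[src], rec$y[src], rec$z[src], rate)
  attr(out, "gap_report") <- gaps
  out
}

#' Sphere-fit auto-calibration from still periods
#'
#' Finds still windows (10 s windows with per-axis SD below
#' `still_sd`), then estimates per-axis scale and offset by iteratively
#' regressing the still-window mean vectors onto their projections on the
#' unit sphere, so that still-point norms approach 1 g. If too few or too
#' one-sided still windows exist, the input is returned unchanged with a
#' warning flag. Calibration is only applied when it reduces the RMS
#' deviation of still-point norms from 1 g.
#'
#' @param rec a regularized `triaxial_recording`
#' @param still_sd stillness threshold, g (per-axis SD in a 10 s window)
#' @param min_windows minimum number of still windows required
#' @param max_iter iterations of the alternating fit
#' @return list with `recording` (calibrated or unchanged), `report`
#'   (offsets, scales, residual before/after, flag)
#' @export
sphere_calibrate <- function(rec, still_sd = 0.013, min_windows = 30,
                             max_iter = 50) {
  win <- max(2, round(10 * rec$rate))           # 10 s windows
  n <- length(rec$x)
  nw <- n %/% win
  no_op <- function(flag) {
    list(recording = rec,
         report = list(offsets = c(0, 0, 0), scales = c(1, 1, 1),
                       residual = NA_real_, residual_before = NA_real_,
                       n_still = 0L, flag = flag))
  }
  if (nw < min_windows) return(no_op("insufficient_data"))
  trim <- nw * win
  win_stats <- function(v) {
    m <- matrix(v[seq_len(trim)], nrow = win)
    list(mean = colMeans(m), sd = apply(m, 2, sd))
  }
  sx <- win_stats(rec$x); sy <- win_stats(rec$y); sz <- win_stats(rec$z)
  still <- sx$sd < still_sd & sy$sd < still_sd & sz$sd < still_sd
  pts <- cbind(sx$mean[still], sy$mean[still], sz$mean[still])
  if (nrow(pts) < min_windows) return(no_op("insufficient_still_data"))
  # orientation diversity: need spread on every axis
  if (any(apply(pts, 2, function(v) diff(range(v))) < 0.25)) {
    return(no_op("insufficient_orientation_diversity"))
  }
  resid <- function(p) sqrt(mean((sqrt(rowSums(p^2)) - 1)^2))
  r0 <- resid(pts)
  # model: observed = true * scale + offset; report the estimated
  # distortion, apply its inverse
  scale <- c(1, 1, 1); offset <- c(0, 0, 0)
  cal <- pts
  for (it in seq_len(max_iter)) {
    target <- cal / sqrt(rowSums(cal^2))       # closest unit-sphere points
    for (ax in 1:3) {
      fit <- stats::lm.fit(cbind(1, target[, ax]), pts[, ax])
      offset[ax] <- fit$coefficients[1]
      scale[ax] <- fit$coefficients[2]
    }
    if (any(scale <= 0)) return(no_op("degenerate_fit"))
    new_cal <- sweep(sweep(pts, 2, offset, "-"), 2, scale, "/")
    if (max(abs(new_cal - cal)) < 1e-10) { cal <- new_cal; break }
    cal <- new_cal
  }
  r1 <- resid(cal)
  if (!is.finite(r1) || r1 > r0) return(no_op("no_improvement"))
  out <- new_recording(rec$subject_id, rec$time_ms,
                       (rec$x - offset[1]) / scale[1],
                       (rec$y - offset[2]) / scale[2],
                       (rec$z - offset[3]) / scale[3], rec$rate)
  list(recording = out,
       report = list(offsets = offset, scales = scale, residual = r1,
                     residual_before = r0, n_still = nrow(pts),
                     flag = "ok"))
}
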