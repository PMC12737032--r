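# Butterworth IIR design (zero-pole-gain form + bilinear transform) and a
# fast causal filter built on stats::filter. No filter-design routine ships
# with the installed stack, so the design is implemented here from the
# analog prototype; coefficients agree with the standard digital designs.

# polynomial coefficients (descending powers) from roots, complex-safe
poly_from_roots <- function(r) {
  p <- complex(real = 1)
  for (ri in r) p <- c(p, 0 + 0i) - c(0 + 0i, p) * ri
  p
}

butter_prototype <- function(n) {
  m <- seq(-n + 1, n - 1, by = 2)
  list(z = complex(0), p = -exp(1i * pi * m / (2 * n)), k = 1)
}

lp2bp_zpk <- function(zpk, wo, bw) {
  z <- zpk$z; p <- zpk$p
  degree <- length(p) - length(z)
  z_lp <- z * bw / 2; p_lp <- p * bw / 2
  z_bp <- c(z_lp + sqrt(z_lp^2 - wo^2), z_lp - sqrt(z_lp^2 - wo^2))
  p_bp <- c(p_lp + sqrt(p_lp^2 - wo^2), p_lp - sqrt(p_lp^2 - wo^2))
  z_bp <- c(z_bp, rep(0 + 0i, degree))
  list(z = z_bp, p = p_bp, k = zpk$k * bw^degree)
}

lp2hp_zpk <- function(zpk, wo) {
  z <- zpk$z; p <- zpk$p
  degree <- length(p) - length(z)
  z_hp <- if (length(z)) wo / z else complex(0)
  p_hp <- wo / p
  z_hp <- c(z_hp, rep(0 + 0i, degree))
  k_hp <- zpk$k * Re(prod(-z) / prod(-p))
  list(z = z_hp, p = p_hp, k = k_hp)
}

bilinear_zpk <- function(zpk, fs) {
  z <- zpk$z; p <- zpk$p
  degree <- length(p) - length(z)
  fs2 <- 2 * fs
  z_d <- (fs2 + z) / (fs2 - z)
  p_d <- (fs2 + p) / (fs2 - p)
  z_d <- c(z_d, rep(-1 + 0i, degree))
  k_d <- zpk$k * Re(prod(fs2 - z) / prod(fs2 - p))
  list(z = z_d, p = p_d, k = k_d)
}

#' Design a digital Butterworth filter
#'
#' Returns transfer-function coefficients `b` (numerator) and `a`
#' (denominator, `a[1] = 1`) for a band-pass or high-pass Butterworth filter
#' designed by bilinear transform with frequency pre-warping.
#'
#' @param n filter order (of the analog prototype; a band-pass doubles it)
#' @param low lower cutoff in Hz (band-pass only)
#' @param high upper cutoff in Hz (band-pass) or the cutoff (high-pass)
#' @param fs sampling rate in Hz
#' @param type `"bandpass"` or `"highpass"`
#' @return list with numeric vectors `b` and `a`
#' @examples
#' bp <- butter_coeffs(3, low = 0.25, high = 2.5, fs = 10)
#' @export
butter_coeffs <- function(n, low = NULL, high, fs,
                          type = c("bandpass", "highpass")) {
  type <- match.arg(type)
  nyq <- fs / 2
  if (high >= nyq) {
    stop_config("cutoff ", high, " Hz is at or above Nyquist (", nyq,
                " Hz) for rate ", fs, " Hz")
  }
  if (type == "bandpass") {
    if (is.null(low) || low <= 0 || low >= high) {
      stop_config("band-pass needs 0 < low < high")
    }
    w <- 2 * fs * tan(pi * c(low, high) / fs)
    zpk <- lp2bp_zpk(butter_prototype(n), wo = sqrt(w[1] * w[2]),
                     bw = w[2] - w[1])
  } else {
    w <- 2 * fs * tan(pi * high / fs)
    zpk <- lp2hp_zpk(butter_prototype(n), w)
  }
  zpk <- bilinear_zpk(zpk, fs)
  b <- Re(poly_from_roots(zpk$z)) * zpk$k
  a <- Re(poly_from_roots(zpk$p))
  list(b = b, a = a)
}

#' Apply an IIR filter causally (single pass, zero initial conditions)
#'
#' Direct-form filtering y = b(z)/a(z) x implemented via `stats::filter`:
#' the moving-average part as a one-sided convolution, the autoregressive
#' part as a recursive filter. Matches sample-by-sample direct-form output
#' from rest.
#'
#' @param coefs list with `b`, `a` as from [butter_coeffs()]
#' @param x numeric vector
#' @return filtered numeric vector, same length
#' @export
apply_filter <- function(coefs, x) {
  b <- coefs$b; a <- coefs$a
  nb <- length(b)
  xp <- c(rep(0, nb - 1), as.numeric(x))
  v <- stats::filter(xp, b, method = "convolution", sides = 1)
  v <- as.numeric(v)[nb:length(xp)]
  if (length(a) > 1) {
    v <- as.numeric(stats::filter(v, -a[-1] / a[1], method = "recursive"))
  }
  v / a[1]
}

#' Frequency response magnitude of a digital filter
#'
#' Evaluates |H(e^{i 2 pi f / fs})| analytically from the transfer-function
#' polynomials; used as an independent oracle for steady-state sinusoid
#' amplitude after filtering.
#'
#' @param coefs list with `b`, `a`
#' @param f frequency in Hz (vectorized)
#' @param fs sampling rate in Hz
#' @return |H(f)|, numeric
#' @export
filter_gain <- function(coefs, f, fs) {
  w <- exp(-1i * 2 * pi * f / fs)
  num <- vapply(w, function(wi) sum(coefs$b * wi^(seq_along(coefs$b) - 1)),
                complex(1))
  den <- vapply(w, function(wi) sum(coefs$a * wi^(seq_along(coefs$a) - 1)),
                complex(1))
  Mod(num / den)
}
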