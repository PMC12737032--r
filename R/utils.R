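#' @importFrom stats sd var runmed median rnorm runif rbinom rpois rexp
#' @importFrom stats hclust dist as.dist cutree binom.test wilcox.test
#' @importFrom utils head tail
NULL

.datatable.aware <- TRUE

`%||%` <- function(a, b) if (is.null(a)) b else a

MS_PER_DAY <- 86400000
MS_PER_HOUR <- 3600000

stop_config <- function(...) {
  stop(structure(class = c("actisig_config_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_format <- function(...) {
  stop(structure(class = c("actisig_format_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

#' Derive a child RNG seed from a parent seed
#'
#' Deterministic splitting of one integer seed into per-subject seeds,
#' kept below 2^31 so the result is a valid R integer seed.
#' @param seed parent seed (integer)
#' @param index child index (1-based)
#' @return integer seed
#' @keywords internal
derive_seed <- function(seed, index) {
  # simple LCG-style mix; avoids collisions for small indices
  as.integer((as.numeric(seed) * 48271 + index * 9973) %% 2147483629L)
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# ---- interval arithmetic on [start, end) sets, units = ms ------------------

# normalize an interval set: matrix with columns start,end; merged, sorted
normalize_intervals <- function(iv) {
  if (is.null(iv) || length(iv) == 0) {
    return(matrix(numeric(0), ncol = 2,
                  dimnames = list(NULL, c("start", "end"))))
  }
  iv <- matrix(as.numeric(iv), ncol = 2,
               dimnames = list(NULL, c("start", "end")))
  iv <- iv[iv[, 2] > iv[, 1], , drop = FALSE]
  if (nrow(iv) == 0) return(iv)
  iv <- iv[order(iv[, 1]), , drop = FALSE]
  out <- iv[1, , drop = FALSE]
  if (nrow(iv) > 1) {
    for (i in 2:nrow(iv)) {
      if (iv[i, 1] <= out[nrow(out), 2]) {
        out[nrow(out), 2] <- max(out[nrow(out), 2], iv[i, 2])
      } else {
        out <- rbind(out, iv[i, , drop = FALSE])
      }
    }
  }
  out
}

interval_total_length <- function(iv) {
  iv <- normalize_intervals(iv)
  if (nrow(iv) == 0) return(0)
  sum(iv[, 2] - iv[, 1])
}

interval_intersection <- function(a, b) {
  a <- normalize_intervals(a); b <- normalize_intervals(b)
  if (nrow(a) == 0 || nrow(b) == 0) {
    return(normalize_intervals(NULL))
  }
  out <- NULL
  for (i in seq_len(nrow(a))) {
    lo <- pmax(a[i, 1], b[, 1]); hi <- pmin(a[i, 2], b[, 2])
    keep <- hi > lo
    if (any(keep)) out <- rbind(out, cbind(lo[keep], hi[keep]))
  }
  normalize_intervals(out)
}

interval_union_length <- function(a, b) {
  interval_total_length(rbind(normalize_intervals(a), normalize_intervals(b)))
}

# seconds-since-midnight parser for "HH:MM" clock strings (or numeric seconds)
parse_clock <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  parts <- strsplit(x, ":", fixed = TRUE)[[1]]
  if (length(parts) < 2) stop_config("cannot parse clock time '", x, "'")
  3600 * as.numeric(parts[1]) + 60 * as.numeric(parts[2]) +
    if (length(parts) >= 3) as.numeric(parts[3]) else 0
}

# centred moving mean with truncated edges, window = 2*half+1 samples
rolling_mean_trunc <- function(x, half) {
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

# label runs: returns data.frame(value, length, start_idx, end_idx)
run_table <- function(x) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  data.frame(value = r$values, length = r$lengths,
             start = ends - r$lengths + 1L, end = ends)
}
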