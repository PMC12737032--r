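# Similarity matrices across signal-processing pipelines and their
# hierarchical organization. Scalar indicators compare via SMAPE,
# L5/M10 windows via circular overlap, sleep segment sets via the
# Jaccard index (IoU); matrices convert to dissimilarities and cluster
# with complete linkage on Euclidean distances between matrix rows.

new_similarity_matrix <- function(m, metric) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  structure(m, metric = metric, class = c("similarity_matrix", "matrix"))
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("<similarity_matrix> %s, %d pipelines\n", attr(x, "metric"),
              nrow(x)))
  print(round(unclass(x), 1))
  invisible(x)
}

#' SMAPE similarity matrix for a scalar indicator
#'
#' Cell (i, j) is the mean over subjects of
#' |Vsi - Vsj| / ((Vsi + Vsj) / 2) * 100, the symmetric mean absolute
#' percentage error (0--200%).
#'
#' @param table numeric matrix: rows = subjects, columns = pipelines
#'   (column names label the pipelines)
#' @return a `similarity_matrix` (`metric = "SMAPE"`, diagonal 0)
#' @export
smape_matrix <- function(table) {
  table <- as.matrix(table)
  k <- ncol(table)
  labs <- colnames(table) %||% paste0("P", seq_len(k))
  m <- matrix(0, k, k, dimnames = list(labs, labs))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i == j) next
      vi <- table[, i]; vj <- table[, j]
      zero <- vi + vj == 0
      if (any(zero)) {
        s <- which(zero)[1]
        stop_config("SMAPE undefined: V=0 for both pipelines at subject ",
                    s, ", pair (", labs[i], ", ", labs[j], ")")
      }
      m[i, j] <- mean(abs(vi - vj) / ((vi + vj) / 2)) * 100
    }
  }
  new_similarity_matrix(m, "SMAPE")
}

# circular intersection (seconds) of two windows of length w_s on a 24 h
# circle, given onsets in seconds-of-day
circular_window_overlap <- function(on1, on2, w_s) {
  d <- abs(on1 - on2) %% 86400
  d <- pmin(d, 86400 - d)
  pmax(0, w_s - d) + pmax(0, w_s - (86400 - d))
}

#' Window-overlap similarity matrix for L5/M10 onsets
#'
#' Cell (i, j) is the mean over subjects of the circular intersection of
#' the two designated windows divided by the window length, as a
#' percentage (0--100%).
#'
#' @param onsets numeric matrix of window onsets in seconds-of-day:
#'   rows = subjects, columns = pipelines
#' @param length_h window length in hours (5 for L5, 10 for M10); all
#'   windows must share it
#' @return a `similarity_matrix` (`metric = "overlap"`, diagonal 100)
#' @export
overlap_matrix <- function(onsets, length_h) {
  onsets <- as.matrix(onsets)
  if (!length_h %in% c(5, 10)) {
    stop_config("window length must be 5 or 10 hours")
  }
  w_s <- length_h * 3600
  k <- ncol(onsets)
  labs <- colnames(onsets) %||% paste0("P", seq_len(k))
  m <- matrix(100, k, k, dimnames = list(labs, labs))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i == j) next
      ov <- circular_window_overlap(onsets[, i], onsets[, j], w_s)
      m[i, j] <- mean(ov / w_s) * 100
    }
  }
  new_similarity_matrix(m, "overlap")
}

#' Jaccard (IoU) similarity matrix for sleep segment sets
#'
#' Cell (i, j) is the mean over subjects of |S_i intersect S_j| /
#' |S_i union S_j| * 100 with interval-arithmetic measures.
#'
#' @param segment_sets named list over pipelines; each element a list
#'   over subjects of interval matrices (columns start, end, ms)
#' @return a `similarity_matrix` (`metric = "IoU"`, diagonal 100)
#' @export
iou_matrix <- function(segment_sets) {
  k <- length(segment_sets)
  labs <- names(segment_sets) %||% paste0("P", seq_len(k))
  ns <- unique(vapply(segment_sets, length, integer(1)))
  if (length(ns) != 1) stop_config("ragged segment table")
  m <- matrix(100, k, k, dimnames = list(labs, labs))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i >= j) next
      vals <- vapply(seq_len(ns), function(s) {
        a <- segment_sets[[i]][[s]]; b <- segment_sets[[j]][[s]]
        u <- interval_union_length(a, b)
        if (u == 0) {
          stop_config("IoU undefined: both segment sets empty at subject ",
                      s, ", pair (", labs[i], ", ", labs[j], ")")
        }
        interval_total_length(interval_intersection(a, b)) / u
      }, numeric(1))
      m[i, j] <- m[j, i] <- mean(vals) * 100
    }
  }
  new_similarity_matrix(m, "IoU")
}

#' Complete-linkage dendrogram of a similarity matrix
#'
#' The matrix is converted to dissimilarities (SMAPE: M/200; overlap and
#' IoU: 1 - M/100), min-max rescaled to [0, 1] over the off-diagonal
#' range, and each pipeline's feature vector is its row of the rescaled
#' matrix; pairwise Euclidean distances between rows feed
#' complete-linkage agglomeration.
#'
#' @param simmat a `similarity_matrix` with >= 2 pipelines
#' @return list with `hclust` (the tree), `dissimilarity` (the rescaled
#'   matrix) and `newick` (Newick string with merge-height branch
#'   lengths)
#' @export
pipeline_dendrogram <- function(simmat) {
  if (nrow(simmat) < 2) stop_config("need >= 2 pipelines")
  metric <- attr(simmat, "metric")
  m <- unclass(simmat)
  d <- switch(metric,
              SMAPE = m / 200,
              overlap = 1 - m / 100,
              IoU = 1 - m / 100,
              stop_config("unknown matrix metric ", metric))
  off <- d[row(d) != col(d)]
  rng <- range(off)
  if (diff(rng) > 0) {
    d <- (d - rng[1]) / diff(rng)
    diag(d) <- 0
    d[d < 0] <- 0
  }
  hc <- hclust(dist(d), method = "complete")
  phy <- ape::as.phylo(hc)
  list(hclust = hc, dissimilarity = d,
       newick = ape::write.tree(phy))
}

#' Pearson-correlation similarity matrix (cross-checking aid)
#'
#' Mean across subjects is not defined here; instead the correlation is
#' computed between whole epoch-value columns of a subjects-by-pipeline
#' value table stacked over subjects. Exposed for comparing pipeline
#' families against correlation structure.
#'
#' @param value_columns named list of equal-length numeric vectors, one
#'   per pipeline (stacked epoch values)
#' @return correlation matrix
#' @export
pearson_matrix <- function(value_columns) {
  stats::cor(do.call(cbind, value_columns))
}
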