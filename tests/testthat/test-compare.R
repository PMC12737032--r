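# Similarity matrices and dendrograms: identities, forced cases,
# brute-force oracles, permutation invariance.

test_that("SMAPE matrix: identities, forced cell, brute-force oracle,
          undefined cells", {
  tab <- cbind(A = c(1, 2, 3), B = c(1, 2, 3))
  m <- smape_matrix(tab)
  expect_equal(unclass(m), matrix(0, 2, 2, dimnames = list(c("A", "B"),
                                                           c("A", "B"))),
               ignore_attr = TRUE)

  one <- smape_matrix(cbind(i = 3, j = 1))
  expect_equal(one["i", "j"], 100)

  set.seed(12)
  tab <- matrix(rexp(5 * 4), 5, 4,
                dimnames = list(NULL, paste0("P", 1:4)))
  m <- smape_matrix(tab)
  for (i in 1:4) {
    for (j in 1:4) {
      want <- 0
      if (i != j) {
        acc <- 0
        for (s in 1:5) {
          acc <- acc + abs(tab[s, i] - tab[s, j]) /
            ((tab[s, i] + tab[s, j]) / 2)
        }
        want <- acc / 5 * 100
      }
      expect_equal(unname(m[i, j]), unname(want))
    }
  }
  expect_true(all(m >= 0 & m <= 200))
  expect_equal(unclass(m), t(unclass(m)))

  expect_error(smape_matrix(cbind(a = c(0, 1), b = c(0, 2))),
               "subject 1", class = "actisig_config_error")
})

test_that("window overlap matrix handles circular intersection", {
  on <- cbind(a = 3600, b = 3600 + 2.5 * 3600)     # 01:00 vs 03:30
  expect_equal(overlap_matrix(on, 5)["a", "b"], 50)

  # 22:00-03:00 vs 00:00-05:00: 3 h circular intersection
  on2 <- cbind(a = 22 * 3600, b = 0)
  expect_equal(overlap_matrix(on2, 5)["a", "b"], 60)

  idt <- overlap_matrix(cbind(a = c(100, 7200), b = c(100, 7200)), 10)
  expect_true(all(idt == 100))

  # wrap-around symmetry: onsets 23:00 and 01:00 overlap 3 h of 5 h
  on3 <- cbind(a = 23 * 3600, b = 1 * 3600)
  expect_equal(overlap_matrix(on3, 5)["a", "b"], 60)

  expect_error(overlap_matrix(on, 7), class = "actisig_config_error")
})

test_that("IoU matrix: identities, disjoint, half-overlap, undefined", {
  hours <- function(a, b) cbind(start = a * 3600000, end = b * 3600000)
  segs <- list(
    A = list(hours(0, 8), hours(2, 6)),
    B = list(hours(0, 8), hours(2, 6)),
    C = list(hours(10, 18), hours(12, 16)))
  m <- iou_matrix(segs)
  expect_equal(m["A", "B"], 100)
  expect_equal(m["A", "C"], 0)

  # equal-length single intervals overlapping half: IoU = 1/3
  half <- list(A = list(hours(0, 4)), B = list(hours(2, 6)))
  expect_equal(iou_matrix(half)["A", "B"], 100 / 3)

  none <- list(A = list(hours(0, 0)), B = list(hours(0, 0)))
  expect_error(iou_matrix(none), "both segment sets empty",
               class = "actisig_config_error")

  # multi-interval sets against a hand-computed value
  a <- rbind(hours(0, 2), hours(5, 7))         # 4 h total
  b <- rbind(hours(1, 6))                      # 5 h total
  # intersection: (1,2) + (5,6) = 2 h; union: (0,7) = 7 h
  two <- list(A = list(a), B = list(b))
  expect_equal(iou_matrix(two)["A", "B"], 2 / 7 * 100)
})

test_that("dendrogram conversion, topology, Newick export, and
          permutation invariance", {
  m <- new_sim <- matrix(c(0, 10, 10, 0), 2, 2,
                         dimnames = list(c("a", "b"), c("a", "b")))
  sm <- structure(m, metric = "SMAPE",
                  class = c("similarity_matrix", "matrix"))
  d <- pipeline_dendrogram(sm)
  expect_equal(length(d$hclust$height), 1)
  expect_match(d$newick, "^\\(")

  # three labels, (a, b) nearly identical, c far: (a, b) merge first
  tab <- cbind(a = c(1, 2, 3, 4), b = c(1.01, 2.02, 3.01, 4.0),
               c = c(9, 8, 9, 8))
  sm3 <- smape_matrix(tab)
  d3 <- pipeline_dendrogram(sm3)
  first_pair <- -d3$hclust$merge[1, ]
  expect_true(all(first_pair > 0))
  expect_setequal(d3$hclust$labels[first_pair], c("a", "b"))
  grp <- cutree(d3$hclust, 2)
  expect_equal(grp[["a"]], grp[["b"]])
  expect_false(grp[["a"]] == grp[["c"]])

  # permuting pipelines relabels without changing topology
  perm <- c("c", "a", "b")
  dp <- pipeline_dendrogram(smape_matrix(tab[, perm]))
  gp <- cutree(dp$hclust, 2)
  expect_equal(gp[["a"]], gp[["b"]])
  expect_false(gp[["a"]] == gp[["c"]])

  expect_error(pipeline_dendrogram(smape_matrix(cbind(a = 1:3))),
               class = "actisig_config_error")
})
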