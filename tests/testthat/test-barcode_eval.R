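make_dist <- function(values, ids) {
  n <- length(ids)
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  D[upper.tri(D)] <- values
  D + t(D)
}

test_that("pair labeling follows the taxonomy and conserves pair count", {
  ids <- c("a1", "a2", "b1", "b2")
  tax <- c(a1 = "A", a2 = "A", b1 = "B", b2 = "B")
  D <- random_dist(4, seed = 1)
  dimnames(D) <- list(ids, ids)
  pairs <- label_pairs(D, tax)
  expect_identical(nrow(pairs), 6L)
  expect_identical(sum(pairs$label == "intra"), 2L)
  expect_identical(sum(pairs$label == "inter"), 4L)

  single <- label_pairs(D, stats::setNames(rep("A", 4), ids))
  expect_true(all(single$label == "intra"))

  D[1, 2] <- D[2, 1] <- NA
  expect_identical(nrow(label_pairs(D, tax)), 5L)
  expect_error(label_pairs(D, tax[-1]), "a1")
})

test_that("range overlap reproduces the published barcode-gap percentages", {
  expect_equal(round(overlap_percentage(c(0, 0.9), c(0, 2.2)), 1), 40.9)
  expect_equal(round(overlap_percentage(c(0, 5.9), c(1.9, 83.7)), 1), 4.8)
  expect_equal(round(overlap_percentage(c(0, 3.6), c(2.3, 44.5)), 1), 2.9)
  expect_equal(round(overlap_percentage(c(0, 5.1), c(4.2, 59.6)), 1), 1.5)
  # disjoint ranges: perfect barcode gap
  expect_equal(overlap_percentage(c(0, 1), c(2, 5)), 0)
  # invariant to swapping which class is wider
  expect_equal(overlap_percentage(c(1.9, 83.7), c(0, 5.9)),
               overlap_percentage(c(0, 5.9), c(1.9, 83.7)))
  expect_error(overlap_percentage(c(1, 1), c(1, 1)), "zero")
})

test_that("gap-midpoint threshold is the mean of the bounding distances", {
  pairs <- data.frame(distance = c(0.01, 0.036, 0.023, 0.05),
                      label = factor(c("intra", "intra", "inter", "inter"),
                                     levels = c("intra", "inter")))
  expect_equal(overlap_minimizing_threshold(pairs), (0.036 + 0.023) / 2)
  expect_error(
    overlap_minimizing_threshold(pairs[pairs$label == "intra", ]),
    "interspecific")
})

test_that("AUC matches exhaustive pair enumeration and the trapezoid sweep", {
  mk <- function(intra, inter) {
    data.frame(distance = c(intra, inter),
               label = factor(rep(c("intra", "inter"),
                                  c(length(intra), length(inter))),
                              levels = c("intra", "inter")))
  }
  sep <- roc_analysis(mk(c(1, 2), c(5, 6)))
  expect_equal(sep$auc, 1)
  expect_equal(sep$J, 1)
  expect_true(sep$youden_threshold > 2 && sep$youden_threshold < 5)

  ident <- roc_analysis(mk(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(ident$auc, 0.5)

  tied <- roc_analysis(mk(c(1, 2, 3), c(2, 3, 4)))
  expect_equal(tied$auc, 7 / 9)  # exhaustive: 6 wins + 2 half-ties of 9

  set.seed(21)
  for (i in 1:20) {
    intra <- round(runif(15, 0, 0.05), 3)
    inter <- round(runif(25, 0.01, 0.2), 3)
    r <- roc_analysis(mk(intra, inter))
    expect_equal(r$auc, trapezoid_auc(intra, inter), tolerance = 1e-9)
    expect_gte(r$youden_threshold, -Inf)
    expect_true(r$youden_threshold <= max(c(intra, inter)))
  }
})

test_that("DeLong confidence interval agrees with pROC", {
  set.seed(33)
  intra <- runif(30, 0, 0.06)
  inter <- runif(40, 0.02, 0.2)
  pairs <- data.frame(distance = c(intra, inter),
                      label = factor(rep(c("intra", "inter"), c(30, 40)),
                                     levels = c("intra", "inter")))
  r <- roc_analysis(pairs)
  proc <- pROC::roc(response = c(rep(0, 30), rep(1, 40)),
                    predictor = c(intra, inter), quiet = TRUE,
                    direction = "<")
  expect_equal(r$auc, as.numeric(pROC::auc(proc)), tolerance = 1e-9)
  ci <- as.numeric(pROC::ci.auc(proc, method = "delong"))
  expect_equal(r$auc_ci_95[1], ci[1], tolerance = 1e-6)
  expect_equal(r$auc_ci_95[2], ci[3], tolerance = 1e-6)
})

test_that("identification efficiency applies the local barcode-gap rule", {
  # 4 perfectly gapped species
  sim <- simulate_sequences(4, 3, 500, 0.005, 0.1, seed = 2)
  D <- k2p_matrix(sim$alignment)
  expect_equal(identification_efficiency(D, sim$taxonomy), 100)

  # 11 of 14 species pass the gap: 78.6%
  ids <- sprintf("s%02d", 1:14)
  tax <- stats::setNames(paste0("sp", 1:14), ids)
  D2 <- matrix(0.10, 14, 14, dimnames = list(ids, ids))
  diag(D2) <- 0
  # make species 1-3 fail: their nearest neighbour sits at distance 0
  D2[1, 2] <- D2[2, 1] <- 0
  D2[2, 3] <- D2[3, 2] <- 0
  D2[1, 3] <- D2[3, 1] <- 0
  expect_equal(round(identification_efficiency(D2, tax), 1), 78.6)

  # two mutually overlapping species -> 0%
  ids3 <- c("x1", "x2", "y1", "y2")
  tax3 <- c(x1 = "X", x2 = "X", y1 = "Y", y2 = "Y")
  D3 <- make_dist(c(0.05, 0.01, 0.03, 0.03, 0.01, 0.05), ids3)
  expect_equal(identification_efficiency(D3, tax3), 0)
})

test_that("barcode report composes and matches independent recomputation", {
  sim <- simulate_sequences(4, 3, 800, 0.01, 0.12, seed = 8)
  rep <- barcode_report(sim$alignment, sim$taxonomy)
  D <- k2p_matrix(sim$alignment)
  pairs <- label_pairs(D, sim$taxonomy)
  intra <- pairs$distance[pairs$label == "intra"]
  inter <- pairs$distance[pairs$label == "inter"]
  expect_equal(rep$intra_range, round(range(intra) * 100, 1))
  expect_equal(rep$inter_range, round(range(inter) * 100, 1))
  expect_equal(rep$overlap_pct,
               round(overlap_percentage(round(range(intra) * 100, 1),
                                        round(range(inter) * 100, 1)), 1))
  expect_equal(rep$efficiency_pct, 100)
  expect_equal(rep$overlap_pct, 0)
  expect_equal(rep$threshold_gap_midpoint, (max(intra) + min(inter)) / 2)
  expect_equal(rep$roc$auc, 1)

  # single species: inter class empty -> error surfaced
  expect_error(barcode_report(sim$alignment,
                              stats::setNames(rep("one", 12),
                                              names(sim$taxonomy))),
               "interspecific")
})

test_that("distribution overlap is 0 for disjoint and ~1 for identical data", {
  mk <- function(intra, inter) {
    data.frame(distance = c(intra, inter),
               label = factor(rep(c("intra", "inter"),
                                  c(length(intra), length(inter))),
                              levels = c("intra", "inter")))
  }
  expect_equal(distribution_overlap(mk(runif(50, 0, 0.3), runif(50, 0.7, 1))), 0)
  set.seed(5)
  x <- runif(200)
  expect_gt(distribution_overlap(mk(x, x)), 0.99)
})
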