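toy_traits <- function() {
  df <- data.frame(
    shape = c("ellipsoidal", "ellipsoidal, ovoid", "spherical", "spherical"),
    pyrenoid = c("present", "present", "absent", "absent"),
    size = c("small", "small", "large", NA),
    stringsAsFactors = FALSE
  )
  rownames(df) <- c("s1", "s2", "s3", "s4")
  df
}

test_that("trait encoding expands states and honours the completeness filter", {
  bm <- encode_traits(toy_traits(), min_completeness = 0)
  # 3-state trait, strain in one state -> one set bit in that block
  shape_cols <- names(attr(bm, "trait"))[attr(bm, "trait") == "shape"]
  expect_identical(length(shape_cols), 3L)
  expect_equal(sum(bm["s1", shape_cols]), 1)
  # polymorphic cell sets both indicators
  expect_equal(sum(bm["s2", shape_cols]), 2)
  # unknown cell -> whole trait block NA
  size_cols <- names(attr(bm, "trait"))[attr(bm, "trait") == "size"]
  expect_true(all(is.na(bm["s4", size_cols])))

  # strain with 7 of 10 traits known (70%) excluded at the 80% filter
  df <- as.data.frame(matrix("x", 2, 10), stringsAsFactors = FALSE)
  rownames(df) <- c("full", "partial")
  df[2, 1:3] <- NA
  bm2 <- encode_traits(df, min_completeness = 0.8)
  expect_identical(rownames(bm2), "full")
  expect_identical(attr(bm2, "dropped_strains"), "partial")
  df[1, 1:3] <- NA
  expect_error(encode_traits(df), "completeness")
})

test_that("Jaccard distances follow the shared-set-bit rule with masking", {
  bm <- encode_traits(toy_traits(), min_completeness = 0)
  J <- jaccard_matrix(bm)
  expect_true(all(diag(J) == 0))
  expect_equal(J, t(J))
  expect_true(all(J >= 0 & J <= 1, na.rm = TRUE))
  # identical determined profiles -> 0
  expect_equal(J["s3", "s4"], 0)

  # hand count: bits {1,0,1} vs {0,1,1} -> 1 - 1/3
  m <- matrix(c(1, 0, 1, 0, 1, 1), 2, 3, byrow = TRUE,
              dimnames = list(c("a", "b"), c("t1=x", "t1=y", "t2=z")))
  attr(m, "trait") <- c(`t1=x` = "t1", `t1=y` = "t1", `t2=z` = "t2")
  expect_equal(jaccard_matrix(m)["a", "b"], 1 - 1 / 3)

  # pair sharing no determined traits is masked
  m2 <- matrix(c(1, NA, NA, 1), 2, 2,
               dimnames = list(c("a", "b"), c("t1=x", "t2=y")))
  attr(m2, "trait") <- c(`t1=x` = "t1", `t2=y` = "t2")
  expect_true(is.na(jaccard_matrix(m2)["a", "b"]))
})

test_that("Mantel statistic and permutation p behave as designed", {
  D <- random_dist(6, seed = 2)
  self <- mantel_test(D, D, n_perm = 99, seed = 1)
  expect_equal(self$r, 1)
  expect_lte(self$p, 0.05)

  # r is invariant under joint relabeling of both matrices
  p <- sample(6)
  expect_equal(mantel_test(D[p, p], random_dist(6, seed = 3)[p, p],
                           n_perm = 9, seed = 1)$r,
               mantel_test(D, random_dist(6, seed = 3),
                           n_perm = 9, seed = 1)$r)

  expect_error(mantel_test(D, matrix(0, 6, 6)), "degenerate")

  # agreement with vegan's Mantel statistic
  d2 <- random_dist(6, seed = 4)
  expect_equal(mantel_test(D, d2, n_perm = 9, seed = 1)$r,
               unname(vegan::mantel(as.dist(D), as.dist(d2),
                                    permutations = 9)$statistic))
})

test_that("4-strain Mantel permutation p matches full enumeration", {
  d1 <- random_dist(4, seed = 11)
  d2 <- random_dist(4, seed = 12)
  exact <- exact_mantel_p(d1, d2)
  est <- mantel_test(d1, d2, n_perm = 10000, seed = 5)$p
  expect_lt(abs(est - exact), 0.02)
})

test_that("per-trait Mantel flags structure-carrying traits", {
  sim <- simulate_trait_matrix(14, 10, 3, missing_frac = 0, noise = 0,
                               seed = 20)
  bm <- encode_traits(sim$traits)
  res <- mantel_per_trait(bm, "trait_01", n_perm = 999, seed = 1)
  expect_true(res$r > 0)
  expect_lte(res$p, 0.05)
  expect_error(mantel_per_trait(bm, "no_such_trait"), "unknown trait")
})

test_that("UPGMA matches hand arithmetic and the naive O(n^3) oracle", {
  ids <- c("A", "B", "C")
  D <- matrix(c(0, 0.2, 0.6, 0.2, 0, 0.6, 0.6, 0.6, 0), 3, 3,
              dimnames = list(ids, ids))
  tree <- upgma_tree(D)
  coph <- ape::cophenetic.phylo(tree)
  expect_equal(coph["A", "B"], 0.2)  # joined at height 0.1
  expect_equal(coph["A", "C"], 0.6)  # C joins at height 0.3

  for (seed in 1:50) {
    Dr <- random_dist(8, seed = 200 + seed)
    coph_ours <- ape::cophenetic.phylo(upgma_tree(Dr))[rownames(Dr), rownames(Dr)]
    expect_equal(coph_ours, naive_upgma_cophenetic(Dr), tolerance = 1e-9)
  }

  Dna <- D
  Dna["A", "B"] <- Dna["B", "A"] <- NA
  expect_error(upgma_tree(Dna), "complete")
})

test_that("UPGMA trees are ultrametric", {
  for (seed in 1:10) {
    D <- random_dist(7, seed = 300 + seed)
    coph <- ape::cophenetic.phylo(upgma_tree(D))
    trips <- utils::combn(rownames(D), 3)
    for (k in seq_len(ncol(trips))) {
      d3 <- sort(c(coph[trips[1, k], trips[2, k]],
                   coph[trips[1, k], trips[3, k]],
                   coph[trips[2, k], trips[3, k]]))
      expect_lt(abs(d3[2] - d3[3]), 1e-9)
    }
  }
})

test_that("PCoA reproduces geometry", {
  # 3 equidistant points form an equilateral triangle
  ids <- c("a", "b", "c")
  D <- matrix(1, 3, 3, dimnames = list(ids, ids))
  diag(D) <- 0
  ord <- pcoa_ordination(D, k = 2)
  dd <- as.matrix(dist(ord$coords))
  expect_equal(dd[upper.tri(dd)], rep(1, 3), tolerance = 1e-9)

  # Euclidean distances are reproduced exactly
  set.seed(9)
  X <- matrix(rnorm(20), 10, 2)
  rownames(X) <- paste0("p", 1:10)
  DE <- as.matrix(dist(X))
  ord2 <- pcoa_ordination(DE, k = 2)
  expect_equal(as.matrix(dist(ord2$coords)), DE, tolerance = 1e-9,
               ignore_attr = TRUE)
  eig <- ord2$eigenvalues
  expect_true(all(diff(eig) <= 1e-9))
})

test_that("congruence tests: identical matrices are congruent, Holm caps at 1", {
  D <- random_dist(10, seed = 77)
  res <- congruence_tests(D, D, n_perm = 499, seed = 1)
  expect_equal(res$W, 1, tolerance = 1e-9)
  expect_equal(res$t0, 1, tolerance = 1e-9)
  expect_lte(res$p_cadm, 0.05)
  expect_lte(res$p_protest, 0.05)
  expect_true(all(res$p_holm >= c(res$p_cadm, res$p_protest)))

  # published case: raw p {0.871, 0.594} Holm-adjust to 1.00 for both
  expect_equal(unname(stats::p.adjust(c(0.871, 0.594), method = "holm")),
               c(1, 1))

  expect_error(congruence_tests(D, random_dist(9, seed = 1)), "different")
})

test_that("independent matrices are not declared congruent", {
  ps <- vapply(1:10, function(i) {
    congruence_tests(random_dist(10, seed = 1000 + i),
                     random_dist(10, seed = 2000 + i),
                     n_perm = 99, seed = i)$p_cadm
  }, numeric(1L))
  expect_gt(mean(ps > 0.05), 0.5)
})
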