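#' Binary indicator expansion of a multi-state trait table
#'
#' Each trait expands into one indicator column per observed state; a strain
#' scores 1 on every state listed in its cell (polymorphic cells such as
#' `"ellipsoidal, ovoid"` set several indicators), 0 on the trait's other
#' states, and `NA` on all of the trait's indicators when the cell is
#' unknown. Strains for which fewer than `min_completeness` of the traits
#' are determined are dropped.
#'
#' @param traits Data frame of character trait columns, strains as row names
#'   (see [read_trait_table()]); `NA` marks an unknown state.
#' @param min_completeness Minimum fraction of determined traits per strain
#'   (default 0.8, i.e. strains with 80 percent or more known states kept).
#' @return Numeric matrix (strains x indicators, entries 0/1/NA) with
#'   attributes `trait` (indicator -> trait name) and `dropped_strains`.
#' @export
encode_traits <- function(traits, min_completeness = 0.8) {
  stopifnot(is.data.frame(traits), ncol(traits) >= 1L)
  determined <- !is.na(as.matrix(traits))
  frac <- rowMeans(determined)
  keep <- frac >= min_completeness
  dropped <- rownames(traits)[!keep]
  if (!any(keep)) stop("no strains meet the completeness filter")
  traits <- traits[keep, , drop = FALSE]

  split_states <- function(cell) {
    if (is.na(cell)) return(character(0L))
    trimws(strsplit(cell, "[,;]")[[1L]])
  }
  cols <- list()
  trait_of <- character(0L)
  for (tr in names(traits)) {
    states <- sort(unique(unlist(lapply(traits[[tr]], split_states))))
    if (length(states) == 0L) next  # trait unknown everywhere
    block <- matrix(NA_real_, nrow(traits), length(states),
                    dimnames = list(rownames(traits),
                                    paste0(tr, "=", states)))
    for (i in seq_len(nrow(traits))) {
      obs <- split_states(traits[[tr]][i])
      if (length(obs) > 0L) block[i, ] <- as.numeric(states %in% obs)
    }
    cols[[tr]] <- block
    trait_of <- c(trait_of, rep(tr, length(states)))
  }
  bm <- do.call(cbind, cols)
  attr(bm, "trait") <- stats::setNames(trait_of, colnames(bm))
  attr(bm, "dropped_strains") <- dropped
  class(bm) <- c("binary_traits", class(bm))
  bm
}

#' Jaccard distance matrix over binary trait indicators
#'
#' For each strain pair, the comparison is restricted to traits determined in
#' both strains: d = 1 - |shared set bits| / |union of set bits|. A pair
#' whose restricted union is empty gets d = 0 by convention; a pair sharing
#' no determined traits is masked (`NA`).
#'
#' @param bm Binary matrix from [encode_traits()] (0/1/NA entries).
#' @return Symmetric distance matrix in [0, 1] with `NA` masks.
#' @export
jaccard_matrix <- function(bm) {
  m <- unclass(bm)
  n <- nrow(m)
  if (n < 2L) stop("need at least 2 strains")
  D <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- !is.na(m[i, ]) & !is.na(m[j, ])
      if (!any(ok)) {
        D[i, j] <- D[j, i] <- NA_real_
        next
      }
      a <- m[i, ok]
      b <- m[j, ok]
      inter <- sum(a == 1 & b == 1)
      union <- sum(a == 1 | b == 1)
      D[i, j] <- D[j, i] <- if (union == 0) 0 else 1 - inter / union
    }
  }
  D
}

# Off-diagonal (upper-triangle) vector of a square symmetric matrix.
offdiag <- function(D) D[upper.tri(D)]

#' Mantel test between two distance matrices
#'
#' The statistic is the Pearson correlation of the off-diagonal entries. The
#' one-tailed upper p-value permutes the strain labels of the second matrix
#' (rows and columns jointly), with the +1 correction:
#' p = (#\{permuted r >= observed r\} + 1) / (n_perm + 1).
#'
#' @param d1,d2 Complete symmetric distance matrices over the same strains.
#' @param n_perm Number of label permutations.
#' @param seed RNG seed for the permutations.
#' @return List with `r`, `p`, `n_perm`.
#' @export
mantel_test <- function(d1, d2, n_perm = 10000L, seed = 1L) {
  if (!identical(dim(d1), dim(d2))) stop("matrices differ in size")
  if (anyNA(offdiag(d1)) || anyNA(offdiag(d2))) {
    stop("Mantel test requires complete matrices")
  }
  v1 <- offdiag(d1)
  if (stats::sd(v1) == 0 || stats::sd(offdiag(d2)) == 0) {
    stop("degenerate trait: zero-variance distance vector")
  }
  r_obs <- stats::cor(v1, offdiag(d2))
  n <- nrow(d1)
  # map a label permutation to the induced permutation of upper-tri entries,
  # then evaluate all permuted correlations in one matrix product
  pos <- matrix(0L, n, n)
  pos[upper.tri(pos)] <- seq_len(n * (n - 1L) / 2L)
  pos <- pos + t(pos)
  v1c <- v1 - mean(v1)
  denom_v1 <- sqrt(sum(v1c^2))
  v2 <- offdiag(d2)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  count <- 0L
  block <- matrix(NA_real_, n_perm, length(v2))
  for (k in seq_len(n_perm)) {
    p <- sample.int(n)
    block[k, ] <- v2[pos[p, p][upper.tri(pos)]]
  }
  bc <- block - rowMeans(block)
  r_perm <- as.vector(bc %*% v1c) / (sqrt(rowSums(bc^2)) * denom_v1)
  # tolerance so that permutations tied with the observed statistic count
  p_val <- (sum(r_perm >= r_obs - 1e-12) + 1) / (n_perm + 1)
  list(r = r_obs, p = p_val, n_perm = n_perm)
}

#' Per-trait Mantel test against the overall Jaccard structure
#'
#' Compares the Jaccard matrix of all traits with the Jaccard matrix of a
#' single trait, over the strains for which that trait is determined. A high
#' correlation marks the trait as a strong contributor to the overall
#' separation of strains.
#'
#' @param bm Binary matrix from [encode_traits()].
#' @param trait Trait name (as in the trait table).
#' @param n_perm,seed Passed to [mantel_test()].
#' @return List with `r`, `p`, `n_perm`, `n_strains`.
#' @export
mantel_per_trait <- function(bm, trait, n_perm = 10000L, seed = 1L) {
  trait_of <- attr(bm, "trait")
  cols <- names(trait_of)[trait_of == trait]
  if (length(cols) == 0L) stop("unknown trait: ", trait)
  sub <- bm[, cols, drop = FALSE]
  ok <- rowSums(is.na(sub)) == 0L
  if (sum(ok) < 3L) stop("trait determined in fewer than 3 strains")
  patterns <- apply(sub[ok, , drop = FALSE], 1L, paste, collapse = "")
  if (length(unique(patterns)) < 2L) {
    stop("degenerate trait: single state pattern across strains")
  }
  overall <- jaccard_matrix(bm[ok, , drop = FALSE])
  single <- jaccard_matrix(structure(sub[ok, , drop = FALSE],
                                     trait = trait_of[cols]))
  if (anyNA(offdiag(overall))) {
    stop("overall Jaccard matrix has masked pairs among these strains")
  }
  res <- mantel_test(overall, single, n_perm = n_perm, seed = seed)
  res$n_strains <- sum(ok)
  res
}

#' UPGMA dendrogram from a distance matrix
#'
#' Average-linkage agglomeration; the returned tree is ultrametric with leaf
#' heights equal to half the cophenetic distances.
#'
#' @param D Complete symmetric distance matrix.
#' @return An `ape` `phylo` object.
#' @export
upgma_tree <- function(D) {
  check_dist_matrix(D)
  if (anyNA(offdiag(D))) {
    stop("UPGMA requires a complete matrix; impute or drop masked pairs first")
  }
  hc <- stats::hclust(stats::as.dist(D), method = "average")
  ape::as.phylo(hc)
}

#' Principal coordinates analysis (classical multidimensional scaling)
#'
#' Double-centered Gower eigendecomposition via [stats::cmdscale()]. Axes
#' with non-positive eigenvalues are dropped; if fewer than `k` positive
#' axes exist the result is truncated with a warning.
#'
#' @param D Complete symmetric distance matrix.
#' @param k Number of coordinate axes requested.
#' @return List with `coords` (strains x <= k) and `eigenvalues`.
#' @export
pcoa_ordination <- function(D, k = 2L) {
  check_dist_matrix(D)
  if (anyNA(offdiag(D))) stop("PCoA requires a complete matrix")
  if (k < 1L) stop("k must be >= 1")
  mds <- stats::cmdscale(stats::as.dist(D), k = min(k, nrow(D) - 1L),
                         eig = TRUE)
  eig <- mds$eig
  n_pos <- sum(eig > sqrt(.Machine$double.eps) * max(abs(eig)))
  keep <- min(k, n_pos, ncol(mds$points))
  if (keep < k) {
    warning("only ", keep, " positive-eigenvalue axes available; truncated")
  }
  list(coords = mds$points[, seq_len(keep), drop = FALSE],
       eigenvalues = eig)
}

#' Morphology-phylogeny congruence: CADM and Procrustes with Holm correction
#'
#' Global concordance of two distance matrices over the same strains,
#' assessed two ways: CADM (Kendall's W over the rank-transformed
#' off-diagonal vectors, permutation test) and Procrustes/protest on the
#' PCoA configurations (t0 = sqrt(1 - m2), permutation test). Because both
#' tests address the same hypothesis, the two p-values are Holm-adjusted.
#'
#' @param dm_morph,dm_phylo Complete symmetric distance matrices with
#'   identical strain sets (order may differ).
#' @param n_perm Number of permutations for both tests.
#' @param seed RNG seed.
#' @param k Number of PCoA axes fed to Procrustes (default 2).
#' @return List with `W`, `p_cadm`, `t0`, `p_protest`, `p_holm`
#'   (named length-2 vector).
#' @export
congruence_tests <- function(dm_morph, dm_phylo, n_perm = 9999L, seed = 1L,
                             k = 2L) {
  check_dist_matrix(dm_morph, "morphological matrix")
  check_dist_matrix(dm_phylo, "phylogenetic matrix")
  if (!setequal(rownames(dm_morph), rownames(dm_phylo))) {
    stop("matrices cover different strains")
  }
  ids <- rownames(dm_morph)
  dm_phylo <- dm_phylo[ids, ids]
  if (anyNA(offdiag(dm_morph)) || anyNA(offdiag(dm_phylo))) {
    stop("congruence tests require complete matrices")
  }
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))

  log <- utils::capture.output(
    cadm <- ape::CADM.global(rbind(dm_morph, dm_phylo), 2, nrow(dm_morph),
                             nperm = n_perm)
  )
  W <- unname(cadm$congruence_analysis["W", 1L])
  p_cadm <- unname(cadm$congruence_analysis["Prob.perm", 1L])

  ord1 <- pcoa_ordination(dm_morph, k = k)$coords
  ord2 <- pcoa_ordination(dm_phylo, k = k)$coords
  kk <- min(ncol(ord1), ncol(ord2))
  pro <- vegan::protest(ord1[, seq_len(kk), drop = FALSE],
                        ord2[, seq_len(kk), drop = FALSE],
                        permutations = n_perm)
  t0 <- unname(pro$t0)
  p_protest <- pro$signif

  p_holm <- stats::p.adjust(c(cadm = p_cadm, protest = p_protest),
                            method = "holm")
  list(W = W, p_cadm = p_cadm, t0 = t0, p_protest = p_protest,
       p_holm = p_holm)
}
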