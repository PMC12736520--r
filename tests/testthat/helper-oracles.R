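# Independent brute-force oracles used to cross-check the implementation.

# O(n^3) UPGMA agglomeration returning the matrix of merge heights
# (the cophenetic distances of the UPGMA tree). Ties: lowest index pair.
naive_upgma_cophenetic <- function(D) {
  n <- nrow(D)
  members <- lapply(seq_len(n), identity)
  act <- D
  coph <- matrix(0, n, n, dimnames = dimnames(D))
  while (length(members) > 1L) {
    m <- length(members)
    best <- c(1L, 2L)
    best_d <- Inf
    for (i in seq_len(m - 1L)) {
      for (j in (i + 1L):m) {
        if (act[i, j] < best_d) {
          best_d <- act[i, j]
          best <- c(i, j)
        }
      }
    }
    i <- best[1L]; j <- best[2L]
    coph[members[[i]], members[[j]]] <- best_d
    coph[members[[j]], members[[i]]] <- best_d
    ni <- length(members[[i]]); nj <- length(members[[j]])
    new_row <- (act[i, ] * ni + act[j, ] * nj) / (ni + nj)
    keep <- setdiff(seq_len(m), c(i, j))
    act <- rbind(cbind(act[keep, keep, drop = FALSE], new_row[keep]),
                 c(new_row[keep], 0))
    members <- c(members[keep], list(c(members[[i]], members[[j]])))
  }
  coph
}

# Connected components of the graph with edges d <= t, by boolean
# matrix-power transitive closure.
brute_components <- function(D, t) {
  A <- (!is.na(D) & D <= t)
  diag(A) <- TRUE
  repeat {
    A2 <- ((A %*% A) > 0) | A
    if (identical(A2, A)) break
    A <- A2
  }
  labels <- apply(A, 1L, paste, collapse = "")
  stats::setNames(match(labels, unique(labels)), rownames(D))
}

# Trapezoid AUC from a full ROC threshold sweep (positives = inter,
# predicted positive when distance > threshold).
trapezoid_auc <- function(intra, inter) {
  thr <- c(-Inf, sort(unique(c(intra, inter))))
  fpr <- vapply(thr, function(x) mean(intra > x), numeric(1L))
  tpr <- vapply(thr, function(x) mean(inter > x), numeric(1L))
  sum((fpr[-length(fpr)] - fpr[-1L]) * (tpr[-length(tpr)] + tpr[-1L]) / 2)
}

# All permutations of 1..n (for exact Mantel enumeration at tiny n).
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- setdiff(seq_len(n), i)
    cbind(i, matrix(rest[sub], nrow = nrow(sub)))
  }))
}

# Exact one-tailed Mantel p-value by full enumeration of label permutations
# (identity included, matching the +1-corrected permutation estimate).
exact_mantel_p <- function(d1, d2) {
  n <- nrow(d1)
  v1 <- d1[upper.tri(d1)]
  r_obs <- stats::cor(v1, d2[upper.tri(d2)])
  P <- all_perms(n)
  r_all <- apply(P, 1L, function(p) {
    dp <- d2[p, p]
    stats::cor(v1, dp[upper.tri(dp)])
  })
  mean(r_all >= r_obs - 1e-12)
}

# Random symmetric distance matrix with zero diagonal.
random_dist <- function(n, seed) {
  set.seed(seed)
  D <- matrix(0, n, n)
  D[upper.tri(D)] <- runif(n * (n - 1L) / 2L)
  D <- D + t(D)
  dimnames(D) <- list(paste0("s", seq_len(n)), paste0("s", seq_len(n)))
  D
}

write_lines_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
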