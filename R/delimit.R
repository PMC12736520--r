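#' Single-linkage distance-threshold clustering
#'
#' MOTUs are the connected components of the graph whose edges join strain
#' pairs with distance less than or equal to `t`. Masked (`NA`) distances are
#' treated as exceeding any threshold. With `linkage = "complete"`, clusters
#' are instead grown agglomeratively so that every within-MOTU pair is within
#' `t` (complete linkage cut).
#'
#' @param D Symmetric proportion-unit distance matrix.
#' @param t Distance threshold (same unit as `D`), `t >= 0`.
#' @param linkage `"single"` (default, graph components) or `"complete"`.
#' @return Named character vector (strain -> MOTU label `"motu_k"`), labels
#'   numbered by first strain occurrence.
#' @export
threshold_cluster <- function(D, t, linkage = c("single", "complete")) {
  linkage <- match.arg(linkage)
  check_dist_matrix(D)
  if (t < 0) stop("threshold must be non-negative")
  ids <- rownames(D)
  n <- length(ids)
  if (linkage == "single") {
    # union-find over edges d <= t
    parent <- seq_len(n)
    find <- function(i) {
      while (parent[i] != i) {
        parent[i] <<- parent[parent[i]]
        i <- parent[i]
      }
      i
    }
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        if (!is.na(D[i, j]) && D[i, j] <= t) {
          parent[find(i)] <- find(j)
        }
      }
    }
    comp <- vapply(seq_len(n), find, integer(1L))
  } else {
    Dc <- D
    Dc[is.na(Dc)] <- Inf
    hc <- stats::hclust(stats::as.dist(Dc), method = "complete")
    comp <- stats::cutree(hc, h = t)
  }
  comp <- match(comp, unique(comp))  # renumber in order of first occurrence
  stats::setNames(paste0("motu_", comp), ids)
}

#' K/theta test for the distinctness of two clades
#'
#' K is the mean pairwise distance across the two clades; theta is the larger
#' of the two within-clade mean pairwise distances (a conservative diversity
#' estimate that leans toward lumping). The clades are judged distinct when
#' K/theta >= `cutoff` (default 4, Birky's rule). With two singleton clades
#' theta is undefined and the verdict is `indeterminate`; with one singleton
#' the other clade's diversity is used.
#'
#' @param D Symmetric proportion-unit distance matrix.
#' @param clade_a,clade_b Disjoint non-empty character vectors of strain ids.
#' @param cutoff Ratio above which the clades are called distinct.
#' @return List with `K`, `theta`, `ratio`, `verdict` in
#'   `c("distinct", "not_distinct", "indeterminate")`.
#' @export
kot_test <- function(D, clade_a, clade_b, cutoff = 4) {
  check_dist_matrix(D)
  if (length(clade_a) == 0L || length(clade_b) == 0L) {
    stop("clades must be non-empty")
  }
  if (length(intersect(clade_a, clade_b)) > 0L) {
    stop("clades overlap: ", paste(intersect(clade_a, clade_b), collapse = ", "))
  }
  missing <- setdiff(c(clade_a, clade_b), rownames(D))
  if (length(missing) > 0L) {
    stop("strain(s) absent from distance matrix: ",
         paste(missing, collapse = ", "))
  }
  K <- mean(D[clade_a, clade_b, drop = FALSE], na.rm = TRUE)
  within_mean <- function(cl) {
    if (length(cl) < 2L) return(NA_real_)
    sub <- D[cl, cl, drop = FALSE]
    mean(sub[upper.tri(sub)], na.rm = TRUE)
  }
  thetas <- c(within_mean(clade_a), within_mean(clade_b))
  if (all(is.na(thetas))) {
    return(list(K = K, theta = NA_real_, ratio = NA_real_,
                verdict = "indeterminate"))
  }
  theta <- max(thetas, na.rm = TRUE)
  if (theta == 0) {
    if (K == 0) {
      return(list(K = K, theta = theta, ratio = NA_real_,
                  verdict = "indeterminate"))
    }
    return(list(K = K, theta = theta, ratio = Inf, verdict = "distinct"))
  }
  ratio <- K / theta
  list(K = K, theta = theta, ratio = ratio,
       verdict = if (ratio >= cutoff) "distinct" else "not_distinct")
}

#' Score a candidate MOTU partition against a reference taxonomy
#'
#' For each reference species with strain set R: `match` when one MOTU equals
#' R exactly; `split` when R spans two or more MOTUs, each wholly contained
#' in R; `merge` when R sits inside a single MOTU that also holds non-R
#' strains; `mixture` otherwise. Percentages are reported to 1 decimal.
#'
#' @param candidate Named character vector (strain -> MOTU).
#' @param reference Named character vector (strain -> species).
#' @return List with `verdicts` (named by species), `counts`, and
#'   `match_pct`, `split_pct`, `merge_pct`, `mixture_pct`.
#' @export
score_partition <- function(candidate, reference) {
  sym_diff <- c(setdiff(names(candidate), names(reference)),
                setdiff(names(reference), names(candidate)))
  if (length(sym_diff) > 0L) {
    stop("candidate and reference cover different strains: ",
         paste(unique(sym_diff), collapse = ", "))
  }
  species <- unique(reference)
  verdicts <- vapply(species, function(s) {
    R <- names(reference)[reference == s]
    motus <- unique(candidate[R])
    if (length(motus) == 1L) {
      motu_members <- names(candidate)[candidate == motus]
      if (setequal(motu_members, R)) "match" else "merge"
    } else {
      contained <- vapply(motus, function(m) {
        all(names(candidate)[candidate == m] %in% R)
      }, logical(1L))
      if (all(contained)) "split" else "mixture"
    }
  }, character(1L))
  counts <- vapply(c("match", "split", "merge", "mixture"),
                   function(v) sum(verdicts == v), integer(1L))
  pct <- round(100 * counts / length(species), 1)
  list(verdicts = verdicts, counts = counts,
       match_pct = pct[["match"]], split_pct = pct[["split"]],
       merge_pct = pct[["merge"]], mixture_pct = pct[["mixture"]])
}
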