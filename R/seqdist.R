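PURINES <- c("A", "G")
PYRIMIDINES <- c("C", "T")

#' Kimura 2-parameter distance between two aligned sequences
#'
#' Sites where either sequence carries a gap or an ambiguity code are excluded
#' (pairwise deletion). With P the transition proportion and Q the
#' transversion proportion over the n compared sites,
#' \deqn{d = -\frac{1}{2}\ln(1 - 2P - Q) - \frac{1}{4}\ln(1 - 2Q).}
#' When a log argument is non-positive the distance is saturated and reported
#' as `NA` with `defined = FALSE` rather than clamped.
#'
#' @param seq1,seq2 Aligned DNA strings (or character vectors of single
#'   bases) of equal length.
#' @return List with `d`, `P`, `Q`, `n_sites`, `defined`.
#' @export
k2p_distance <- function(seq1, seq2) {
  a <- if (length(seq1) == 1L) strsplit(toupper(seq1), "")[[1L]] else toupper(seq1)
  b <- if (length(seq2) == 1L) strsplit(toupper(seq2), "")[[1L]] else toupper(seq2)
  if (length(a) != length(b)) stop("sequences differ in aligned length")
  a[a == "U"] <- "T"
  b[b == "U"] <- "T"
  ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  n <- sum(ok)
  if (n == 0L) stop("no comparable sites after pairwise deletion")
  a <- a[ok]
  b <- b[ok]
  diff <- a != b
  ts <- diff & ((a %in% PURINES) == (b %in% PURINES))  # within purines/pyrimidines
  P <- sum(ts) / n
  Q <- sum(diff & !ts) / n
  arg1 <- 1 - 2 * P - Q
  arg2 <- 1 - 2 * Q
  if (arg1 <= 0 || arg2 <= 0) {
    return(list(d = NA_real_, P = P, Q = Q, n_sites = n, defined = FALSE))
  }
  d <- -0.5 * log(arg1) - 0.25 * log(arg2)
  list(d = d, P = P, Q = Q, n_sites = n, defined = TRUE)
}

#' Pairwise K2P distance matrix for an alignment
#'
#' Applies [k2p_distance()] to every unordered pair under pairwise deletion.
#' Saturated pairs (undefined log) are masked as `NA` and do not abort the
#' computation.
#'
#' @param aln A [dna_alignment()].
#' @return Symmetric proportion-unit matrix, `NA` where undefined.
#' @export
k2p_matrix <- function(aln) {
  stopifnot(inherits(aln, "dna_alignment"))
  m <- unclass(aln)
  n <- nrow(m)
  if (n < 2L) stop("need at least 2 sequences")
  D <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      r <- k2p_distance(m[i, ], m[j, ])
      D[i, j] <- D[j, i] <- r$d
    }
  }
  D
}

#' Proportion of variable alignment columns
#'
#' A column is variable when at least two distinct unambiguous bases
#' (A/C/G/T) occur in it; gaps and ambiguity codes never make a column
#' variable. All columns, including all-gap ones, count in the denominator.
#'
#' @param aln A [dna_alignment()].
#' @return Percentage of variable columns (0-100).
#' @export
variable_site_proportion <- function(aln) {
  stopifnot(inherits(aln, "dna_alignment"))
  m <- unclass(aln)
  if (nrow(m) < 2L) stop("need at least 2 sequences")
  variable <- apply(m, 2L, function(col) {
    bases <- unique(col[col %in% c("A", "C", "G", "T")])
    length(bases) >= 2L
  })
  100 * sum(variable) / ncol(m)
}

#' Uncorrected p-distance between two aligned sequences (pairwise deletion)
#'
#' Companion to [k2p_distance()]; shares its site-exclusion rule.
#'
#' @inheritParams k2p_distance
#' @return Proportion of differing compared sites.
#' @export
p_distance <- function(seq1, seq2) {
  r <- k2p_distance(seq1, seq2)
  # P and Q already partition the differing sites
  r$P + r$Q
}
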