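#' Label distance pairs as intra- or interspecific
#'
#' Every unordered strain pair with a defined distance is labeled `intra`
#' when both strains share a species in the taxonomy and `inter` otherwise.
#'
#' @param D Symmetric proportion-unit distance matrix (`NA` = masked).
#' @param taxonomy Named character vector (strain -> species).
#' @return Data frame with columns `strain_i`, `strain_j`, `distance`,
#'   `label` (factor intra/inter).
#' @export
label_pairs <- function(D, taxonomy) {
  check_dist_matrix(D)
  ids <- rownames(D)
  missing <- setdiff(ids, names(taxonomy))
  if (length(missing) > 0L) {
    stop("strain(s) absent from taxonomy: ", paste(missing, collapse = ", "))
  }
  idx <- which(upper.tri(D), arr.ind = TRUE)
  d <- D[upper.tri(D)]
  keep <- !is.na(d)
  sp_i <- taxonomy[ids[idx[keep, 1L]]]
  sp_j <- taxonomy[ids[idx[keep, 2L]]]
  data.frame(
    strain_i = ids[idx[keep, 1L]],
    strain_j = ids[idx[keep, 2L]],
    distance = d[keep],
    label = factor(ifelse(sp_i == sp_j, "intra", "inter"),
                   levels = c("intra", "inter")),
    stringsAsFactors = FALSE
  )
}

#' Percentage of overlapping distances from the total range
#'
#' The barcode-gap summary used in marker comparison tables: the width of the
#' intersection of the intraspecific and interspecific distance ranges,
#' divided by the width of their union (overall minimum to overall maximum),
#' times 100.
#'
#' @param intra_range,inter_range Numeric length-2 vectors `c(min, max)`;
#'   any consistent unit (both ranges in percent, or both in proportions).
#' @return Overlap percentage (0-100), not rounded.
#' @export
overlap_percentage <- function(intra_range, inter_range) {
  stopifnot(length(intra_range) == 2L, length(inter_range) == 2L)
  if (intra_range[1L] > intra_range[2L] || inter_range[1L] > inter_range[2L]) {
    stop("ranges must be ordered c(min, max)")
  }
  total <- max(intra_range[2L], inter_range[2L]) -
    min(intra_range[1L], inter_range[1L])
  if (total == 0) stop("total distance range is zero; overlap undefined")
  overlap <- max(0, min(intra_range[2L], inter_range[2L]) -
                    max(intra_range[1L], inter_range[1L]))
  100 * overlap / total
}

#' Gap-midpoint (overlap-minimizing) distance threshold
#'
#' The arithmetic mean of the maximum intraspecific and the minimum
#' interspecific distance.
#'
#' @param pairs Labeled pairs from [label_pairs()].
#' @return Threshold in the unit of the input distances.
#' @export
overlap_minimizing_threshold <- function(pairs) {
  intra <- pairs$distance[pairs$label == "intra"]
  inter <- pairs$distance[pairs$label == "inter"]
  if (length(intra) == 0L) stop("no intraspecific pairs")
  if (length(inter) == 0L) stop("no interspecific pairs")
  (max(intra) + min(inter)) / 2
}

# Mann-Whitney AUC with 1/2 credit for ties; interspecific = positive class.
mw_auc <- function(intra, inter) {
  r <- rank(c(intra, inter), ties.method = "average")
  n_neg <- length(intra)
  n_pos <- length(inter)
  (sum(r[(n_neg + 1L):(n_neg + n_pos)]) - n_pos * (n_pos + 1) / 2) /
    (n_pos * n_neg)
}

#' ROC analysis of a barcode's separating power
#'
#' Interspecific pairs are the positive class; a pair is called positive when
#' its distance exceeds the threshold. AUC is the Mann-Whitney statistic with
#' tie correction; its 95 percent confidence interval uses the DeLong
#' placement variance. The operating threshold maximizes Youden's
#' J = sensitivity + specificity - 1 over midpoints between consecutive
#' sorted unique distances (with -Inf/+Inf sentinels); ties resolve to the
#' smallest threshold.
#'
#' @param pairs Labeled pairs from [label_pairs()].
#' @return List with `auc`, `auc_ci_95`, `youden_threshold`, `sensitivity`,
#'   `specificity`, `J`.
#' @export
roc_analysis <- function(pairs) {
  intra <- pairs$distance[pairs$label == "intra"]
  inter <- pairs$distance[pairs$label == "inter"]
  if (length(intra) == 0L || length(inter) == 0L) {
    stop("both intra- and interspecific pairs are required for ROC analysis")
  }
  auc <- mw_auc(intra, inter)

  # DeLong placements: psi(x, y) = 1 if y > x, 1/2 if tie
  psi_pos <- vapply(inter, function(y) {
    mean((y > intra) + 0.5 * (y == intra))
  }, numeric(1L))
  psi_neg <- vapply(intra, function(x) {
    mean((inter > x) + 0.5 * (inter == x))
  }, numeric(1L))
  v <- var_or_zero(psi_pos) / length(inter) + var_or_zero(psi_neg) / length(intra)
  half <- stats::qnorm(0.975) * sqrt(v)
  ci <- c(max(0, auc - half), min(1, auc + half))

  u <- sort(unique(c(intra, inter)))
  cand <- c(-Inf, if (length(u) > 1L) (u[-length(u)] + u[-1L]) / 2, Inf)
  sens <- vapply(cand, function(t) mean(inter > t), numeric(1L))
  spec <- vapply(cand, function(t) mean(intra <= t), numeric(1L))
  J <- sens + spec - 1
  best <- which.max(J)  # first index = smallest threshold on ties
  list(auc = auc, auc_ci_95 = ci, youden_threshold = cand[best],
       sensitivity = sens[best], specificity = spec[best], J = J[best])
}

var_or_zero <- function(x) if (length(x) < 2L) 0 else stats::var(x)

#' Species identification efficiency under the local barcode gap
#'
#' A species is counted as identified when its maximum intraspecific distance
#' is strictly smaller than its minimum distance to any strain of another
#' species (singleton species use 0 as their intraspecific maximum). Masked
#' distances are ignored.
#'
#' @param D Symmetric proportion-unit distance matrix.
#' @param taxonomy Named character vector (strain -> species).
#' @return Percentage of identified species (0-100), not rounded.
#' @export
identification_efficiency <- function(D, taxonomy) {
  check_dist_matrix(D)
  ids <- rownames(D)
  missing <- setdiff(ids, names(taxonomy))
  if (length(missing) > 0L) {
    stop("strain(s) absent from taxonomy: ", paste(missing, collapse = ", "))
  }
  sp <- taxonomy[ids]
  species <- unique(sp)
  if (length(species) < 2L) stop("need at least 2 species")
  identified <- vapply(species, function(s) {
    inside <- which(sp == s)
    outside <- which(sp != s)
    intra_max <- if (length(inside) > 1L) {
      max(D[inside, inside][upper.tri(D[inside, inside])], na.rm = TRUE)
    } else 0
    inter_min <- min(D[inside, outside, drop = FALSE], na.rm = TRUE)
    is.finite(intra_max) && is.finite(inter_min) && intra_max < inter_min
  }, logical(1L))
  100 * sum(identified) / length(species)
}

#' Histogram overlap of intra/inter distance distributions
#'
#' Overlap coefficient between the two empirical distributions on a shared
#' Freedman-Diaconis binning: the sum over bins of the smaller of the two
#' relative frequencies. A secondary, distribution-based companion to the
#' range-based [overlap_percentage()].
#'
#' @param pairs Labeled pairs from [label_pairs()].
#' @return Overlap coefficient in [0, 1].
#' @export
distribution_overlap <- function(pairs) {
  intra <- pairs$distance[pairs$label == "intra"]
  inter <- pairs$distance[pairs$label == "inter"]
  if (length(intra) == 0L || length(inter) == 0L) {
    stop("both classes are required")
  }
  all_d <- c(intra, inter)
  if (diff(range(all_d)) == 0) return(1)
  iqr <- stats::IQR(all_d)
  bw <- if (iqr > 0) 2 * iqr / length(all_d)^(1 / 3) else diff(range(all_d)) / 10
  breaks <- seq(min(all_d), max(all_d), by = bw)
  if (breaks[length(breaks)] < max(all_d)) breaks <- c(breaks, max(all_d))
  h1 <- graphics::hist(intra, breaks = breaks, plot = FALSE)$counts / length(intra)
  h2 <- graphics::hist(inter, breaks = breaks, plot = FALSE)$counts / length(inter)
  sum(pmin(h1, h2))
}

#' Assemble a barcode evaluation report
#'
#' Composes the distance-range, overlap, threshold, ROC and identification
#' statistics for one barcode from an alignment and a reference taxonomy.
#' Ranges are reported in percent, rounded to 1 decimal; thresholds and AUC
#' keep full precision.
#'
#' @param aln A [dna_alignment()].
#' @param taxonomy Named character vector (strain -> species).
#' @return List with fields `intra_range`, `inter_range`, `overlap_pct`,
#'   `efficiency_pct`, `variable_site_pct`, `threshold_gap_midpoint`,
#'   `roc`, `distribution_overlap`, `n_pairs_masked`.
#' @export
barcode_report <- function(aln, taxonomy) {
  D <- k2p_matrix(aln)
  pairs <- label_pairs(D, taxonomy)
  intra <- pairs$distance[pairs$label == "intra"]
  inter <- pairs$distance[pairs$label == "inter"]
  if (length(intra) == 0L) stop("no intraspecific pairs in this dataset")
  if (length(inter) == 0L) stop("no interspecific pairs in this dataset")
  intra_range <- round(range(intra) * 100, 1)
  inter_range <- round(range(inter) * 100, 1)
  list(
    intra_range = intra_range,
    inter_range = inter_range,
    overlap_pct = round(overlap_percentage(intra_range, inter_range), 1),
    efficiency_pct = round(identification_efficiency(D, taxonomy), 1),
    variable_site_pct = round(variable_site_proportion(aln), 1),
    threshold_gap_midpoint = overlap_minimizing_threshold(pairs),
    roc = roc_analysis(pairs),
    distribution_overlap = distribution_overlap(pairs),
    n_pairs_masked = sum(is.na(D[upper.tri(D)]))
  )
}
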