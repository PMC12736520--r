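#' Parse a fatty-acid name of the form C:D with optional double-bond positions
#'
#' Accepts the lipid shorthand used in composition tables, e.g. `"16:0"`,
#' `"18:3 Δ9,12,15"`, `"19:1Δ10"` (the Greek delta may also be
#' written `d` or `D`). When positions are listed their number must equal
#' the double-bond count.
#'
#' @param name Fatty-acid name string.
#' @return List with `carbons`, `n_double_bonds`, `positions`
#'   (integer vector, possibly empty).
#' @export
parse_fa_name <- function(name) {
  m <- regmatches(name,
                  regexec("^\\s*(\\d+):(\\d+)\\s*(?:[ΔdD]\\s*([0-9]+(?:\\s*,\\s*[0-9]+)*))?\\s*$",
                          name))[[1L]]
  if (length(m) == 0L) stop("cannot parse fatty-acid name: '", name, "'")
  carbons <- as.integer(m[2L])
  ndb <- as.integer(m[3L])
  positions <- integer(0L)
  if (nzchar(m[4L])) {
    positions <- as.integer(strsplit(gsub("\\s", "", m[4L]), ",")[[1L]])
    if (length(positions) != ndb) {
      stop("fatty acid '", name, "' lists ", length(positions),
           " double-bond positions but declares ", ndb)
    }
  }
  list(carbons = carbons, n_double_bonds = ndb, positions = positions)
}

#' Unsaturation index of a fatty-acid profile
#'
#' UI = sum over fatty acids of (mass percent x number of double bonds) / 100,
#' a standard membrane-fluidity proxy. Double-bond counts are parsed from the
#' fatty-acid names; `NA` percentages (e.g. not-detected entries) count as 0.
#'
#' @param fa_names Character vector of fatty-acid names (see
#'   [parse_fa_name()]).
#' @param mass_pct Numeric vector of mass percentages of total FAs.
#' @return The unsaturation index (dimensionless).
#' @export
unsaturation_index <- function(fa_names, mass_pct) {
  if (length(fa_names) != length(mass_pct)) {
    stop("fa_names and mass_pct differ in length")
  }
  ndb <- vapply(fa_names, function(x) parse_fa_name(x)$n_double_bonds,
                integer(1L))
  pct <- ifelse(is.na(mass_pct), 0, mass_pct)
  if (any(pct < 0)) stop("mass percentages must be non-negative")
  sum(pct * ndb) / 100
}

#' One-way ANOVA with eta-squared from summary statistics or raw replicates
#'
#' The primary path takes per-group (mean, sd, n), as printed in composition
#' tables: SSB = sum n_i (m_i - grand mean)^2, SSW = sum (n_i - 1) s_i^2,
#' F = (SSB/(k-1)) / (SSW/(N-k)), eta2 = SSB / (SSB + SSW), p from the F
#' distribution. Raw replicate vectors give identical results through the
#' same decomposition.
#'
#' @param groups Either a data frame / list with elements `mean`, `sd`, `n`
#'   (one entry per group), or a list of numeric replicate vectors.
#' @return List with `F`, `p`, `eta_sq`, `df`, and the per-group summary.
#' @export
one_way_anova <- function(groups) {
  if (is.list(groups) && !is.data.frame(groups) &&
      all(vapply(groups, is.numeric, logical(1L))) &&
      is.null(groups$mean)) {
    n <- vapply(groups, length, integer(1L))
    if (any(n < 2L)) stop("each group needs n >= 2 replicates")
    means <- vapply(groups, mean, numeric(1L))
    sds <- vapply(groups, stats::sd, numeric(1L))
  } else {
    means <- groups$mean
    sds <- groups$sd
    n <- groups$n
    if (is.null(means) || is.null(sds) || is.null(n)) {
      stop("summary input needs elements 'mean', 'sd', 'n'")
    }
    if (any(n < 2L)) stop("summary-statistic ANOVA needs n >= 2 per group")
  }
  k <- length(means)
  if (k < 2L) stop("need at least 2 groups")
  if (any(sds < 0)) stop("standard deviations must be non-negative")
  N <- sum(n)
  grand <- sum(n * means) / N
  ssb <- sum(n * (means - grand)^2)
  ssw <- sum((n - 1) * sds^2)
  df1 <- k - 1L
  df2 <- N - k
  f_stat <- if (ssw == 0) {
    if (ssb == 0) 0 else Inf
  } else {
    (ssb / df1) / (ssw / df2)
  }
  p <- stats::pf(f_stat, df1, df2, lower.tail = FALSE)
  eta_sq <- if (ssb + ssw == 0) 0 else ssb / (ssb + ssw)
  list(F = f_stat, p = p, eta_sq = eta_sq, df = c(df1, df2),
       groups = data.frame(mean = means, sd = sds, n = n))
}

#' t-based confidence interval for a mean
#'
#' mean +/- t(1 - alpha/2, n - 1) * sd / sqrt(n). Negative lower bounds are
#' reported as-is; for near-zero trace quantities they indicate a true mean
#' close to zero, not an error.
#'
#' @param mean,sd,n Summary statistics (n >= 2, sd >= 0).
#' @param level Confidence level (default 0.95).
#' @return Numeric `c(lower, upper)`.
#' @export
t_ci <- function(mean, sd, n, level = 0.95) {
  if (n < 2L) stop("n must be >= 2")
  if (sd < 0) stop("sd must be non-negative")
  half <- stats::qt(1 - (1 - level) / 2, df = n - 1) * sd / sqrt(n)
  c(lower = mean - half, upper = mean + half)
}

#' Pairwise Welch t-tests between fatty-acid groups (from summary statistics)
#'
#' Companion to [one_way_anova()] for post-hoc contrasts when only
#' mean/sd/n are available. This is a Welch procedure, not Tukey's HSD.
#'
#' @param groups Data frame / list with `mean`, `sd`, `n` and optionally
#'   `label`.
#' @param p_adjust Multiple-testing correction passed to
#'   [stats::p.adjust()] (default `"holm"`).
#' @return Data frame of pairwise comparisons with t, df, raw and adjusted p.
#' @export
pairwise_welch <- function(groups, p_adjust = "holm") {
  means <- groups$mean
  sds <- groups$sd
  n <- groups$n
  labels <- if (!is.null(groups$label)) groups$label else seq_along(means)
  k <- length(means)
  if (k < 2L) stop("need at least 2 groups")
  combs <- utils::combn(k, 2L)
  res <- apply(combs, 2L, function(ij) {
    i <- ij[1L]; j <- ij[2L]
    se2 <- sds[i]^2 / n[i] + sds[j]^2 / n[j]
    t_stat <- (means[i] - means[j]) / sqrt(se2)
    df <- se2^2 / (sds[i]^4 / (n[i]^2 * (n[i] - 1)) +
                     sds[j]^4 / (n[j]^2 * (n[j] - 1)))
    c(t = t_stat, df = df,
      p = 2 * stats::pt(abs(t_stat), df, lower.tail = FALSE))
  })
  out <- data.frame(group_a = labels[combs[1L, ]],
                    group_b = labels[combs[2L, ]],
                    t = res["t", ], df = res["df", ], p = res["p", ])
  out$p_adj <- stats::p.adjust(out$p, method = p_adjust)
  out
}

#' Full fatty-acid report for a long-format summary table
#'
#' For each condition: the unsaturation index of the mean profile; for each
#' fatty acid present in at least two conditions: one-way ANOVA with
#' eta-squared across conditions and 95 percent t-CIs per condition.
#'
#' @param fa_table Data frame from [read_fa_table()] (columns `fa`,
#'   `condition`, `mean`, `sd`, `n`). Rows whose `fa` does not parse as a
#'   C:D name (e.g. a pre-computed index row) are used for ANOVA/CI but
#'   excluded from UI.
#' @return List with `ui` (named by condition) and `anova` (data frame: fa,
#'   F, p, eta_sq) and `ci` (data frame: fa, condition, lower, upper).
#' @export
fa_report <- function(fa_table) {
  conditions <- unique(fa_table$condition)
  parses <- vapply(unique(fa_table$fa), function(x) {
    !inherits(tryCatch(parse_fa_name(x), error = function(e) e), "error")
  }, logical(1L))
  ui <- vapply(conditions, function(cond) {
    sub <- fa_table[fa_table$condition == cond & parses[fa_table$fa], ]
    unsaturation_index(sub$fa, sub$mean)
  }, numeric(1L))
  names(ui) <- conditions

  anova_rows <- lapply(unique(fa_table$fa), function(f) {
    sub <- fa_table[fa_table$fa == f & !is.na(fa_table$mean), ]
    if (nrow(sub) < 2L || any(sub$n < 2L)) return(NULL)
    a <- one_way_anova(sub)
    data.frame(fa = f, F = a$F, p = a$p, eta_sq = a$eta_sq)
  })
  ci_rows <- lapply(seq_len(nrow(fa_table)), function(i) {
    row <- fa_table[i, ]
    if (is.na(row$mean) || row$n < 2L) return(NULL)
    ci <- t_ci(row$mean, row$sd, row$n)
    data.frame(fa = row$fa, condition = row$condition,
               lower = ci[["lower"]], upper = ci[["upper"]])
  })
  list(ui = ui,
       anova = do.call(rbind, anova_rows),
       ci = do.call(rbind, ci_rows))
}
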