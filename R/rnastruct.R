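CANONICAL_PAIRS <- c("AU", "UA", "GC", "CG", "GU", "UG")

#' Parse a dot-bracket secondary structure
#'
#' Base pairs come from stack matching of `(` and `)`; pseudoknots are not
#' supported. Helices are maximal runs of stacked pairs
#' (i, j), (i+1, j-1), ..., numbered 1, 2, ... in 5' to 3' order of their
#' base (outermost) pair. T is treated as U.
#'
#' @param seq RNA/DNA string.
#' @param db Dot-bracket string of the same length.
#' @return A `secondary_structure` list: `sequence` (RNA letters),
#'   `dotbracket`, `pairs` (matrix, columns i/j, 1-based, i < j), `helix`
#'   (helix id per pair), `n_helices`.
#' @export
parse_dotbracket <- function(seq, db) {
  seq <- toupper(seq)
  seq <- gsub("T", "U", seq, fixed = TRUE)
  if (nchar(seq) != nchar(db)) {
    stop("sequence and dot-bracket strings differ in length")
  }
  chars <- strsplit(db, "")[[1L]]
  bad <- setdiff(unique(chars), c("(", ")", "."))
  if (length(bad) > 0L) {
    stop("unsupported dot-bracket symbols: ", paste(bad, collapse = ", "))
  }
  stack <- integer(0L)
  pairs <- matrix(integer(0L), ncol = 2L, dimnames = list(NULL, c("i", "j")))
  for (pos in seq_along(chars)) {
    if (chars[pos] == "(") {
      stack <- c(stack, pos)
    } else if (chars[pos] == ")") {
      if (length(stack) == 0L) {
        stop("unbalanced dot-bracket: unmatched ')' at position ", pos)
      }
      pairs <- rbind(pairs, c(stack[length(stack)], pos))
      stack <- stack[-length(stack)]
    }
  }
  if (length(stack) > 0L) {
    stop("unbalanced dot-bracket: unmatched '(' at position ",
         stack[length(stack)])
  }
  if (nrow(pairs) > 0L) {
    pairs <- pairs[order(pairs[, 1L]), , drop = FALSE]
    # helix break when the next pair is not stacked directly inside this one
    new_helix <- c(TRUE, !(diff(pairs[, 1L]) == 1L &
                             diff(pairs[, 2L]) == -1L))
    helix <- cumsum(new_helix)
  } else {
    helix <- integer(0L)
  }
  structure(list(sequence = seq, dotbracket = db, pairs = pairs,
                 helix = helix, n_helices = if (length(helix)) max(helix) else 0L),
            class = "secondary_structure")
}

# alignment column -> ungapped sequence position (NA at gaps)
aln_position_map <- function(gapped) {
  chars <- strsplit(gapped, "")[[1L]]
  pos <- cumsum(chars != "-")
  pos[chars == "-"] <- NA_integer_
  pos
}

#' Classify base-pair changes between two secondary structures
#'
#' Walks the base pairs of `ss1`; through the pairwise alignment, each pair
#' is matched to the corresponding positions of `ss2` and classified:
#' `identical` (both nucleotides unchanged, pairing retained), `CBC` (both
#' nucleotides differ, both pairs canonical Watson-Crick or G.U), `hemi_CBC`
#' (exactly one nucleotide differs, both pairs canonical), `mismatch`
#' (pairing retained but a non-canonical pair on either side), `pair_lost`
#' (the ss1 pair has no pairing in ss2). Pairs present only in ss2 are
#' counted as `pair_gained`.
#'
#' @param ss1,ss2 [parse_dotbracket()] structures.
#' @param aln1,aln2 Gapped strings aligning the two sequences (same length;
#'   ungapped content must equal the structures' sequences). Defaults assume
#'   equal-length sequences aligned position-by-position.
#' @return A `cbc_report` list: `per_pair` data frame (ss1 pairs with helix,
#'   nucleotides and class), `totals` (named counts incl. pair_gained),
#'   `per_helix` (class counts by ss1 helix).
#' @export
compare_structures <- function(ss1, ss2, aln1 = ss1$sequence,
                               aln2 = ss2$sequence) {
  stopifnot(inherits(ss1, "secondary_structure"),
            inherits(ss2, "secondary_structure"))
  aln1 <- gsub("T", "U", toupper(aln1), fixed = TRUE)
  aln2 <- gsub("T", "U", toupper(aln2), fixed = TRUE)
  if (nchar(aln1) != nchar(aln2)) stop("alignment rows differ in length")
  if (gsub("-", "", aln1, fixed = TRUE) != ss1$sequence) {
    stop("alignment row 1 does not match the first structure's sequence")
  }
  if (gsub("-", "", aln2, fixed = TRUE) != ss2$sequence) {
    stop("alignment row 2 does not match the second structure's sequence")
  }
  map1 <- aln_position_map(aln1)
  map2 <- aln_position_map(aln2)
  col_of1 <- match(seq_len(nchar(ss1$sequence)), map1)
  s1 <- strsplit(ss1$sequence, "")[[1L]]
  s2 <- strsplit(ss2$sequence, "")[[1L]]
  paired2 <- integer(nchar(ss2$sequence))  # partner position, 0 = unpaired
  if (nrow(ss2$pairs) > 0L) {
    paired2[ss2$pairs[, 1L]] <- ss2$pairs[, 2L]
    paired2[ss2$pairs[, 2L]] <- ss2$pairs[, 1L]
  }

  classify_one <- function(i, j) {
    ci <- col_of1[i]
    cj <- col_of1[j]
    i2 <- map2[ci]
    j2 <- map2[cj]
    if (is.na(i2) || is.na(j2) || paired2[i2] != j2) {
      return(list(cls = "pair_lost", nt2 = c(NA_character_, NA_character_)))
    }
    pair1 <- paste0(s1[i], s1[j])
    pair2 <- paste0(s2[i2], s2[j2])
    canonical <- pair1 %in% CANONICAL_PAIRS && pair2 %in% CANONICAL_PAIRS
    n_changed <- (s1[i] != s2[i2]) + (s1[j] != s2[j2])
    cls <- if (n_changed == 0L) {
      "identical"
    } else if (!canonical) {
      "mismatch"
    } else if (n_changed == 2L) {
      "CBC"
    } else {
      "hemi_CBC"
    }
    list(cls = cls, nt2 = c(s2[i2], s2[j2]))
  }

  n1 <- nrow(ss1$pairs)
  cls <- character(n1)
  nt2i <- character(n1)
  nt2j <- character(n1)
  for (k in seq_len(n1)) {
    res <- classify_one(ss1$pairs[k, 1L], ss1$pairs[k, 2L])
    cls[k] <- res$cls
    nt2i[k] <- res$nt2[1L]
    nt2j[k] <- res$nt2[2L]
  }
  per_pair <- data.frame(
    i = ss1$pairs[, 1L], j = ss1$pairs[, 2L], helix = ss1$helix,
    nt1_i = s1[ss1$pairs[, 1L]], nt1_j = s1[ss1$pairs[, 2L]],
    nt2_i = nt2i, nt2_j = nt2j, class = cls, stringsAsFactors = FALSE
  )

  # ss2 pairs whose aligned ss1 positions are not mutually paired
  pair_gained <- 0L
  if (nrow(ss2$pairs) > 0L) {
    col_of2 <- match(seq_len(nchar(ss2$sequence)), map2)
    paired1 <- integer(nchar(ss1$sequence))
    if (n1 > 0L) {
      paired1[ss1$pairs[, 1L]] <- ss1$pairs[, 2L]
      paired1[ss1$pairs[, 2L]] <- ss1$pairs[, 1L]
    }
    for (k in seq_len(nrow(ss2$pairs))) {
      i1 <- map1[col_of2[ss2$pairs[k, 1L]]]
      j1 <- map1[col_of2[ss2$pairs[k, 2L]]]
      if (is.na(i1) || is.na(j1) || paired1[i1] != j1) {
        pair_gained <- pair_gained + 1L
      }
    }
  }

  levels <- c("identical", "CBC", "hemi_CBC", "mismatch", "pair_lost")
  totals <- vapply(levels, function(l) sum(cls == l), integer(1L))
  totals <- c(totals, pair_gained = pair_gained)
  per_helix <- if (n1 > 0L) {
    table(helix = per_pair$helix,
          class = factor(per_pair$class, levels = levels))
  } else {
    table(helix = integer(0L), class = factor(character(0L), levels = levels))
  }
  structure(list(per_pair = per_pair, totals = totals, per_helix = per_helix),
            class = "cbc_report")
}

#' Count CBCs in conserved helix regions and issue a species-cut verdict
#'
#' The classical ITS2 rule considers the first `regions[["1"]]` pairs of
#' helix I counted from the helix base, the first `regions[["2"]]` pairs of
#' helix II, and all of helix III conserved; a single CBC inside these spans
#' signals sexual incompatibility, i.e. distinct species. Helix numbering
#' follows the structure's 5' to 3' helix order unless remapped via
#' `helix_map`.
#'
#' @param report A `cbc_report` from [compare_structures()].
#' @param regions Named numeric vector: helix number (as character) ->
#'   number of conserved pairs from the helix base (`Inf` = entire helix).
#'   Default `c("1" = 5, "2" = 10, "3" = Inf)`.
#' @param helix_map Optional integer vector remapping structural helix ids to
#'   nomenclature numbers, e.g. `c(2, 1, 3)` says structural helix 1 is
#'   nomenclature helix 2.
#' @return List with `cbc_count`, `verdict` (`"distinct"`/`"not_distinct"`),
#'   and `cbc_pairs` (rows of `per_pair` that triggered).
#' @export
cbc_in_conserved_regions <- function(report,
                                     regions = c("1" = 5, "2" = 10, "3" = Inf),
                                     helix_map = NULL) {
  stopifnot(inherits(report, "cbc_report"))
  pp <- report$per_pair
  helix_nom <- pp$helix
  if (!is.null(helix_map)) {
    if (length(helix_map) < max(pp$helix, 0L)) {
      stop("helix_map shorter than the number of helices")
    }
    helix_nom <- helix_map[pp$helix]
  }
  present <- unique(helix_nom)
  asked <- as.integer(names(regions))
  absent <- setdiff(asked, present)
  if (length(absent) > 0L) {
    stop("conserved-region rule references missing helix/helices: ",
         paste(absent, collapse = ", "))
  }
  in_region <- rep(FALSE, nrow(pp))
  for (h in asked) {
    span <- regions[[as.character(h)]]
    sel <- which(helix_nom == h)
    if (length(sel) == 0L) next
    # pairs are in 5'->3' order of i, i.e. base-first within a helix
    keep <- sel[seq_len(min(span, length(sel)))]
    in_region[keep] <- TRUE
  }
  hit <- pp$class == "CBC" & in_region
  list(cbc_count = sum(hit),
       verdict = if (any(hit)) "distinct" else "not_distinct",
       cbc_pairs = pp[hit, , drop = FALSE])
}
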