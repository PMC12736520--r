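#' @import stats
#' @import utils
NULL

IUPAC_DNA <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
               "B", "D", "H", "V", "N", "-")

#' Construct an aligned DNA sequence set
#'
#' An alignment is stored as a character matrix with one row per strain and
#' one column per alignment site. Sequences are upper-cased and RNA 'U' is
#' normalized to 'T'; only IUPAC DNA symbols and '-' gaps are accepted.
#'
#' @param seqs Named character vector of equal-length gapped DNA strings.
#' @return A `dna_alignment` object (character matrix, rows named by strain).
#' @export
dna_alignment <- function(seqs) {
  if (length(seqs) == 0L) stop("alignment is empty")
  ids <- names(seqs)
  if (is.null(ids) || any(!nzchar(ids))) stop("all sequences must be named")
  if (anyDuplicated(ids)) {
    stop("duplicate strain identifiers: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- toupper(seqs)
  seqs <- gsub("U", "T", seqs, fixed = TRUE)
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) {
    stop("unaligned input: sequence lengths differ (",
         paste(range(lens), collapse = "-"), ")")
  }
  m <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  rownames(m) <- ids
  bad <- setdiff(unique(as.vector(m)), IUPAC_DNA)
  if (length(bad) > 0L) {
    stop("invalid symbols in alignment: ", paste(bad, collapse = ", "))
  }
  structure(m, class = c("dna_alignment", "matrix", "array"))
}

#' Read an aligned FASTA file
#'
#' @param path FASTA file of equal-length (aligned) DNA sequences.
#' @return A [dna_alignment()] object; record order is preserved.
#' @export
read_alignment <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop("empty FASTA file: ", path)
  seqs <- as.character(ss)
  # keep only the first whitespace-delimited token of each header
  names(seqs) <- sub("\\s.*$", "", names(ss))
  dna_alignment(seqs)
}

#' Write an alignment to FASTA
#'
#' @param aln A `dna_alignment`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  stopifnot(inherits(aln, "dna_alignment"))
  seqs <- apply(unclass(aln), 1L, paste, collapse = "")
  ss <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(ss, path, width = 80L)
  invisible(path)
}

#' Strain identifiers of an alignment or distance matrix
#' @param x A `dna_alignment` or square distance matrix.
#' @return Character vector of strain ids.
#' @export
strain_ids <- function(x) {
  if (inherits(x, "dna_alignment")) return(rownames(x))
  if (is.matrix(x)) return(rownames(x))
  stop("no strain ids for object of class ", paste(class(x), collapse = "/"))
}

read_two_column_map <- function(path, value_col, what) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE)
  for (col in c("strain", value_col)) {
    if (!col %in% names(df)) {
      stop(what, " table is missing required column '", col, "'")
    }
  }
  make_strain_map(df$strain, df[[value_col]], what)
}

make_strain_map <- function(strains, values, what) {
  if (anyDuplicated(strains)) {
    stop("duplicate strain ids in ", what, " table: ",
         paste(unique(strains[duplicated(strains)]), collapse = ", "))
  }
  if (any(is.na(values) | !nzchar(values))) {
    stop("empty ", what, " label for strain(s): ",
         paste(strains[is.na(values) | !nzchar(values)], collapse = ", "))
  }
  stats::setNames(as.character(values), strains)
}

#' Read a strain-to-species taxonomy table
#'
#' Expects a TSV with header columns `strain` and `species`.
#'
#' @param path TSV file.
#' @return Named character vector mapping strain id to species label.
#' @export
read_taxonomy <- function(path) read_two_column_map(path, "species", "taxonomy")

#' Read a strain-to-MOTU partition table
#'
#' Expects a TSV with header columns `strain` and `motu`. MOTU labels are
#' opaque; only the induced grouping matters.
#'
#' @param path TSV file.
#' @return Named character vector mapping strain id to MOTU label.
#' @export
read_partition <- function(path) read_two_column_map(path, "motu", "partition")

#' Write a partition (or taxonomy) to TSV
#' @param x Named character vector (strain -> label).
#' @param path Output file.
#' @param value_col Name for the label column (`"motu"` or `"species"`).
#' @return `path`, invisibly.
#' @export
write_partition <- function(x, path, value_col = "motu") {
  df <- data.frame(strain = names(x), label = unname(x),
                   stringsAsFactors = FALSE)
  names(df)[2L] <- value_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a morphological trait table
#'
#' TSV with a `strain` column followed by one column per trait. Cells hold a
#' state token or a comma-separated list of tokens for polymorphic
#' observations; the literal token `?` (or an empty cell) marks an unknown
#' state and becomes `NA`.
#'
#' @param path TSV file.
#' @return Data frame of character columns, strains as row names.
#' @export
read_trait_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE)
  if (!"strain" %in% names(df)) stop("trait table is missing column 'strain'")
  if (anyDuplicated(df$strain)) stop("duplicate strain ids in trait table")
  rownames(df) <- df$strain
  df$strain <- NULL
  if (ncol(df) == 0L) stop("trait table has no trait columns")
  df[] <- lapply(df, function(col) {
    col <- trimws(col)
    col[col == "?" | col == ""] <- NA_character_
    col
  })
  df
}

#' Read a fatty-acid summary table
#'
#' Long-format TSV with columns `fa`, `condition`, `mean`, `sd`, `n`
#' (mass percent of total fatty acids; `n` biological replicates).
#'
#' @param path TSV file.
#' @return Data frame with typed columns.
#' @export
read_fa_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE,
                          colClasses = c(fa = "character",
                                         condition = "character"))
  req <- c("fa", "condition", "mean", "sd", "n")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0L) {
    stop("fatty-acid table is missing column(s): ", paste(miss, collapse = ", "))
  }
  df
}

#' Write a dendrogram to newick
#'
#' @param tree An `ape` `phylo` object (e.g. from [upgma_tree()]).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read a newick tree
#' @param path Newick file.
#' @return An `ape` `phylo` object.
#' @export
read_newick <- function(path) {
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop("could not parse newick file: ", path)
  tr
}

#' Read a secondary-structure file
#'
#' Plain-text format: line 1 the RNA/DNA sequence, line 2 the dot-bracket
#' string of equal length (lines may be preceded by a `>name` header line).
#'
#' @param path Structure file.
#' @return A `secondary_structure` object (see [parse_dotbracket()]).
#' @export
read_structure <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), ">")]
  if (length(lines) < 2L) {
    stop("structure file must contain a sequence line and a dot-bracket line")
  }
  parse_dotbracket(trimws(lines[1L]), trimws(lines[2L]))
}

# Validate a symmetric distance matrix (NA = masked/undefined entry).
check_dist_matrix <- function(D, what = "distance matrix") {
  if (!is.matrix(D) || nrow(D) != ncol(D)) stop(what, " must be square")
  if (is.null(rownames(D)) || !identical(rownames(D), colnames(D))) {
    stop(what, " must have matching row/column strain names")
  }
  if (!isTRUE(all.equal(D, t(D), check.attributes = FALSE))) {
    stop(what, " must be symmetric")
  }
  if (any(diag(D) != 0, na.rm = TRUE)) stop(what, " diagonal must be zero")
  if (any(D < 0, na.rm = TRUE)) stop(what, " entries must be non-negative")
  invisible(D)
}

#' Write a square distance matrix to TSV (percent units)
#'
#' Distances are held as proportions internally; on disk they are percentages
#' with 4 decimals, following the reporting convention of barcoding tables.
#'
#' @param D Symmetric proportion-unit distance matrix (NA = undefined).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_dist_tsv <- function(D, path) {
  check_dist_matrix(D)
  out <- format(round(D * 100, 4), trim = TRUE)
  out[is.na(D)] <- "NA"
  df <- data.frame(strain = rownames(D), out, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a square distance matrix TSV written by [write_dist_tsv()]
#' @param path TSV file (percent units on disk).
#' @return Proportion-unit symmetric matrix with NA for undefined entries.
#' @export
read_dist_tsv <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE)
  ids <- as.character(df[[1L]])
  D <- as.matrix(df[, -1L, drop = FALSE]) / 100
  rownames(D) <- ids
  colnames(D) <- ids
  check_dist_matrix(D)
}
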