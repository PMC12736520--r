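# Evolve each row of a character matrix along a branch of expected length b
# (substitutions per site) under a two-class Kimura process: per site the
# number of events is Poisson(b); each event is a transition with probability
# kappa/(kappa + 2), otherwise one of the two transversions at random.
evolve_branch <- function(seqs, b, kappa) {
  if (b == 0) return(seqs)
  p_ts <- kappa / (kappa + 2)
  transition <- c(A = "G", G = "A", C = "T", T = "C")
  transversions <- list(A = c("C", "T"), G = c("C", "T"),
                        C = c("A", "G"), T = c("A", "G"))
  n_events <- matrix(stats::rpois(length(seqs), b), nrow(seqs), ncol(seqs))
  max_ev <- max(n_events)
  for (round in seq_len(max_ev)) {
    hit <- which(n_events >= round)
    if (length(hit) == 0L) break
    is_ts <- stats::runif(length(hit)) < p_ts
    cur <- seqs[hit]
    new <- character(length(hit))
    new[is_ts] <- transition[cur[is_ts]]
    if (any(!is_ts)) {
      tv_from <- cur[!is_ts]
      pick <- stats::runif(sum(!is_ts)) < 0.5
      new[!is_ts] <- vapply(seq_along(tv_from), function(k) {
        transversions[[tv_from[k]]][if (pick[k]) 1L else 2L]
      }, character(1L))
    }
    seqs[hit] <- new
  }
  seqs
}

#' Simulate a two-level species/strain barcode alignment
#'
#' Emulates the divergence structure a barcode-gap analysis assumes: a star
#' phylogeny of species around a common root, each species ancestor at
#' expected distance `d_between / 2` from the root (so species pairs sit at
#' expected K2P distance `d_between`), and a star of strains around each
#' species ancestor at `d_within / 2`. Substitutions follow the two-class
#' transition/transversion process with rate ratio `kappa`, exactly the
#' process the K2P estimator inverts.
#'
#' @param n_species,strains_per_species Dataset shape.
#' @param seq_length Alignment length in nucleotides (>= 100 recommended).
#' @param d_within,d_between Expected within- and between-species distances
#'   (proportions); `0 <= d_within < d_between`.
#' @param kappa Transition/transversion rate ratio (default 2).
#' @param seed RNG seed; the generator is a pure function of its arguments.
#' @return List with `alignment` (a [dna_alignment()]) and `taxonomy`
#'   (named character vector strain -> species).
#' @export
simulate_sequences <- function(n_species, strains_per_species, seq_length,
                               d_within, d_between, kappa = 2, seed = 1L) {
  if (d_within < 0 || d_between <= d_within) {
    stop("require 0 <= d_within < d_between")
  }
  if (kappa < 0) stop("kappa must be non-negative")
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))

  root <- sample(c("A", "C", "G", "T"), seq_length, replace = TRUE)
  n_total <- n_species * strains_per_species
  species <- rep(sprintf("species_%02d", seq_len(n_species)),
                 each = strains_per_species)
  strains <- sprintf("%s_s%d", species,
                     rep(seq_len(strains_per_species), times = n_species))
  rows <- matrix("", n_total, seq_length)
  for (sp in seq_len(n_species)) {
    anc <- evolve_branch(matrix(root, 1L), d_between / 2, kappa)
    idx <- ((sp - 1L) * strains_per_species + 1L):(sp * strains_per_species)
    block <- matrix(rep(anc, strains_per_species), strains_per_species,
                    seq_length, byrow = TRUE)
    rows[idx, ] <- evolve_branch(block, d_within / 2, kappa)
  }
  seqs <- stats::setNames(apply(rows, 1L, paste, collapse = ""), strains)
  list(alignment = dna_alignment(seqs),
       taxonomy = stats::setNames(species, strains))
}

#' Simulate a multi-state morphological trait matrix with cluster signal
#'
#' Strains are assigned round-robin to `n_clusters` clusters; each cluster
#' has a modal state per trait (drawn from a per-trait vocabulary of
#' `n_states` tokens) and each observed cell deviates to a random other
#' state with probability `noise`. Unknown cells (`NA`) are placed uniformly
#' at random at rate `missing_frac`.
#'
#' @param n_strains,n_traits,n_clusters Matrix shape and signal structure.
#' @param missing_frac Unknown-cell rate, `0 <= missing_frac < 0.5`.
#' @param noise Per-cell deviation probability (default 0.05).
#' @param n_states States per trait vocabulary (default 3).
#' @param seed RNG seed.
#' @return List with `traits` (character data frame, strains as row names)
#'   and `clusters` (named integer vector, the true cluster map).
#' @export
simulate_trait_matrix <- function(n_strains, n_traits, n_clusters,
                                  missing_frac = 0, noise = 0.05,
                                  n_states = 3L, seed = 1L) {
  if (missing_frac < 0 || missing_frac >= 0.5) {
    stop("missing_frac must lie in [0, 0.5)")
  }
  if (n_clusters > n_strains) stop("more clusters than strains")
  if (n_states < 2L) stop("need at least 2 states per trait")
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))

  clusters <- rep_len(seq_len(n_clusters), n_strains)
  strains <- sprintf("strain_%03d", seq_len(n_strains))
  vocab <- function(tr) sprintf("t%d_state%d", tr, seq_len(n_states))
  modal <- matrix("", n_clusters, n_traits)
  for (tr in seq_len(n_traits)) {
    modal[, tr] <- sample(vocab(tr), n_clusters, replace = TRUE)
  }
  cells <- matrix("", n_strains, n_traits,
                  dimnames = list(strains, sprintf("trait_%02d", seq_len(n_traits))))
  for (tr in seq_len(n_traits)) {
    states <- vocab(tr)
    cell <- modal[clusters, tr]
    flip <- stats::runif(n_strains) < noise
    if (any(flip)) {
      cell[flip] <- vapply(cell[flip], function(cur) {
        sample(setdiff(states, cur), 1L)
      }, character(1L))
    }
    cells[, tr] <- cell
  }
  cells[stats::runif(length(cells)) < missing_frac] <- NA_character_
  traits <- as.data.frame(cells, stringsAsFactors = FALSE)
  list(traits = traits, clusters = stats::setNames(clusters, strains))
}

#' Derive a candidate partition from a taxonomy by controlled splits/merges
#'
#' Exactly `n_splits` species (with at least two strains each) are divided
#' into two MOTUs, and `n_merges` disjoint species pairs (chosen among the
#' remaining, unsplit species) are fused into single MOTUs; all other
#' species map to one MOTU each. By construction, scoring the result against
#' the reference yields exactly `n_splits` split and `2 * n_merges` merge
#' verdicts.
#'
#' @param reference Named character vector (strain -> species).
#' @param n_splits,n_merges Perturbation counts.
#' @param seed RNG seed.
#' @return Named character vector (strain -> MOTU label).
#' @export
perturb_partition <- function(reference, n_splits = 0L, n_merges = 0L,
                              seed = 1L) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))

  species <- unique(reference)
  splittable <- species[vapply(species, function(s) sum(reference == s) >= 2L,
                               logical(1L))]
  if (n_splits > length(splittable)) {
    stop("cannot split ", n_splits, " species: only ", length(splittable),
         " have >= 2 strains")
  }
  to_split <- if (n_splits > 0L) sample(splittable, n_splits) else character(0L)
  remaining <- setdiff(species, to_split)
  if (2L * n_merges > length(remaining)) {
    stop("cannot merge ", n_merges, " disjoint pairs among ",
         length(remaining), " unsplit species")
  }
  merge_pool <- if (n_merges > 0L) sample(remaining, 2L * n_merges) else character(0L)

  motu <- paste0("motu_", reference)
  names(motu) <- names(reference)
  for (s in to_split) {
    members <- names(reference)[reference == s]
    k <- sample(seq_len(length(members) - 1L), 1L)
    half <- sample(members, k)
    motu[half] <- paste0("motu_", s, "_a")
    motu[setdiff(members, half)] <- paste0("motu_", s, "_b")
  }
  if (n_merges > 0L) {
    for (m in seq_len(n_merges)) {
      pair <- merge_pool[c(2L * m - 1L, 2L * m)]
      members <- names(reference)[reference %in% pair]
      motu[members] <- paste0("motu_merge_", m)
    }
  }
  motu
}

#' Simulate fatty-acid replicate measurements from stated means and SDs
#'
#' Per fatty acid, `n` replicates are drawn normal(mean, sd) and clipped at
#' zero (mass percentages cannot be negative); clipping events are reported.
#'
#' @param means,sds Named numeric vectors (fatty acid -> mass percent), same
#'   names.
#' @param n Replicates per fatty acid (default 3, the usual biological
#'   triplicate).
#' @param seed RNG seed.
#' @return List with `replicates` (matrix fa x n) and `n_clipped`.
#' @export
simulate_fa_replicates <- function(means, sds, n = 3L, seed = 1L) {
  if (n < 2L) stop("need n >= 2 replicates")
  if (!identical(names(means), names(sds))) {
    stop("means and sds must share fatty-acid names")
  }
  if (any(sds < 0)) stop("sds must be non-negative")
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  draws <- matrix(stats::rnorm(length(means) * n, mean = rep(means, each = n),
                               sd = rep(sds, each = n)),
                  nrow = length(means), byrow = TRUE,
                  dimnames = list(names(means), paste0("rep", seq_len(n))))
  n_clipped <- sum(draws < 0)
  if (n_clipped > 0L) {
    message(n_clipped, " negative draw(s) clipped to 0")
    draws[draws < 0] <- 0
  }
  list(replicates = draws, n_clipped = n_clipped)
}
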