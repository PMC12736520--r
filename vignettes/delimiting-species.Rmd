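---
title: "Methods: barcode gaps, partition scoring, and the supporting statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: barcode gaps, partition scoring, and the supporting statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(delimetrics)
```

`delimetrics` quantifies the lines of evidence used in integrative species
delimitation. This vignette explains the models and procedures, the
parameters that matter, what the synthetic-data generators do and do not
emulate, and the numerical choices made where the field's conventions leave
room.

## Genetic distances

The Kimura 2-parameter model treats transitions (A↔G, C↔T) and
transversions as two rate classes. With *P* and *Q* the observed transition
and transversion proportions over the *n* sites compared,

$$ d = -\tfrac{1}{2}\ln(1 - 2P - Q) - \tfrac{1}{4}\ln(1 - 2Q). $$

Three conventions are fixed here and matter for comparability:

- **Pairwise deletion.** Sites with a gap or an ambiguity code in either
  sequence of a pair are excluded for that pair only, keeping per-pair *n*
  maximal. This is the dominant convention of the distance software used in
  barcoding workflows. Ambiguity codes are excluded rather than
  probabilistically resolved: barcoding pipelines typically screen inputs to
  be free of ambiguous bases, so the codes that remain carry little signal.
- **Saturation is reported, not hidden.** When a log argument is
  non-positive the distance is undefined; the pair is masked (`NA`),
  excluded from range summaries, and counted in `n_pairs_masked`. Clamping
  to a large value would silently distort ranges and thresholds.
- **Variable-site proportion.** A column is variable when two or more
  distinct unambiguous bases occur in it. All columns count in the
  denominator, including all-gap columns — the alternative (dropping them)
  is defensible, but a single convention has to be fixed for percentages to
  be comparable across markers of different gappiness.

## Barcode-gap evaluation

Each unordered strain pair is labeled intraspecific or interspecific by the
reference taxonomy. Four summaries are computed:

- **Range overlap percentage**: the width of the intersection of the intra-
  and interspecific distance ranges over the width of their union, × 100.
  This is a pure function of the four range bounds, so it can be computed
  from published range tables without the underlying matrices.
- **Distribution overlap**: the overlap coefficient of the two empirical
  histograms on shared Freedman–Diaconis bins — deterministic,
  dependency-free, and reported separately because the range-based statistic
  ignores how mass is distributed inside the ranges.
- **Gap-midpoint threshold**: the arithmetic mean of the maximum
  intraspecific and minimum interspecific distance.
- **ROC analysis**: interspecific pairs are the positive class (larger
  distance = more positive). AUC is the tie-corrected Mann–Whitney
  statistic; an internal invariant checked by the test suite is that it
  equals the trapezoid area under the full threshold sweep to 1e-9. The 95%
  CI uses the DeLong placement variance. Candidate operating thresholds are
  midpoints between consecutive sorted unique distances with ±∞ sentinels;
  Youden's J = sensitivity + specificity − 1 is maximized, and ties resolve
  to the smallest threshold, favoring sensitivity for the interspecific
  class.

**Identification efficiency** needs a definition of "identified species";
the one adopted is the local barcode gap: a species is identified when its
maximum intraspecific distance is strictly below its minimum distance to any
other species, singletons counting an intraspecific maximum of 0. This rule
is standard in the barcode-gap literature and reproduces the published
11-of-14 = 78.6% arithmetic on constructed fixtures; whether any given
published table used this rule or a threshold-based one is usually not
stated, so a threshold-based alternative can be derived from
`roc_analysis()` without endorsing either as "the" published rule.

## Delimitation and partition scoring

**Threshold clustering** realizes the intuitive "distance threshold" as
single linkage: MOTUs are connected components of the graph with edges where
d ≤ t. This is the graph-connectivity reading of a distance cutoff, is
monotone (lower thresholds refine higher ones), and is cheap to verify
against brute-force transitive closure — both properties the tests exercise.
Complete linkage is available behind a flag for users who want compact
clusters. Masked distances are treated as exceeding any threshold.

**K/θ** compares the mean between-clade distance K to the within-clade
diversity θ, calling clades distinct when K/θ ≥ 4 (Birky's rule). Published
descriptions leave the θ estimator underspecified, so a choice had to be
made: θ is the *larger* of the two within-clade mean pairwise distances —
conservative toward lumping, because a large denominator is harder to beat.
With two singleton clades θ is undefined and the verdict is `indeterminate`;
with one singleton the other clade's diversity is used. These choices are
documented here as this package's, not asserted as any published tool's.

**Scoring** a candidate partition against a reference taxonomy is per
reference species with strain set R: `match` when one MOTU equals R exactly;
`split` when R spans several MOTUs each wholly inside R; `merge` when R sits
strictly inside one MOTU; `mixture` otherwise. Verdict counts always sum to
the number of species, and percentages are reported to 1 decimal (so an
11-species reference yields the familiar 90.9 / 81.8 / 72.7 ladder).
Partitions from external delimitation algorithms are consumed as TSV and
scored identically; those algorithms themselves are out of scope.

## Morphology

Multi-state traits are expanded into binary indicators, one per state;
polymorphic cells ("ellipsoidal, broadly ellipsoidal") set several
indicators, preserving shared-state semantics in the Jaccard numerator.
Strains with fewer than 80% of traits determined are dropped (the
`min_completeness` default). Jaccard distance for a pair is computed over
the traits determined in both strains: d = 1 − |shared bits| / |union bits|;
an empty union gives d = 0 by convention, and a pair with no jointly
determined traits is masked.

The **per-trait Mantel test** correlates the off-diagonal entries of the
overall Jaccard matrix with those of a single trait's Jaccard matrix. The
permutation test permutes strain labels of one matrix (rows and columns
jointly), one-tailed upper with the +1 correction; published usage typically
states neither tail nor correction, so both are fixed and documented here.
The permutation loop is vectorized (a label permutation induces a
permutation of the off-diagonal vector, so all permuted correlations reduce
to one matrix product), making 10,000 permutations cheap. The test suite
checks the permutation p against full 4!-enumeration at n = 4 and its null
uniformity by KS test over 200 simulated independent matrices.

**UPGMA** is average-linkage agglomeration (via `stats::hclust`, returned as
an `ape` tree with ultrametric leaf heights at half the cophenetic
distance); the tests verify it against a naive O(n³) re-implementation and
check ultrametricity on random matrices. **PCoA** is classical scaling
(double-centered Gower eigendecomposition); negative-eigenvalue axes are
dropped with a warning when fewer than the requested axes remain.

**Congruence** between a morphological and a phylogenetic distance matrix is
tested twice — CADM (Kendall's W over the two rank-transformed off-diagonal
vectors, the two-matrix case of the general test) and Procrustes/protest on
the PCoA configurations (both centered and scaled to unit sum of squares
before rotation, the standard protest convention; t0 = √(1−m²)) — with 9999
permutations each and Holm correction over the two p-values, since they
address one hypothesis. Whether published patristic distances were scaled
before Procrustes is usually unstated; scaling is protest's default and is
used here.

## ITS secondary structures

Structures arrive as sequence + dot-bracket (folding is out of scope); pairs
come from stack matching, and helices are maximal runs of stacked pairs
numbered 5′→3′. Because automatic homology assignment of ITS helices to the
conventional numbering (I–IV) is out of scope, the numbering can be remapped
via `helix_map` when the structural order differs from the nomenclature.

Pair changes between two aligned structures are classified against the
canonical set {AU, UA, GC, CG, GU, UG}: both nucleotides changed with both
pairs canonical is a **CBC**; exactly one changed with pairing retained is a
**hemi-CBC**; a retained but non-canonical pairing is a mismatch, never a
CBC; pairing present on only one side is lost/gained (swapping the inputs
swaps lost and gained — a tested invariant). The **conserved-region rule**
counts CBCs in the first 5 pairs of helix I, the first 10 of helix II, and
all of helix III — pairs counted from the base (outermost pair) of each
helix, following the convention used in comparative ITS figures — and a
single such CBC yields the verdict "distinct" (sexual incompatibility).
Whether the 5-bp/10-bp spans should count from base or apex is not fully
settled in the literature; base-first is the default and the spans are
configurable.

## Fatty acids

Names parse as C:D with optional Δ-positions (the position count must match
D). The unsaturation index is UI = Σ(mass% × double bonds)/100 over the
listed fatty acids; trace acids absent from a table are simply absent from
the sum, which reproduces published UIs within 0.01. Since composition
tables print means ± SD, the primary ANOVA path works from summary
statistics — SSB = Σnᵢ(ȳᵢ−ȳ)², SSW = Σ(nᵢ−1)sᵢ², η² = SSB/(SSB+SSW) — and is
algebraically identical to the raw-replicate path (a tested 1e-12
invariant). Confidence intervals are mean ± t₁₋α/₂,ₙ₋₁·sd/√n; negative lower
bounds on near-zero quantities are reported as-is, indicating a true mean
near zero. Tukey HSD letter assignment is out of scope; pairwise Welch
t-tests are provided as a clearly labeled alternative.

## Synthetic data: what it emulates, what it does not

The generators exist so every stage is testable without external sequence
databases; their defaults are the study conditions of the analyses they feed.

- `simulate_sequences()` builds a star phylogeny of species around a root
  (species ancestors at expected distance `d_between`/2 from the root, so
  species pairs sit at `d_between`) and a star of strains within each
  species at `d_within`/2. Substitution counts per site are Poisson with the
  branch length as mean; each event is a transition with probability
  κ/(κ+2) (κ defaults to 2, a typical nuclear ribosomal value), else one of
  the two transversions. This is exactly the two-class process the K2P
  estimator inverts, so estimates are consistent for the configured
  divergences — by design: the point is to test the estimator, not to model
  genealogies. There is no coalescent, rate heterogeneity, indel process, or
  base-composition bias; passing tests therefore certify the distance and
  threshold machinery, not robustness to those real-data features.
- `simulate_trait_matrix()` gives each cluster a modal state per trait and
  flips cells to a random other state with probability `noise` (default
  0.05, light observational error); unknowns are placed uniformly at random
  (not blockwise, so missingness is ignorable by construction).
- `perturb_partition()` splits and merges whole species, so the expected
  scoring outcome is known exactly by construction — the oracle for the
  match/split/merge arithmetic.
- `simulate_fa_replicates()` draws normal replicates from stated means/SDs
  (n = 3 by default, the usual biological triplicate) and clips at zero,
  reporting how often clipping fired.

All generators are pure functions of (parameters, seed) and restore the
caller's RNG state.

## Problem sizes and tolerances

The test suite runs at deliberately small scale: alignments of 1000–5000 nt
with 12 strains, 50-seed recovery sweeps, 200-replicate null calibrations at
999 permutations each, and 4-strain exact enumerations. These sizes make the
statistical checks sharp (binomial/KS bounds are computed from them
explicitly in the tests) while keeping the whole suite under a minute.
Oracle-equivalence checks (UPGMA vs naive agglomeration, Mann–Whitney vs
trapezoid AUC, clustering vs transitive closure) use 1e-9; algebraic
identities use 1e-12; permutation p-values carry the granularity of their
permutation counts. Mantel permutation counts use a 1e-12 tie tolerance so
permutations numerically tied with the observed statistic count as ≥, which
full enumeration at n = 4 shows is the correct convention.

## Known limitations

- Only K2P is implemented; there is deliberately no JC/TN93/GTR fallback,
  and no model selection.
- Single- and complete-linkage threshold clustering only; no ASAP-style
  recursive partition ranking, GMYC, or PTP — external partitions are scored
  instead.
- UPGMA inherits `hclust`'s tie-breaking, which may differ from
  lowest-index-pair conventions on exactly tied merges (ties have measure
  zero on continuous distances).
- CBC detection requires a user-supplied pairwise alignment and dot-bracket
  structures; no folding, free-energy computation, or automatic helix
  homology.
- The morphological module accepts any user-declared state vocabulary; it
  does not attempt to standardize published textual descriptions into
  states.
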