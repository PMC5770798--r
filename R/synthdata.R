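#' Family profile for synthetic sequence generation
#'
#' A synthetic "family" is defined by a background residue distribution
#' plus a set of gapped residue pairs whose frequency is enriched relative
#' to that background, emulating the family-specific pair-composition
#' signal a GPC-based classifier exploits.
#'
#' @param name Class label.
#' @param base_frequencies Named 20-vector of residue probabilities
#'   (default uniform); must sum to 1.
#' @param biased_pairs data.frame with columns `a`, `b` (residues), `gap`
#'   (non-negative integer) and `mult` (enrichment multiplier > 1), or NULL
#'   for a null (signal-free) profile.
#' @param length_range Integer (min, max) sequence length; the default
#'   80-600 straddles the length variability of real HSP families. min must
#'   be at least max(gap) + 2.
#' @return Object of class `family_profile`.
#' @export
family_profile <- function(name,
                           base_frequencies = stats::setNames(rep(1 / 20, 20),
                                                              AA_ALPHABET),
                           biased_pairs = NULL,
                           length_range = c(80L, 600L)) {
  if (!setequal(names(base_frequencies), AA_ALPHABET) ||
      abs(sum(base_frequencies) - 1) > 1e-9) {
    stop("base_frequencies must cover the 20 amino acids and sum to 1")
  }
  if (!is.null(biased_pairs)) {
    stopifnot(all(c("a", "b", "gap", "mult") %in% names(biased_pairs)),
              all(biased_pairs$a %in% AA_ALPHABET),
              all(biased_pairs$b %in% AA_ALPHABET),
              all(biased_pairs$gap >= 0L),
              all(biased_pairs$mult > 1))
    if (length_range[1L] < max(biased_pairs$gap) + 2L) {
      stop("minimum length must be at least max(gap) + 2")
    }
  }
  structure(list(name = name,
                 base_frequencies = base_frequencies[AA_ALPHABET],
                 biased_pairs = biased_pairs,
                 length_range = as.integer(length_range)),
            class = "family_profile")
}

#' Generate one synthetic protein sequence from a profile
#'
#' Length is uniform over the profile's range; residues are drawn i.i.d.
#' from the background distribution; then, for each biased pair
#' (a, b, gap G, multiplier m), enough start positions are rewritten to
#' raise the expected count of (a, G skipped, b) occurrences to m times its
#' background expectation. Rewriting positions (rather than
#' rejection-sampling whole sequences) guarantees the intended enrichment
#' at any length in bounded time. Consumes the current R RNG stream; seed
#' with `set.seed()` for reproducibility.
#'
#' @param profile A [family_profile()].
#' @param id Identifier for the sequence.
#' @return A [protein_sequence()].
#' @export
generate_sequence <- function(profile, id = profile$name) {
  stopifnot(inherits(profile, "family_profile"))
  L <- sample(profile$length_range[1L]:profile$length_range[2L], 1L)
  res <- sample(AA_ALPHABET, L, replace = TRUE,
                prob = profile$base_frequencies)
  bp <- profile$biased_pairs
  if (!is.null(bp)) {
    for (r in seq_len(nrow(bp))) {
      G <- bp$gap[r]
      n_pairs <- L - G - 1L
      p_null <- profile$base_frequencies[[bp$a[r]]] *
        profile$base_frequencies[[bp$b[r]]]
      n_plant <- round((bp$mult[r] - 1) * p_null * n_pairs)
      if (n_plant == 0L) next
      if (n_plant > n_pairs) {
        stop("profile '", profile$name, "': cannot plant ", n_plant,
             " pairs of (", bp$a[r], ",", bp$b[r], ", gap ", G,
             ") in a sequence of length ", L)
      }
      starts <- sample(n_pairs, n_plant)
      res[starts] <- bp$a[r]
      res[starts + G + 1L] <- bp$b[r]
    }
  }
  protein_sequence(id, paste(res, collapse = ""))
}

#' Benchmark specification
#'
#' @param profiles List of [family_profile()].
#' @param counts Integer vector of per-class sequence counts, parallel to
#'   `profiles` (all at least 1).
#' @param seed Integer seed; the whole benchmark is deterministic given it.
#' @return Object of class `benchmark_spec`.
#' @export
benchmark_spec <- function(profiles, counts, seed = 1L) {
  stopifnot(length(profiles) == length(counts), all(counts >= 1L))
  structure(list(profiles = profiles, counts = as.integer(counts),
                 seed = as.integer(seed)),
            class = "benchmark_spec")
}

#' Generate a labeled synthetic benchmark
#'
#' @param spec A [benchmark_spec()].
#' @return A [labeled_dataset()] with exactly the requested class counts,
#'   ids `<class>_<serial>`.
#' @export
generate_benchmark <- function(spec) {
  stopifnot(inherits(spec, "benchmark_spec"))
  set.seed(spec$seed)
  seqs <- list(); labels <- character(0L)
  for (i in seq_along(spec$profiles)) {
    prof <- spec$profiles[[i]]
    ids <- sprintf("%s_%04d", prof$name, seq_len(spec$counts[i]))
    seqs <- c(seqs, lapply(ids, function(id) generate_sequence(prof, id)))
    labels <- c(labels, rep(prof$name, spec$counts[i]))
  }
  names(seqs) <- vapply(seqs, `[[`, character(1L), "id")
  labeled_dataset(seqs, labels,
                  label_set = vapply(spec$profiles, `[[`, character(1L),
                                     "name"))
}

#' Default per-family biased pairs for the six-family benchmark
#'
#' Each family receives four unique (residue, residue, gap) signatures, one
#' per gap 0-3, at the given multiplier; the non-HSP profile carries none.
#' @keywords internal
family_pair_table <- function(mult = 8) {
  pairs <- list(
    HSP20  = list(c("A", "C"), c("D", "E"), c("F", "G"), c("H", "I")),
    HSP40  = list(c("K", "L"), c("M", "N"), c("P", "Q"), c("R", "S")),
    HSP60  = list(c("T", "V"), c("W", "Y"), c("A", "E"), c("C", "G")),
    HSP70  = list(c("D", "I"), c("F", "K"), c("H", "M"), c("L", "P")),
    HSP90  = list(c("N", "R"), c("Q", "T"), c("S", "W"), c("V", "A")),
    HSP100 = list(c("Y", "C"), c("E", "H"), c("G", "K"), c("I", "N")))
  lapply(pairs, function(ps) {
    data.frame(a = vapply(ps, `[[`, character(1L), 1L),
               b = vapply(ps, `[[`, character(1L), 2L),
               gap = 0:3, mult = mult)
  })
}

#' The six-family + non-HSP benchmark with realistic class imbalance
#'
#' Builds a benchmark whose positive class counts follow the heavily
#' imbalanced composition of curated HSP family collections (354 HSP20,
#' 1257 HSP40, 159 HSP60, 278 HSP70, 52 HSP90, 81 HSP100), plus a
#' signal-free non-HSP class. Each family plants four unique gapped pairs
#' (gaps 0-3) at the given multiplier over a uniform background.
#'
#' @param mult Enrichment multiplier (> 1); 8 gives a strong, cleanly
#'   recoverable signal, 1 + epsilon approaches the null.
#' @param n_neg Number of non-HSP sequences (default 2181, matching the
#'   positive total for a balanced stage-1 problem).
#' @param counts Named positive-class counts (default as above).
#' @param length_range Sequence length range passed to every profile.
#' @param seed Benchmark seed.
#' @return A `benchmark_spec`; pass to [generate_benchmark()].
#' @export
hsp_benchmark_spec <- function(mult = 8, n_neg = 2181L,
                               counts = c(HSP20 = 354L, HSP40 = 1257L,
                                          HSP60 = 159L, HSP70 = 278L,
                                          HSP90 = 52L, HSP100 = 81L),
                               length_range = c(80L, 600L), seed = 1L) {
  pair_tab <- family_pair_table(mult)
  profiles <- lapply(names(counts), function(fam) {
    family_profile(fam, biased_pairs = pair_tab[[fam]],
                   length_range = length_range)
  })
  profiles <- c(profiles,
                list(family_profile("non-HSP",
                                    length_range = length_range)))
  benchmark_spec(profiles, c(unname(counts), as.integer(n_neg)),
                 seed = seed)
}

#' A null benchmark: identical signal-free profiles
#'
#' All classes share one background distribution and carry no biased pairs,
#' so no classifier can beat chance. Used as the no-signal calibration.
#'
#' @param classes Class labels.
#' @param n_per_class Sequences per class.
#' @param length_range Length range.
#' @param seed Benchmark seed.
#' @return A `benchmark_spec`.
#' @export
null_benchmark_spec <- function(classes = c("HSP", "non-HSP"),
                                n_per_class = 200L,
                                length_range = c(80L, 600L), seed = 1L) {
  profiles <- lapply(classes, family_profile,
                     length_range = length_range)
  benchmark_spec(profiles, rep(as.integer(n_per_class), length(classes)),
                 seed = seed)
}

#' Synthetic DnaJ sub-type benchmark
#'
#' Four classes shaped like curated DnaJ collections (63 Type-I, 53
#' Type-II, 1107 Type-III, 22 Type-IV), each with its own planted pair
#' signatures.
#'
#' @inheritParams hsp_benchmark_spec
#' @param counts Named per-type counts.
#' @return A `benchmark_spec`.
#' @export
dnaj_benchmark_spec <- function(mult = 8,
                                counts = c("Type-I" = 63L, "Type-II" = 53L,
                                           "Type-III" = 1107L,
                                           "Type-IV" = 22L),
                                length_range = c(80L, 600L), seed = 1L) {
  pairs <- list(
    "Type-I"   = list(c("A", "D"), c("C", "F")),
    "Type-II"  = list(c("E", "G"), c("H", "K")),
    "Type-III" = list(c("I", "M"), c("L", "N")),
    "Type-IV"  = list(c("P", "R"), c("Q", "S")))
  profiles <- lapply(names(counts), function(ty) {
    ps <- pairs[[ty]]
    bp <- data.frame(a = vapply(ps, `[[`, character(1L), 1L),
                     b = vapply(ps, `[[`, character(1L), 2L),
                     gap = c(0L, 1L), mult = mult)
    family_profile(ty, biased_pairs = bp, length_range = length_range)
  })
  benchmark_spec(profiles, unname(counts), seed = seed)
}
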