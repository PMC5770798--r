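## Internal: residue string -> integer codes 1..20 in AA_ALPHABET order
aa_codes <- function(seq) {
  stopifnot(inherits(seq, "protein_sequence"))
  match(strsplit(seq$residues, "")[[1L]], AA_ALPHABET)
}

#' G-spaced amino-acid pair composition (GPC)
#'
#' The frequency of every ordered amino-acid pair whose members sit G
#' skipped residues apart: a pair occupies positions p and p + G + 1, so
#' G = 0 is the ordinary dipeptide composition. For a sequence of length N
#' there are exactly N - G - 1 such pairs, and each of the 400 descriptors is
#'
#'   f_G(i, j) = D_G(i, j) / (N - G - 1),
#'
#' where D_G(i, j) counts pairs with residue i first and residue j second.
#' The 400 values therefore sum to 1. Descriptor names follow
#' `g{G}_{a}{b}` in row-major alphabetical order (AA, AC, ..., YY).
#'
#' @param seq A [protein_sequence()].
#' @param G Non-negative integer gap (number of skipped residues).
#' @return Named numeric vector of length 400.
#' @export
gpc <- function(seq, G = 0L) {
  G <- as.integer(G)
  stopifnot(G >= 0L)
  n_pairs <- seq$length - G - 1L
  if (n_pairs < 1L) {
    stop("sequence '", seq$id, "' too short for gap ", G,
         ": length N = ", seq$length, " requires N >= ", G + 2L)
  }
  codes <- aa_codes(seq)
  first <- codes[seq_len(n_pairs)]
  second <- codes[seq_len(n_pairs) + G + 1L]
  counts <- tabulate((first - 1L) * 20L + second, nbins = 400L)
  out <- counts / n_pairs
  names(out) <- paste0("g", G, "_",
                       rep(AA_ALPHABET, each = 20L),
                       rep(AA_ALPHABET, times = 20L))
  out
}

#' Concatenated GPC over a set of gaps
#'
#' Concatenates [gpc()] blocks for each gap in ascending order; with the
#' default gaps 0-3 this is the 1,600-dimensional "GPC-0123" encoding. Each
#' 400-descriptor block sums to 1 independently.
#'
#' @inheritParams gpc
#' @param gaps Integer vector of gaps.
#' @return Named numeric vector of length `400 * length(gaps)`.
#' @export
gpc_combined <- function(seq, gaps = 0:3) {
  gaps <- sort(unique(as.integer(gaps)))
  unlist(lapply(gaps, function(G) gpc(seq, G)))
}

#' PAAC configuration
#'
#' @param d Number of correlation tiers (sequence-order depth); must be
#'   smaller than the length of every sequence it is applied to.
#' @param w Positive weight of the sequence-order terms relative to the
#'   composition terms; 0.05 is the classical convention.
#' @param property An [aa_property_table()] supplying the residue property
#'   behind the correlation function; defaults to Kyte-Doolittle hydropathy.
#' @return Object of class `paac_config`.
#' @export
paac_config <- function(d = 1L, w = 0.05,
                        property = bundled_properties("hydrophobicity_KD")[[1L]]) {
  d <- as.integer(d)
  if (d < 1L) stop("d must be a positive integer")
  if (!is.numeric(w) || w <= 0) stop("w must be > 0")
  stopifnot(inherits(property, "aa_property_table"))
  structure(list(d = d, w = w, property = property), class = "paac_config")
}

#' Pseudo amino-acid composition (PAAC)
#'
#' Augments the 20 amino-acid occurrence counts f_x with d sequence-order
#' correlation factors. The property values are standardized to zero mean
#' and unit root-mean-square deviation over the alphabet, giving
#' Theta(psi); the tier-j factor is
#'
#'   rho_j = (1 / (L - j)) * sum_i [Theta(psi_i) - Theta(psi_{i+j})]^2 .
#'
#' The final vector shares one denominator, sum(f) + w * sum(rho):
#' entries 1..20 are f_x over it, entries 21..20+d are w * rho_{x-20} over
#' it, so all 20 + d entries are non-negative and sum to 1. f_x here is the
#' raw occurrence count (Chou's original convention), which is what makes
#' the sum-to-one identity exact.
#'
#' @param seq A [protein_sequence()].
#' @param config A [paac_config()].
#' @return Named numeric vector of length `20 + config$d`.
#' @export
paac <- function(seq, config = paac_config()) {
  stopifnot(inherits(config, "paac_config"))
  L <- seq$length
  d <- config$d
  if (L <= d) {
    stop("sequence '", seq$id, "' too short for PAAC: L = ", L,
         " must exceed d = ", d)
  }
  theta_std <- standardize_property(config$property)
  codes <- aa_codes(seq)
  th <- theta_std[codes]
  rho <- vapply(seq_len(d), function(j) {
    mean((th[seq_len(L - j)] - th[seq_len(L - j) + j])^2)
  }, numeric(1L))
  f <- tabulate(codes, nbins = 20L)
  denom <- sum(f) + config$w * sum(rho)
  out <- c(f, config$w * rho) / denom
  names(out) <- c(paste0("paac_", AA_ALPHABET),
                  paste0("paac_tier", seq_len(d)))
  out
}

#' Composition-transition-distribution (CTD) descriptors
#'
#' For each physicochemical attribute in the scheme, residues are mapped to
#' one of three groups and 21 descriptors are computed:
#' \describe{
#'   \item{C (3)}{fraction of residues falling in each group (sums to 1).}
#'   \item{T (3)}{for each unordered group pair (1,2), (1,3), (2,3), the
#'     number of adjacent residue pairs whose members fall in the two groups
#'     in either order, divided by N - 1.}
#'   \item{D (15)}{per group, the 1-based positions of the first, 25\%,
#'     50\%, 75\% and last residue of that group, each divided by N. The
#'     q-quantile position is that of the `ceiling(q * count)`-th
#'     occurrence. All five values are 0 for a group absent from the
#'     sequence.}
#' }
#'
#' @param seq A [protein_sequence()].
#' @param scheme A `ctd_scheme` (default: [default_ctd_scheme()], 7
#'   attributes, hence 147 descriptors).
#' @return Named numeric vector of length `21 * length(scheme)`.
#' @export
ctd <- function(seq, scheme = default_ctd_scheme()) {
  stopifnot(inherits(scheme, "ctd_scheme"))
  N <- seq$length
  if (N < 2L) {
    stop("sequence '", seq$id,
         "' too short for CTD transitions: N must be >= 2")
  }
  chars <- strsplit(seq$residues, "")[[1L]]
  out <- unlist(lapply(names(scheme), function(attr) {
    groups <- scheme[[attr]]
    gidx <- integer(20L)
    for (g in 1:3) gidx[match(groups[[g]], AA_ALPHABET)] <- g
    gs <- gidx[match(chars, AA_ALPHABET)]
    comp <- tabulate(gs, nbins = 3L) / N
    a <- gs[-N]; b <- gs[-1L]
    lo <- pmin(a, b); hi <- pmax(a, b)
    trans <- c(sum(lo == 1L & hi == 2L),
               sum(lo == 1L & hi == 3L),
               sum(lo == 2L & hi == 3L)) / (N - 1L)
    dist <- unlist(lapply(1:3, function(g) {
      pos <- which(gs == g)
      n <- length(pos)
      if (n == 0L) return(numeric(5L))
      pos[c(1L, ceiling(c(0.25, 0.5, 0.75) * n), n)] / N
    }))
    vals <- c(comp, trans, dist)
    names(vals) <- paste0(attr, "_",
                          c("C1", "C2", "C3", "T12", "T13", "T23",
                            paste0("D", rep(1:3, each = 5L),
                                   rep(c("first", "p25", "p50", "p75",
                                         "p100"), times = 3L))))
    vals
  }))
  out
}

#' Autocorrelation function (ACF) descriptors
#'
#' For each residue property table (standardized exactly as PAAC
#' standardizes its property: zero mean, unit root-mean-square deviation
#' over the alphabet) and each lag j in 1..order, the descriptor is the mean
#' lagged product along the sequence:
#'
#'   acf_u(j) = (1 / (N - j)) * sum_{i=1}^{N-j} u(psi_i) * u(psi_{i+j}) .
#'
#' With the full 531-entry AAindex collection and order n this yields
#' 531 * n descriptors; the bundled default collection gives 5 * n.
#'
#' @param seq A [protein_sequence()].
#' @param indices Named list of [aa_property_table()] (an AAindex-style
#'   collection); defaults to [bundled_properties()].
#' @param order Highest lag n; must be smaller than the sequence length.
#' @return Named numeric vector of length `length(indices) * order`,
#'   grouped by table, lags ascending within each table.
#' @export
acf_features <- function(seq, indices = bundled_properties(), order = 1L) {
  order <- as.integer(order)
  stopifnot(order >= 1L)
  N <- seq$length
  if (N <= order) {
    stop("sequence '", seq$id, "' too short for ACF order ", order,
         ": N = ", N, " must exceed the order")
  }
  codes <- aa_codes(seq)
  out <- unlist(lapply(names(indices), function(nm) {
    u <- standardize_property(indices[[nm]])[codes]
    vals <- vapply(seq_len(order), function(j) {
      mean(u[seq_len(N - j)] * u[seq_len(N - j) + j])
    }, numeric(1L))
    names(vals) <- paste0(nm, "_lag", seq_len(order))
    vals
  }))
  out
}

#' Encoder constructors
#'
#' An encoder bundles one of the descriptor families with its parameters so
#' datasets, models and the CLI can share a single feature-space definition.
#' Each constructor returns an object of class `hsp_encoder` with a `name`
#' and an `encode(seq)` function producing a named numeric vector.
#'
#' @param gaps Integer gaps for the GPC family.
#' @param config A [paac_config()].
#' @param scheme A `ctd_scheme`.
#' @param indices Property table collection for ACF.
#' @param order ACF order.
#' @return An `hsp_encoder`.
#' @name encoders
NULL

new_encoder <- function(name, encode, params = list()) {
  structure(list(name = name, encode = encode, params = params),
            class = "hsp_encoder")
}

#' @rdname encoders
#' @export
gpc_encoder <- function(gaps = 0:3) {
  gaps <- sort(unique(as.integer(gaps)))
  new_encoder(paste0("gpc", paste(gaps, collapse = "")),
              function(seq) gpc_combined(seq, gaps),
              list(gaps = gaps))
}

#' @rdname encoders
#' @export
paac_encoder <- function(config = paac_config()) {
  new_encoder("paac", function(seq) paac(seq, config), list(config = config))
}

#' @rdname encoders
#' @export
ctd_encoder <- function(scheme = default_ctd_scheme()) {
  new_encoder("ctd", function(seq) ctd(seq, scheme), list(scheme = scheme))
}

#' @rdname encoders
#' @export
acf_encoder <- function(indices = bundled_properties(), order = 1L) {
  new_encoder(paste0("acf", order),
              function(seq) acf_features(seq, indices, order),
              list(indices = indices, order = order))
}

#' @exportS3Method base::print
print.hsp_encoder <- function(x, ...) {
  cat("<hsp_encoder>", x$name, "\n")
  invisible(x)
}

#' Encode a dataset into a feature matrix
#'
#' Applies an encoder to every sequence, one row per sequence in input
#' order, columns named by the encoder. If any sequence violates the
#' encoder's preconditions (e.g. too short for the largest gap), the error
#' reports every failing sequence id, not just the first.
#'
#' @param data A `labeled_dataset` or a plain list of `protein_sequence`.
#' @param encoder An `hsp_encoder`.
#' @return Numeric matrix with rownames = sequence ids; the dataset's
#'   labels, if any, are attached as attribute `labels`.
#' @export
encode_dataset <- function(data, encoder) {
  stopifnot(inherits(encoder, "hsp_encoder"))
  seqs <- if (inherits(data, "labeled_dataset")) data$sequences else data
  labels <- if (inherits(data, "labeled_dataset")) data$labels else NULL
  rows <- vector("list", length(seqs))
  errs <- character(0L)
  for (i in seq_along(seqs)) {
    rows[[i]] <- tryCatch(encoder$encode(seqs[[i]]),
                          error = function(e) {
                            errs[[length(errs) + 1L]] <<-
                              conditionMessage(e)
                            NULL
                          })
  }
  if (length(errs) > 0L) {
    stop("encoding failed for ", length(errs), " sequence(s):\n  ",
         paste(errs, collapse = "\n  "))
  }
  if (length(rows) == 0L) {
    template <- NULL
    # derive column names from a minimal probe sequence
    probe <- protein_sequence("probe",
                              paste(rep(AA_ALPHABET, 3L), collapse = ""))
    template <- encoder$encode(probe)
    mat <- matrix(numeric(0L), nrow = 0L, ncol = length(template),
                  dimnames = list(NULL, names(template)))
    return(mat)
  }
  mat <- do.call(rbind, rows)
  rownames(mat) <- vapply(seqs, `[[`, character(1L), "id")
  if (!is.null(labels)) attr(mat, "labels") <- labels
  mat
}
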