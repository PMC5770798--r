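#' Construct an amino-acid property table
#'
#' One real value per standard amino acid, e.g. a hydropathy scale or an
#' AAindex entry. Used as the residue property behind the PAAC correlation
#' factors and the ACF autocorrelation descriptors.
#'
#' @param name Short name of the property.
#' @param values Named numeric vector; names must be exactly the 20 standard
#'   one-letter codes (any order).
#' @return Object of class `aa_property_table`.
#' @export
aa_property_table <- function(name, values) {
  if (is.null(names(values)) || !setequal(names(values), AA_ALPHABET) ||
      length(values) != 20L) {
    stop("property '", name,
         "' must have exactly one value per standard amino acid")
  }
  if (any(!is.finite(values))) {
    stop("property '", name, "' contains non-finite values")
  }
  structure(list(name = name, values = values[AA_ALPHABET]),
            class = "aa_property_table")
}

#' Standardize a property table to zero mean and unit root-mean-square
#' deviation over the 20 amino acids
#'
#' The transform is (v - mean) / rms, where rms is the root of the mean
#' squared deviation over the 20 values (denominator 20, not 19). A constant
#' table has rms 0 and is an error, because the standardized values would be
#' undefined.
#'
#' @param table An `aa_property_table`.
#' @return Numeric vector of 20 standardized values named by amino acid.
#' @export
standardize_property <- function(table) {
  stopifnot(inherits(table, "aa_property_table"))
  v <- table$values
  m <- mean(v)
  rms <- sqrt(mean((v - m)^2))
  if (rms == 0) {
    stop("property '", table$name,
         "' is constant; zero-variance standardization is undefined")
  }
  (v - m) / rms
}

#' Read property tables from a TSV file
#'
#' Expected layout: header `property` then the 20 one-letter codes; one row
#' per property. This is the format of the bundled table file (see
#' [bundled_properties()]).
#'
#' @param path TSV path.
#' @return Named list of `aa_property_table` (an AAindex-style collection).
#' @export
read_property_tables <- function(path) {
  tab <- read.delim(path, header = TRUE, check.names = FALSE)
  if (!"property" %in% names(tab)) {
    stop("property file must have a 'property' column: ", path)
  }
  aas <- setdiff(names(tab), "property")
  out <- lapply(seq_len(nrow(tab)), function(i) {
    vals <- as.numeric(tab[i, aas])
    names(vals) <- aas
    aa_property_table(tab$property[i], vals)
  })
  names(out) <- tab$property
  out
}

#' Bundled classical property tables
#'
#' Ships a small set of classical residue property scales (Kyte-Doolittle
#' hydropathy, Hopp-Woods hydrophilicity, side-chain mass, Grantham
#' polarity, isoelectric point). These are the defaults behind PAAC and ACF;
#' a user-supplied AAindex-style TSV (e.g. the full 531-entry collection)
#' can be substituted via [read_property_tables()].
#'
#' @param which Optional character vector of property names to keep.
#' @return Named list of `aa_property_table`.
#' @export
bundled_properties <- function(which = NULL) {
  path <- system.file("extdata", "aa_properties.tsv", package = "hspkit",
                      mustWork = TRUE)
  tabs <- read_property_tables(path)
  if (!is.null(which)) {
    missing <- setdiff(which, names(tabs))
    if (length(missing) > 0L) {
      stop("no bundled property named: ", paste(missing, collapse = ", "))
    }
    tabs <- tabs[which]
  }
  tabs
}

#' Read a CTD grouping scheme from a TSV file
#'
#' Each row defines one physicochemical attribute as a partition of the 20
#' amino acids into three disjoint, exhaustive groups (columns `group1`,
#' `group2`, `group3`, each a string of one-letter codes).
#'
#' @param path TSV path.
#' @return Object of class `ctd_scheme`: a named list, one element per
#'   attribute, each a list of three character vectors.
#' @export
read_ctd_scheme <- function(path) {
  tab <- read.delim(path, header = TRUE)
  need <- c("attribute", "group1", "group2", "group3")
  if (!all(need %in% names(tab))) {
    stop("CTD scheme file must have columns ", paste(need, collapse = ", "))
  }
  scheme <- lapply(seq_len(nrow(tab)), function(i) {
    groups <- lapply(tab[i, c("group1", "group2", "group3")],
                     function(g) strsplit(as.character(g), "")[[1L]])
    all20 <- unlist(groups)
    if (anyDuplicated(all20) || !setequal(all20, AA_ALPHABET)) {
      stop("attribute '", tab$attribute[i],
           "': groups must partition the 20 amino acids")
    }
    groups
  })
  names(scheme) <- tab$attribute
  structure(scheme, class = "ctd_scheme")
}

#' The default seven-attribute CTD scheme
#'
#' The classical Dubchak-style grouping: hydrophobicity, normalized van der
#' Waals volume, polarity, polarizability, charge, secondary-structure
#' propensity and solvent accessibility, each splitting the alphabet into
#' three groups. Yields 7 x 21 = 147 descriptors.
#'
#' @return A `ctd_scheme`.
#' @export
default_ctd_scheme <- function() {
  read_ctd_scheme(system.file("extdata", "ctd_scheme.tsv",
                              package = "hspkit", mustWork = TRUE))
}
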