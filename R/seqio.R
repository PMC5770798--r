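#' Read a protein FASTA file into raw sequence records
#'
#' Parses a multi-record, multi-line FASTA file. Each header line (minus the
#' leading `">"`) is split at the first whitespace into an identifier and a
#' description; sequence lines are concatenated with all whitespace removed
#' and letters uppercased. No residue validation is performed at this stage:
#' see [validate_residues()] / [clean_dataset()].
#'
#' @param path Path to an existing FASTA file.
#' @return A list of raw records, each a list with elements `id`,
#'   `description` and `residues` (uppercase character string).
#' @seealso [clean_dataset()], [write_protein_fasta()]
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path)
  }
  first <- readLines(path, n = 50L, warn = FALSE)
  nonblank <- first[nzchar(trimws(first))]
  if (length(nonblank) == 0L) {
    stop("FASTA file is empty: ", path)
  }
  if (!startsWith(nonblank[[1L]], ">")) {
    stop("not FASTA: text before the first '>' header in ", path)
  }
  raw <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                            whole.header = TRUE)
  records <- lapply(raw, function(x) {
    header <- attr(x, "name")
    id <- sub("\\s.*$", "", header)
    description <- sub("^\\S+\\s*", "", header)
    residues <- toupper(gsub("\\s", "", as.character(x)))
    list(id = id, description = description, residues = residues)
  })
  names(records) <- vapply(records, `[[`, character(1L), "id")
  empty <- vapply(records, function(r) nchar(r$residues) == 0L, logical(1L))
  if (any(empty)) {
    stop("empty sequence record(s) in ", path, ": ",
         paste(names(records)[empty], collapse = ", "))
  }
  records
}

#' Construct a validated protein sequence
#'
#' @param id Sequence identifier.
#' @param residues Character string over the 20-letter standard amino-acid
#'   alphabet (uppercased before checking).
#' @return An object of class `protein_sequence` with fields `id`,
#'   `residues` and `length`.
#' @export
protein_sequence <- function(id, residues) {
  residues <- toupper(residues)
  if (nchar(residues) < 1L) {
    stop("protein sequence '", id, "' is empty")
  }
  bad <- setdiff(strsplit(residues, "")[[1L]], AA_ALPHABET)
  if (length(bad) > 0L) {
    stop("protein sequence '", id, "' contains non-standard residue(s): ",
         paste(sort(unique(bad)), collapse = ", "))
  }
  structure(list(id = id, residues = residues, length = nchar(residues)),
            class = "protein_sequence")
}

#' @exportS3Method base::print
print.protein_sequence <- function(x, ...) {
  cat("<protein_sequence>", x$id, "-", x$length, "aa\n")
  cat(substr(x$residues, 1L, 60L),
      if (x$length > 60L) "..." else "", "\n")
  invisible(x)
}

#' Validate the residues of one raw sequence record
#'
#' The standard-residue filter: only the 20 canonical amino acids are
#' admitted. Ambiguity codes (B, J, Z), unknowns (X), rare residues (O, U),
#' stops (`*`) and gaps (`-`) are all non-standard. Under `policy = "reject"`
#' an offending record yields a rejection object carrying the offending
#' characters; under `policy = "drop"` the caller is expected to exclude it
#' (see [clean_dataset()], which does so with a logged count).
#'
#' @param record A raw record from [read_fasta()], or anything with `id` and
#'   `residues` fields.
#' @param policy `"reject"` (default) or `"drop"`.
#' @return A [protein_sequence()] if all residues are standard; otherwise an
#'   object of class `residue_rejection` with fields `id`, `offending` and
#'   `policy`.
#' @export
validate_residues <- function(record, policy = c("reject", "drop")) {
  policy <- match.arg(policy)
  residues <- toupper(record$residues)
  if (is.null(residues) || nchar(residues) == 0L) {
    stop("record '", record$id, "' has an empty residue string")
  }
  bad <- setdiff(strsplit(residues, "")[[1L]], AA_ALPHABET)
  if (length(bad) > 0L) {
    return(structure(list(id = record$id,
                          offending = sort(unique(bad)),
                          policy = policy),
                     class = "residue_rejection"))
  }
  protein_sequence(record$id, residues)
}

#' Is an object a residue rejection record?
#' @param x Object to test.
#' @export
is_rejection <- function(x) inherits(x, "residue_rejection")

#' Validate a list of raw records into a clean sequence list
#'
#' Applies [validate_residues()] to every record. With `policy = "reject"`
#' (the default) any non-standard record is an error listing every offending
#' identifier and its offending characters, so data can never be lost
#' silently. With `policy = "drop"` offending records are excluded and their
#' count reported via `message()`, mirroring dataset-cleaning practice.
#'
#' @param records List of raw records (from [read_fasta()]).
#' @param policy `"reject"` or `"drop"`.
#' @return A named list of `protein_sequence` objects, with an attribute
#'   `n_dropped` giving the number of excluded records (0 under reject).
#' @export
clean_dataset <- function(records, policy = c("reject", "drop")) {
  policy <- match.arg(policy)
  checked <- lapply(records, validate_residues, policy = policy)
  rejected <- vapply(checked, is_rejection, logical(1L))
  if (any(rejected)) {
    if (policy == "reject") {
      msgs <- vapply(checked[rejected], function(r) {
        paste0(r$id, " [", paste(r$offending, collapse = ""), "]")
      }, character(1L))
      stop("non-standard residues in ", sum(rejected), " record(s): ",
           paste(msgs, collapse = "; "))
    }
    message("dropped ", sum(rejected),
            " record(s) with non-standard residues")
  }
  kept <- checked[!rejected]
  names(kept) <- vapply(kept, `[[`, character(1L), "id")
  attr(kept, "n_dropped") <- sum(rejected)
  kept
}

#' Read and validate a protein FASTA file in one step
#'
#' @inheritParams read_fasta
#' @inheritParams clean_dataset
#' @return Named list of `protein_sequence` objects.
#' @export
read_protein_fasta <- function(path, policy = c("reject", "drop")) {
  clean_dataset(read_fasta(path), policy = match.arg(policy))
}

#' Construct a labeled sequence dataset
#'
#' @param sequences List of `protein_sequence` objects.
#' @param labels Character vector of class labels, parallel to `sequences`.
#' @param label_set Declared label universe; defaults to the labels present.
#' @return Object of class `labeled_dataset` with fields `sequences`,
#'   `labels`, `label_set`.
#' @export
labeled_dataset <- function(sequences, labels, label_set = unique(labels)) {
  if (length(sequences) != length(labels)) {
    stop("sequences (", length(sequences), ") and labels (", length(labels),
         ") differ in length")
  }
  stray <- setdiff(unique(labels), label_set)
  if (length(stray) > 0L) {
    stop("label(s) outside the declared label set: ",
         paste(stray, collapse = ", "))
  }
  structure(list(sequences = sequences,
                 labels = as.character(labels),
                 label_set = label_set),
            class = "labeled_dataset")
}

#' @exportS3Method base::print
print.labeled_dataset <- function(x, ...) {
  cat("<labeled_dataset>", length(x$sequences), "sequences,",
      length(x$label_set), "classes\n")
  print(table(factor(x$labels, levels = x$label_set)))
  invisible(x)
}

#' Read a two-column (id, label) TSV into a named label vector
#'
#' @param path Path to a TSV with a header row and columns `id`, `label`.
#' @return Named character vector of labels.
#' @export
read_labels <- function(path) {
  tab <- read.delim(path, header = TRUE, colClasses = "character")
  if (!all(c("id", "label") %in% names(tab))) {
    stop("label table must have columns 'id' and 'label': ", path)
  }
  stats::setNames(tab$label, tab$id)
}

#' Write sequences to FASTA
#'
#' @param sequences List of `protein_sequence` objects (or a
#'   `labeled_dataset`, in which case its sequences are written).
#' @param path Output path.
#' @export
write_protein_fasta <- function(sequences, path) {
  if (inherits(sequences, "labeled_dataset")) sequences <- sequences$sequences
  seqinr::write.fasta(as.list(vapply(sequences, `[[`, character(1L),
                                     "residues")),
                      names = vapply(sequences, `[[`, character(1L), "id"),
                      file.out = path, nbchar = 60L)
  invisible(path)
}

#' Write a labeled dataset as FASTA plus label TSV
#'
#' @param data A `labeled_dataset`.
#' @param fasta_path,label_path Output paths.
#' @export
write_labeled_dataset <- function(data, fasta_path, label_path) {
  write_protein_fasta(data$sequences, fasta_path)
  tab <- data.frame(id = vapply(data$sequences, `[[`, character(1L), "id"),
                    label = data$labels)
  write.table(tab, label_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(data)
}

#' Read a labeled dataset from FASTA plus label TSV
#'
#' @param fasta_path FASTA of sequences.
#' @param label_path Two-column TSV (id, label).
#' @param label_set Optional declared label set.
#' @inheritParams clean_dataset
#' @export
read_labeled_dataset <- function(fasta_path, label_path, label_set = NULL,
                                 policy = "reject") {
  seqs <- read_protein_fasta(fasta_path, policy = policy)
  labs <- read_labels(label_path)
  missing <- setdiff(names(seqs), names(labs))
  if (length(missing) > 0L) {
    stop("no label for sequence(s): ", paste(missing, collapse = ", "))
  }
  labels <- unname(labs[names(seqs)])
  labeled_dataset(seqs, labels,
                  label_set = if (is.null(label_set)) unique(labels)
                              else label_set)
}

#' Write a feature matrix as a TSV table
#'
#' First column `id`, remaining columns the named features, written at full
#' round-trip precision (17 significant digits).
#'
#' @param matrix Numeric matrix with column names.
#' @param ids Character vector of row identifiers, one per row.
#' @param path Output path.
#' @export
write_feature_table <- function(matrix, ids, path) {
  if (nrow(matrix) != length(ids)) {
    stop("matrix has ", nrow(matrix), " rows but ", length(ids),
         " ids were given")
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("id", colnames(matrix)), collapse = "\t"), con)
  if (nrow(matrix) > 0L) {
    body <- apply(matrix, 1L, function(row) {
      paste(format(row, digits = 17, scientific = TRUE, trim = TRUE),
            collapse = "\t")
    })
    writeLines(paste(ids, body, sep = "\t"), con)
  }
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#'
#' @param path TSV path.
#' @return Numeric matrix with rownames set to the id column.
#' @export
read_feature_table <- function(path) {
  tab <- read.delim(path, header = TRUE, check.names = FALSE,
                    colClasses = NA)
  ids <- as.character(tab[["id"]])
  mat <- as.matrix(tab[, setdiff(names(tab), "id"), drop = FALSE])
  mode(mat) <- "double"
  rownames(mat) <- ids
  mat
}
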