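# Sequence containers and FASTA I/O.
#
# A SequenceSet is a light S3 container: a named character vector of
# residues plus a molecule tag ("aa" or "nt") and optional source strains.
# Parsing is delegated to Biostrings; validation (unique ids, non-empty,
# alphabet with error positions) is layered on top per this module's
# contract.

#' Construct a sequence set
#'
#' @param residues named character vector of sequences (names are ids).
#' @param molecule `"aa"` or `"nt"`.
#' @param source_strain optional character vector (recycled) naming the
#'   strain each sequence came from, e.g. `"KB-1"` or `"CBDB1"`.
#' @return an object of class `rdh_seqset`.
#' @export
sequence_set <- function(residues, molecule = c("nt", "aa"),
                         source_strain = NA_character_) {
  molecule <- match.arg(molecule)
  if (length(residues) == 0) stop("empty sequence set")
  ids <- names(residues)
  if (is.null(ids) || any(!nzchar(ids))) stop("all sequences must have ids")
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate sequence id: '", dup[1L], "'")
  residues <- toupper(residues)
  alphabet <- if (molecule == "nt") names(IUPAC_NT_MASK) else AA_ALPHABET
  for (i in seq_along(residues)) {
    if (!nzchar(residues[[i]])) stop("sequence '", ids[i], "' is empty")
    ch <- strsplit(residues[[i]], "", fixed = TRUE)[[1]]
    bad <- which(!(ch %in% alphabet))
    if (length(bad)) {
      stop("sequence '", ids[i], "': residue '", ch[bad[1L]],
           "' outside ", molecule, " alphabet at position ", bad[1L])
    }
  }
  structure(
    list(residues = residues, molecule = molecule,
         source_strain = rep_len(as.character(source_strain), length(residues))),
    class = "rdh_seqset")
}

#' @export
length.rdh_seqset <- function(x) length(x$residues)

#' @export
names.rdh_seqset <- function(x) names(x$residues)

#' @export
`[.rdh_seqset` <- function(x, i) {
  sequence_set(x$residues[i], x$molecule, x$source_strain[i])
}

#' @export
print.rdh_seqset <- function(x, ...) {
  cat("SequenceSet of", length(x), x$molecule, "sequences\n")
  n <- min(length(x), 6L)
  for (i in seq_len(n)) {
    cat(sprintf("  %-20s %6d residues\n", names(x)[i], nchar(x$residues[i])))
  }
  if (length(x) > n) cat("  ...\n")
  invisible(x)
}

#' Lengths of the sequences in a set
#' @param seqs an `rdh_seqset`.
#' @return named integer vector of residue counts.
#' @export
seq_lengths <- function(seqs) {
  stopifnot(inherits(seqs, "rdh_seqset"))
  setNames(nchar(seqs$residues), names(seqs))
}

#' Read sequences from a FASTA file
#'
#' Ids are the header tokens before the first whitespace; records keep file
#' order. Duplicate ids, empty files and residues outside the IUPAC
#' alphabet (degenerate nucleotide codes allowed) are hard errors.
#'
#' @param path path to a FASTA file.
#' @param molecule `"nt"` or `"aa"`.
#' @return an `rdh_seqset`.
#' @export
read_fasta <- function(path, molecule = c("nt", "aa")) {
  molecule <- match.arg(molecule)
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) stop("empty FASTA file: ", path)
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L)
  res <- setNames(as.character(set), ids)
  sequence_set(res, molecule)
}

#' Write a sequence set to FASTA
#'
#' Lines are wrapped at 60 columns.
#'
#' @param seqs an `rdh_seqset`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(inherits(seqs, "rdh_seqset"))
  set <- Biostrings::BStringSet(seqs$residues)
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Split a set into full-length and partial sequences
#'
#' Sequences shorter than `min_nt` residues are set aside as partial, the
#' screening applied before phylogenetic comparison (callers scale `min_nt`
#' for amino-acid sets). Order is preserved in both outputs.
#'
#' @param seqs an `rdh_seqset`.
#' @param min_nt minimum residue count to keep (default 850 nucleotides).
#' @return list with elements `kept` and `excluded` (`excluded` may be
#'   `NULL` when nothing is filtered); also `excluded_ids`.
#' @export
filter_full_length <- function(seqs, min_nt = 850L) {
  stopifnot(inherits(seqs, "rdh_seqset"))
  len <- seq_lengths(seqs)
  drop <- len < min_nt
  list(
    kept = if (any(!drop)) seqs[!drop] else NULL,
    excluded = if (any(drop)) seqs[drop] else NULL,
    excluded_ids = names(seqs)[drop]
  )
}
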