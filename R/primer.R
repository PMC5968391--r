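# In-silico qPCR primer specificity screening.
#
# Matching is ungapped (Hamming) over every offset on both strands; a
# degenerate IUPAC base in primer or template counts as a match whenever
# the two expansion sets intersect. The annealing temperature is carried
# as metadata only (no thermodynamic model).

#' Construct a primer pair
#'
#' @param name assay name, e.g. `"KB1-14/vcrA"`.
#' @param fwd,rev primer sequences, 5'->3', IUPAC degenerate codes allowed.
#' @param annealing_temp annealing temperature in degrees C (metadata).
#' @param target_gene targeted gene name.
#' @return an object of class `rdh_primer_pair`.
#' @export
primer_pair <- function(name, fwd, rev, annealing_temp = NA_real_,
                        target_gene = NA_character_) {
  fwd <- toupper(fwd); rev <- toupper(rev)
  for (p in c(fwd, rev)) {
    len <- nchar(p)
    if (len < 10 || len > 40) stop("primer length ", len, " outside [10, 40]")
    nt_mask(strsplit(p, "", fixed = TRUE)[[1]])  # alphabet check
  }
  structure(list(name = name, fwd = fwd, rev = rev,
                 annealing_temp = annealing_temp, target_gene = target_gene),
            class = "rdh_primer_pair")
}

# minimum-mismatch ungapped scan of one primer against one strand;
# returns all offsets' mismatch counts (vector over 0-based offsets)
scan_strand <- function(pmask, tmask) {
  np <- length(pmask); nt <- length(tmask)
  n_off <- nt - np + 1L
  mm <- integer(n_off)
  for (k in seq_len(n_off)) {
    mm[k] <- sum(bitwAnd(pmask, tmask[k:(k + np - 1L)]) == 0L)
  }
  mm
}

#' Best ungapped match of a primer on a template
#'
#' Scans every offset on both strands and returns the minimum Hamming
#' mismatch count; degenerate bases match when their expansions intersect.
#' Ties prefer the forward strand, then the smallest offset.
#'
#' @param primer primer sequence (5'->3', IUPAC codes allowed).
#' @param template an `rdh_seqset` of length 1 (nt) or a nucleotide string.
#' @return list with `mismatches`, `position` (0-based offset of the
#'   primer's 5'-most aligned template base on the plus strand), `strand`
#'   (`"+"` or `"-"`).
#' @export
best_primer_match <- function(primer, template) {
  if (inherits(template, "rdh_seqset")) {
    stopifnot(length(template) == 1L, template$molecule == "nt")
    template <- unname(template$residues[[1]])
  }
  primer <- toupper(primer); template <- toupper(template)
  np <- nchar(primer); nt <- nchar(template)
  if (nt < np) stop("template (", nt, " nt) shorter than primer (", np, " nt)")
  pmask <- nt_mask(strsplit(primer, "", fixed = TRUE)[[1]])
  tmask <- nt_mask(strsplit(template, "", fixed = TRUE)[[1]])
  fwd_mm <- scan_strand(pmask, tmask)
  # minus strand: scan the reverse complement of the template
  rmask <- nt_mask(strsplit(revcomp(template), "", fixed = TRUE)[[1]])
  rev_mm <- scan_strand(pmask, rmask)

  best_f <- min(fwd_mm); best_r <- min(rev_mm)
  if (best_f <= best_r) {
    off <- which.min(fwd_mm) - 1L
    list(mismatches = best_f, position = off, strand = "+")
  } else {
    off_rc <- which.min(rev_mm) - 1L   # offset on the revcomp strand
    # report the plus-strand coordinate of the site's 5'-most base
    off <- nt - (off_rc + np)
    list(mismatches = best_r, position = off, strand = "-")
  }
}

#' Screen a primer pair against a sequence set
#'
#' One row per sequence. An amplicon is predicted when the forward primer's
#' best site lies on the plus strand upstream of the reverse primer's best
#' site on the minus strand; its length spans the forward 5' coordinate to
#' the reverse primer's 3'-most plus-strand coordinate, inclusive.
#'
#' @param pair an [primer_pair()].
#' @param seqs an `rdh_seqset` of nucleotide sequences.
#' @param max_mismatches largest per-primer mismatch count still treated
#'   as a binding site when calling an amplicon (default 2; a best match
#'   exists at every offset, so amplicon calling needs a plausibility
#'   cut-off). Mismatch counts themselves are always reported.
#' @return data frame with columns `sequence_id`, `fwd_mismatches`,
#'   `rev_mismatches`, `fwd_pos`, `rev_pos` (0-based), `orientation_ok`,
#'   `amplicon_length` (NA when no amplicon).
#' @export
screen_primer_pair <- function(pair, seqs, max_mismatches = 2L) {
  stopifnot(inherits(pair, "rdh_primer_pair"), inherits(seqs, "rdh_seqset"),
            seqs$molecule == "nt")
  rows <- lapply(seq_len(length(seqs)), function(i) {
    id <- names(seqs)[i]
    f <- best_primer_match(pair$fwd, seqs[i])
    r <- best_primer_match(pair$rev, seqs[i])
    ok <- f$strand == "+" && r$strand == "-" && r$position > f$position &&
      f$mismatches <= max_mismatches && r$mismatches <= max_mismatches
    amp <- NA_integer_
    if (ok) {
      rev_end <- r$position + nchar(pair$rev) - 1L  # rev 3'-most plus coord
      amp <- rev_end - f$position + 1L
    }
    data.frame(sequence_id = id,
               fwd_mismatches = f$mismatches, rev_mismatches = r$mismatches,
               fwd_pos = f$position, rev_pos = r$position,
               orientation_ok = ok, amplicon_length = amp,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Read a primer table
#'
#' TSV columns: `name`, `fwd`, `rev`, `annealing_temp_C`, `target_gene`
#' (extra columns ignored).
#'
#' @param path TSV file path.
#' @return list of [primer_pair()] objects.
#' @export
read_primer_table <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  lapply(seq_len(nrow(tab)), function(i) {
    primer_pair(tab$name[i], tab$fwd[i], tab$rev[i],
                if ("annealing_temp_C" %in% names(tab))
                  tab$annealing_temp_C[i] else NA_real_,
                if ("target_gene" %in% names(tab))
                  tab$target_gene[i] else NA_character_)
  })
}
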