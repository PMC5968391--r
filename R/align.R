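# Pairwise global alignment and percent identity.
#
# The dynamic-programming core (Gotoh, affine gaps, deterministic
# traceback preferring diagonal > up > left) lives in src/align.cpp. This
# file provides parameterization, the substitution schemes, and PID.
#
# Scoring conventions:
#   * a gap of length L costs gap_open + L * gap_extend; end gaps count;
#   * identity_nt: 1.9 for compatible bases (IUPAC expansions intersect),
#     0 otherwise;
#   * iub_nt: as identity_nt but transitions (A<->G, C<->T) score
#     1.9 * 0.5 = 0.95 (the DNA transition weight);
#   * protein_default: BLOSUM62.
# PID is matches / aligned_columns where both rows carry a residue; a
# degenerate nucleotide code never counts as an identity even against
# itself (conservative), nor does amino-acid X.

#' Alignment parameters
#'
#' @param gap_open gap opening penalty (default 10).
#' @param gap_extend gap extension penalty per residue (default 0.1).
#' @param substitution_scheme one of `"identity_nt"`, `"iub_nt"`,
#'   `"protein_default"`.
#' @return an object of class `rdh_align_params`.
#' @export
align_params <- function(gap_open = 10, gap_extend = 0.1,
                         substitution_scheme = c("iub_nt", "identity_nt",
                                                 "protein_default")) {
  substitution_scheme <- match.arg(substitution_scheme)
  if (!(gap_open >= gap_extend && gap_extend > 0)) {
    stop("require gap_open >= gap_extend > 0")
  }
  structure(list(gap_open = gap_open, gap_extend = gap_extend,
                 substitution_scheme = substitution_scheme),
            class = "rdh_align_params")
}

# substitution matrix + residue encoding for a scheme
scheme_matrix <- function(scheme) {
  if (scheme == "protein_default") {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    m <- e$BLOSUM62
    return(list(alphabet = rownames(m), matrix = unname(m)))
  }
  alpha <- names(IUPAC_NT_MASK)
  k <- length(alpha)
  masks <- unname(IUPAC_NT_MASK)
  m <- matrix(0, k, k)
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (bitwAnd(masks[i], masks[j]) != 0L) m[i, j] <- 1.9
    }
  }
  if (scheme == "iub_nt") {
    # transitions between unambiguous purines / pyrimidines down-weighted
    ti <- function(x, y) {
      (x == "A" && y == "G") || (x == "G" && y == "A") ||
        (x == "C" && y %in% c("T", "U")) || (x %in% c("T", "U") && y == "C")
    }
    for (i in seq_len(k)) {
      for (j in seq_len(k)) {
        if (ti(alpha[i], alpha[j])) m[i, j] <- 1.9 * 0.5
      }
    }
  }
  list(alphabet = alpha, matrix = m)
}

encode_seq <- function(x, alphabet) {
  ch <- strsplit(x, "", fixed = TRUE)[[1]]
  code <- match(ch, alphabet)
  if (anyNA(code)) {
    stop("residue '", ch[which(is.na(code))[1L]], "' not in scoring alphabet")
  }
  code
}

# does a pair of residues count as an identity for PID?
is_identity_pair <- function(ra, rb, molecule) {
  if (ra != rb) return(FALSE)
  if (molecule == "nt") {
    return(ra %in% c("A", "C", "G", "T", "U"))
  }
  ra != "X"
}

#' Optimal global alignment of two sequences
#'
#' Needleman-Wunsch with affine gap penalties (Gotoh). Traceback ties are
#' broken deterministically: diagonal, then up (gap in `b`), then left.
#'
#' @param a,b `rdh_seqset` objects of length 1, or single named character
#'   strings, of the same molecule type.
#' @param params an [align_params()] object; the default picks
#'   `"iub_nt"` for nucleotides and `"protein_default"` for amino acids.
#' @param molecule molecule type when `a`/`b` are bare strings.
#' @return an object of class `rdh_alignment` with fields `id_a`, `id_b`,
#'   `aligned_a`, `aligned_b`, `score`, `matches`, `aligned_columns`,
#'   `pid`.
#' @export
global_align <- function(a, b, params = NULL, molecule = NULL) {
  pick <- function(x, nm) {
    if (inherits(x, "rdh_seqset")) {
      stopifnot(length(x) == 1L)
      list(id = names(x), seq = unname(x$residues[[1]]), molecule = x$molecule)
    } else {
      stopifnot(is.character(x), length(x) == 1L)
      id <- if (!is.null(names(x))) names(x) else nm
      list(id = id, seq = toupper(unname(x)), molecule = molecule)
    }
  }
  ra <- pick(a, "a"); rb <- pick(b, "b")
  if (is.null(ra$molecule)) stop("molecule must be given for bare strings")
  if (!identical(ra$molecule, rb$molecule)) {
    stop("cannot align ", ra$molecule, " against ", rb$molecule)
  }
  mol <- ra$molecule
  if (!nzchar(ra$seq) || !nzchar(rb$seq)) stop("empty sequence")
  if (is.null(params)) {
    params <- align_params(substitution_scheme =
                             if (mol == "nt") "iub_nt" else "protein_default")
  }
  sm <- scheme_matrix(params$substitution_scheme)
  ea <- encode_seq(ra$seq, sm$alphabet)
  eb <- encode_seq(rb$seq, sm$alphabet)
  res <- gotoh_align(ea, eb, sm$matrix, params$gap_open, params$gap_extend)
  ga <- c("-", sm$alphabet)[res$path_a + 1L]
  gb <- c("-", sm$alphabet)[res$path_b + 1L]
  both <- res$path_a != 0L & res$path_b != 0L
  aligned_columns <- sum(both)
  matches <- 0L
  idx <- which(both)
  for (i in idx) {
    if (is_identity_pair(ga[i], gb[i], mol)) matches <- matches + 1L
  }
  pid <- if (aligned_columns > 0) matches / aligned_columns else 0
  structure(
    list(id_a = ra$id, id_b = rb$id,
         aligned_a = paste(ga, collapse = ""),
         aligned_b = paste(gb, collapse = ""),
         score = res$score, matches = matches,
         aligned_columns = aligned_columns, pid = pid,
         all_gap_overlap = aligned_columns == 0L),
    class = "rdh_alignment")
}

#' @export
print.rdh_alignment <- function(x, ...) {
  cat(sprintf("Global alignment %s vs %s: score %.2f, PID %.3f (%d/%d)\n",
              x$id_a, x$id_b, x$score, x$pid, x$matches, x$aligned_columns))
  invisible(x)
}

#' Percent identity of an alignment
#'
#' Defined as matches over columns where both rows carry a residue (gap
#' columns excluded from the denominator).
#'
#' @param r an `rdh_alignment`.
#' @return PID in `[0, 1]`. An all-gap overlap returns 0 with a warning.
#' @export
percent_identity <- function(r) {
  stopifnot(inherits(r, "rdh_alignment"))
  if (r$aligned_columns == 0L) {
    warning("all-gap overlap between ", r$id_a, " and ", r$id_b,
            "; PID reported as 0")
    return(0)
  }
  r$matches / r$aligned_columns
}
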