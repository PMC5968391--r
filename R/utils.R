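# Shared small utilities: IUPAC tables, geometric mean, adjusted Rand index.

# IUPAC nucleotide codes as A/C/G/T bitmasks (A=1, C=2, G=4, T=8).
IUPAC_NT_MASK <- c(
  A = 1L, C = 2L, G = 4L, T = 8L, U = 8L,
  R = 5L, Y = 10L, S = 6L, W = 9L, K = 12L, M = 3L,
  B = 14L, D = 13L, H = 11L, V = 7L, N = 15L
)

AA_ALPHABET <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F",
                 "P","S","T","W","Y","V","B","Z","X","*")

nt_mask <- function(x) {
  m <- IUPAC_NT_MASK[x]
  if (anyNA(m)) {
    bad <- which(is.na(m))[1L]
    stop("invalid nucleotide code '", x[bad], "' at position ", bad)
  }
  unname(m)
}

#' Reverse complement of a nucleotide string (IUPAC-aware)
#'
#' @param x a single nucleotide string, possibly containing degenerate codes.
#' @return the reverse complement as a string.
#' @export
revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", U = "A",
            R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
            B = "V", D = "H", H = "D", V = "B", N = "N")
  ch <- strsplit(toupper(x), "", fixed = TRUE)[[1]]
  out <- comp[ch]
  if (anyNA(out)) stop("invalid nucleotide code in revcomp: '",
                       ch[which(is.na(out))[1L]], "'")
  paste(rev(unname(out)), collapse = "")
}

geomean <- function(x) exp(mean(log(x)))

#' Adjusted Rand index between two partitions
#'
#' Measures agreement between two labelings of the same items; 1 means the
#' partitions are identical up to label permutation, 0 is the chance level.
#'
#' @param a,b vectors of cluster labels of equal length.
#' @return the adjusted Rand index.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  expected <- sum_a * sum_b / ch2(n)
  maxi <- (sum_a + sum_b) / 2
  if (abs(maxi - expected) < .Machine$double.eps) return(1)
  (sum_ij - expected) / (maxi - expected)
}

# collapse a character vector of flags into one comma-joined field
join_flags <- function(flags) {
  if (length(flags) == 0) "" else paste(sort(unique(flags)), collapse = ",")
}
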