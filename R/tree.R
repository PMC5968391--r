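# Distance trees: neighbor joining, midpoint rooting, Newick export.
#
# Trees are ape "phylo" objects throughout. NJ is implemented here (the
# Q-criterion tie-break and negative-branch handling are part of the
# contract); midpoint rooting delegates to phangorn for n >= 3 and is
# property-tested against an independent path-length computation.

#' Neighbor-joining tree from a distance matrix
#'
#' Classic Saitou-Nei agglomeration: each step joins the pair minimizing
#' `Q(i,j) = (n-2) d(i,j) - sum_k d(i,k) - sum_k d(j,k)`; branch lengths
#' use the standard split formula. Ties are broken by the lowest
#' (row, column) index pair. Negative branch lengths are clamped to zero
#' with the deficit moved to the sibling branch, so the joined pair's
#' distance is preserved.
#'
#' @param d symmetric distance matrix (or `dist`) with zero diagonal,
#'   `n >= 3`, labels as dimnames. A PID matrix is converted with
#'   `1 - PID` by [pid_dist()].
#' @return an unrooted `phylo` tree.
#' @export
nj_tree <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  n <- nrow(d)
  if (is.null(n) || n < 3) stop("need at least 3 taxa")
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-9))) {
    stop("distance matrix must be symmetric")
  }
  if (any(d < 0)) stop("negative input distance")
  labels <- rownames(d)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))

  frag <- paste0("p", seq_len(n))  # placeholder labels, restored after parse
  act <- seq_len(n)

  while (length(act) > 3) {
    m <- length(act)
    dm <- d
    r <- rowSums(dm)
    q <- (m - 2) * dm - outer(r, r, `+`)
    diag(q) <- Inf
    # lowest (row, col), i < j, lexicographic tie-break
    best <- NULL; bestq <- Inf
    for (i in seq_len(m - 1)) {
      for (j in seq.int(i + 1, m)) {
        if (q[i, j] < bestq - 1e-12) { bestq <- q[i, j]; best <- c(i, j) }
      }
    }
    i <- best[1]; j <- best[2]
    dij <- dm[i, j]
    li <- dij / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- dij - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    newfrag <- sprintf("(%s:%.12g,%s:%.12g)", frag[i], li, frag[j], lj)
    dnew <- (dm[i, ] + dm[j, ] - dij) / 2
    dnew <- pmax(dnew[-c(i, j)], 0)
    keep <- setdiff(seq_len(m), c(i, j))
    d <- rbind(cbind(dm[keep, keep, drop = FALSE], dnew),
               c(dnew, 0))
    frag <- c(frag[keep], newfrag)
    act <- seq_len(m - 1)
  }

  d12 <- d[1, 2]; d13 <- d[1, 3]; d23 <- d[2, 3]
  v <- c((d12 + d13 - d23) / 2, (d12 + d23 - d13) / 2, (d13 + d23 - d12) / 2)
  v <- pmax(v, 0)
  nwk <- sprintf("(%s:%.12g,%s:%.12g,%s:%.12g);",
                 frag[1], v[1], frag[2], v[2], frag[3], v[3])
  tr <- ape::read.tree(text = nwk)
  idx <- as.integer(sub("^p", "", tr$tip.label))
  tr$tip.label <- labels[idx]
  tr
}

#' Convert a PID matrix to a p-distance matrix
#'
#' The tree distance is `1 - PID` (no multiple-hit correction).
#'
#' @param m a PID matrix as from [pid_matrix()].
#' @return a distance matrix.
#' @export
pid_dist <- function(m) {
  d <- 1 - m
  diag(d) <- 0
  d
}

#' Root a tree at the midpoint of its longest leaf-to-leaf path
#'
#' The two mutually farthest leaves end up equidistant from the root.
#'
#' @param t an unrooted `phylo` with branch lengths.
#' @return a rooted `phylo`.
#' @export
midpoint_root <- function(t) {
  stopifnot(inherits(t, "phylo"))
  if (is.null(t$edge.length)) stop("tree has no branch lengths")
  if (sum(t$edge.length) <= 0) {
    warning("zero-length tree; rooting position is arbitrary")
    return(t)
  }
  n <- length(t$tip.label)
  if (n == 2) {
    half <- sum(t$edge.length) / 2
    t$edge.length <- rep(half, length(t$edge.length))
    return(t)
  }
  phangorn::midpoint(t)
}

#' Root-to-leaf depths of a rooted tree
#'
#' @param t a rooted `phylo`.
#' @return named numeric vector of path lengths from the root to each tip.
#' @export
leaf_depths <- function(t) {
  stopifnot(inherits(t, "phylo"))
  n <- length(t$tip.label)
  root <- n + 1L
  dn <- ape::dist.nodes(t)
  setNames(dn[root, seq_len(n)], t$tip.label)
}

quote_newick_label <- function(x) {
  needs <- grepl("[][(),:; \t']", x)
  x[needs] <- paste0("'", gsub("'", "''", x[needs]), "'")
  x
}

phylo_to_newick <- function(t, digits = 6) {
  n <- length(t$tip.label)
  children <- split(seq_len(nrow(t$edge)), t$edge[, 1])
  fmt <- paste0("%.", digits, "f")
  rec <- function(node) {
    if (node <= n) return(quote_newick_label(t$tip.label[node]))
    rows <- children[[as.character(node)]]
    parts <- vapply(rows, function(r) {
      paste0(rec(t$edge[r, 2]), ":", sprintf(fmt, t$edge.length[r]))
    }, character(1))
    paste0("(", paste(parts, collapse = ","), ")")
  }
  paste0(rec(n + 1L), ";")
}

#' Write a tree in Newick format
#'
#' Branch lengths are written with 6 decimal places; labels containing
#' Newick metacharacters are single-quoted.
#'
#' @param t a `phylo`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(t, path) {
  stopifnot(inherits(t, "phylo"))
  writeLines(phylo_to_newick(t), path)
  invisible(path)
}

#' Read a Newick tree (quoted labels supported)
#'
#' @param path file path, or use `text`.
#' @param text optional Newick string.
#' @return a `phylo`.
#' @export
read_newick <- function(path = NULL, text = NULL) {
  if (is.null(text)) text <- paste(readLines(path), collapse = "")
  # protect single-quoted labels from the parser, restore afterwards
  quoted <- regmatches(text, gregexpr("'(?:[^']|'')*'", text, perl = TRUE))[[1]]
  if (length(quoted)) {
    keys <- sprintf("RDHFPQL%dX", seq_along(quoted))
    for (i in seq_along(quoted)) {
      text <- sub(quoted[i], keys[i], text, fixed = TRUE)
    }
  }
  tr <- ape::read.tree(text = text)
  if (length(quoted)) {
    vals <- gsub("''", "'", substr(quoted, 2, nchar(quoted) - 1))
    hit <- match(tr$tip.label, keys)
    tr$tip.label[!is.na(hit)] <- vals[hit[!is.na(hit)]]
  }
  tr
}
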