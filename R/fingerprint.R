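# rdhA/16S gene-copy ratio fingerprints, abundance bins, Pearson/UPGMA
# two-way clustering.
#
# Each gene's ratio approximates the fraction of D. mccartyi genomes
# carrying it (the organism has a single 16S rRNA copy per genome).
# Censoring semantics: a gene below its MDL while 16S is quantifiable is
# "below_detection" (an upper bound, not zero); if 16S itself is below the
# MDL the whole profile is "undefined".

RATIO_BINS <- c("gt_0.6", "0.1_to_0.6", "0.01_to_0.1", "0.001_to_0.01",
                "lt_0.001", "nd")

#' Build a ratio profile for one sample
#'
#' @param measurements measurement rows for one sample (as produced by
#'   [quantify_plate()]), including the 16S target.
#' @param sixteen_s name of the 16S rRNA gene target (default `"Dhc16S"`).
#' @return an object of class `rdh_ratio_profile`: data frame `ratios`
#'   (`gene`, `ratio`, `status` in ok/below_detection/undefined),
#'   `sample_id`, `dhc_16s_copies`, `metadata`.
#' @export
compute_ratios <- function(measurements, sixteen_s = "Dhc16S") {
  sid <- unique(measurements$sample_id)
  if (length(sid) != 1) stop("measurements must belong to a single sample")
  s16 <- measurements[measurements$target == sixteen_s, , drop = FALSE]
  if (nrow(s16) != 1) stop("missing 16S target '", sixteen_s,
                           "' for sample ", sid)
  genes <- measurements[measurements$target != sixteen_s, , drop = FALSE]
  if (s16$censored) {
    tab <- data.frame(gene = genes$target, ratio = NA_real_,
                      status = "undefined", stringsAsFactors = FALSE)
    denom <- NA_real_
  } else {
    denom <- s16$copies_per_unit
    status <- ifelse(genes$censored, "below_detection", "ok")
    ratio <- ifelse(genes$censored, NA_real_, genes$copies_per_unit / denom)
    tab <- data.frame(gene = genes$target, ratio = ratio, status = status,
                      stringsAsFactors = FALSE)
    high <- !is.na(ratio) & ratio > 1
    if (any(high)) {
      attr(tab, "gt1_flag") <- tab$gene[high]
    }
  }
  structure(list(sample_id = sid, ratios = tab, dhc_16s_copies = denom,
                 metadata = list()),
            class = "rdh_ratio_profile")
}

#' Construct a ratio profile directly
#'
#' Convenience constructor for workflows that already have ratios (e.g.
#' published tables) rather than plate measurements.
#'
#' @param sample_id sample name.
#' @param ratios named numeric vector of gene ratios; `NA` entries are
#'   censored according to `status`.
#' @param status per-gene status, `"ok"`, `"below_detection"` or
#'   `"undefined"` (recycled; default `"ok"`, with `NA` ratios defaulting
#'   to `"below_detection"`).
#' @param dhc_16s_copies optional 16S denominator, metadata only here.
#' @return an `rdh_ratio_profile`.
#' @export
ratio_profile <- function(sample_id, ratios, status = NULL,
                          dhc_16s_copies = NA_real_) {
  genes <- names(ratios)
  if (is.null(genes)) stop("ratios must be named by gene")
  if (is.null(status)) {
    status <- ifelse(is.na(ratios), "below_detection", "ok")
  }
  status <- rep_len(status, length(ratios))
  if (!all(status %in% c("ok", "below_detection", "undefined"))) {
    stop("invalid status")
  }
  structure(list(sample_id = sample_id,
                 ratios = data.frame(gene = genes, ratio = unname(ratios),
                                     status = status, stringsAsFactors = FALSE),
                 dhc_16s_copies = dhc_16s_copies, metadata = list()),
            class = "rdh_ratio_profile")
}

#' @export
print.rdh_ratio_profile <- function(x, ...) {
  cat("Ratio profile for", x$sample_id, "(16S =",
      format(x$dhc_16s_copies, digits = 3), "copies/unit)\n")
  print(x$ratios, row.names = FALSE)
  invisible(x)
}

#' Bin a ratio into the heatmap abundance classes
#'
#' Half-open bins, lower edge inclusive: `[0.6, Inf)`, `[0.1, 0.6)`,
#' `[0.01, 0.1)`, `[0.001, 0.01)`, `(0, 0.001)`; censored values map to
#' `"nd"`.
#'
#' @param rho numeric ratio(s); `NA` means censored/undefined.
#' @return character bin labels.
#' @export
bin_ratio <- function(rho) {
  if (any(!is.na(rho) & rho < 0)) stop("negative ratio")
  out <- ifelse(is.na(rho), "nd",
         ifelse(rho >= 0.6, "gt_0.6",
         ifelse(rho >= 0.1, "0.1_to_0.6",
         ifelse(rho >= 0.01, "0.01_to_0.1",
         ifelse(rho >= 0.001, "0.001_to_0.01", "lt_0.001")))))
  out
}

# assemble a genes x samples ratio matrix from a list of profiles
profile_matrix <- function(profiles) {
  stopifnot(length(profiles) >= 1)
  genes <- unique(unlist(lapply(profiles, function(p) p$ratios$gene)))
  samples <- vapply(profiles, `[[`, character(1), "sample_id")
  m <- matrix(NA_real_, length(genes), length(samples),
              dimnames = list(genes, samples))
  status <- matrix("undefined", length(genes), length(samples),
                   dimnames = list(genes, samples))
  for (p in profiles) {
    idx <- match(p$ratios$gene, genes)
    m[idx, p$sample_id] <- p$ratios$ratio
    status[idx, p$sample_id] <- p$ratios$status
  }
  list(ratio = m, status = status)
}

#' Pearson similarity across samples or genes
#'
#' Correlations are computed on log10-transformed ratios; below-detection
#' entries are imputed at the floor `1e-4` (the decade below the lowest
#' heatmap bin); undefined entries are dropped pairwise. Distance is
#' `1 - r`.
#'
#' @param profiles list of `rdh_ratio_profile`s.
#' @param axis cluster `"samples"` or `"genes"`.
#' @param floor imputation value for censored ratios.
#' @return list with `similarity` (Pearson r matrix) and `distance`
#'   (`1 - r`).
#' @export
pearson_similarity <- function(profiles, axis = c("samples", "genes"),
                               floor = 1e-4) {
  axis <- match.arg(axis)
  pm <- profile_matrix(profiles)
  lg <- log10(pmax(pm$ratio, floor))
  lg[pm$status == "below_detection"] <- log10(floor)
  lg[pm$status == "undefined"] <- NA_real_
  x <- if (axis == "samples") lg else t(lg)   # columns = items
  items <- colnames(x)
  if (length(items) < 2) stop("need at least 2 ", axis)
  shared <- crossprod(!is.na(x))
  bad <- which(shared < 2 & upper.tri(shared), arr.ind = TRUE)
  if (nrow(bad)) {
    stop("similarity undefined for pair (", items[bad[1, 1]], ", ",
         items[bad[1, 2]], "): fewer than 2 shared defined entries")
  }
  r <- suppressWarnings(cor(x, use = "pairwise.complete.obs"))
  diag(r) <- 1
  list(similarity = r, distance = 1 - r)
}

#' UPGMA hierarchical clustering
#'
#' Classic unweighted pair-group agglomeration: the closest pair merges;
#' a merged cluster's distance to others is the size-weighted arithmetic
#' mean of its parts. Ties break to the lowest active index pair. The
#' result is `hclust`-compatible (with merge heights), plus the per-merge
#' cophenetic similarity percent `100 * (1 - height)` used to annotate
#' dendrogram branches.
#'
#' @param d symmetric distance matrix with zero diagonal (or `dist`).
#' @return object of classes `rdh_upgma` and `hclust`, with extra field
#'   `similarity_percent`.
#' @export
upgma <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  n <- nrow(d)
  if (is.null(n) || n < 2) stop("need at least 2 items")
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-9))) {
    stop("distance matrix must be symmetric")
  }
  labels <- rownames(d)
  if (is.null(labels)) labels <- paste0("i", seq_len(n))

  # active clusters: id (negative = singleton, positive = merge row), size
  id <- -seq_len(n)
  size <- rep(1L, n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  dm <- d
  for (step in seq_len(n - 1L)) {
    m <- length(id)
    best <- c(1L, 2L); bestd <- Inf
    for (i in seq_len(m - 1L)) {
      for (j in seq.int(i + 1L, m)) {
        if (dm[i, j] < bestd - 1e-12) { bestd <- dm[i, j]; best <- c(i, j) }
      }
    }
    i <- best[1L]; j <- best[2L]
    merge[step, ] <- sort(c(id[i], id[j]))
    height[step] <- bestd
    dnew <- (size[i] * dm[i, ] + size[j] * dm[j, ]) / (size[i] + size[j])
    keep <- setdiff(seq_len(m), c(i, j))
    dm <- rbind(cbind(dm[keep, keep, drop = FALSE], dnew[keep]),
                c(dnew[keep], 0))
    id <- c(id[keep], step)
    size <- c(size[keep], size[i] + size[j])
  }

  # leaf order by recursive traversal (left subtree first)
  ord <- integer(0)
  walk <- function(node) {
    if (node < 0) { ord <<- c(ord, -node); return(invisible()) }
    walk(merge[node, 1L]); walk(merge[node, 2L])
  }
  walk(n - 1L)

  structure(list(merge = merge, height = height, order = ord,
                 labels = labels, method = "upgma",
                 call = match.call(), dist.method = "euclidean",
                 similarity_percent = 100 * (1 - height)),
            class = c("rdh_upgma", "hclust"))
}

#' Two-way clustered heatmap table of binned ratios
#'
#' Genes and samples are ordered by their respective UPGMA dendrograms
#' (Pearson distance on log10 ratios), so reordering the input leaves the
#' output unchanged.
#'
#' @param profiles list of `rdh_ratio_profile`s (>= 2 samples and genes).
#' @return list with `bins` and `ratios` (genes x samples matrices in
#'   dendrogram order), `gene_dendrogram`, `sample_dendrogram`.
#' @export
heatmap_table <- function(profiles) {
  # canonicalize input order so the output depends only on the data
  ids <- vapply(profiles, `[[`, character(1), "sample_id")
  profiles <- profiles[order(ids)]
  profiles <- lapply(profiles, function(p) {
    p$ratios <- p$ratios[order(p$ratios$gene), , drop = FALSE]
    p
  })
  pm <- profile_matrix(profiles)
  sam <- upgma(pearson_similarity(profiles, "samples")$distance)
  gen <- upgma(pearson_similarity(profiles, "genes")$distance)
  gene_order <- gen$labels[gen$order]
  sample_order <- sam$labels[sam$order]
  ratios <- pm$ratio[gene_order, sample_order, drop = FALSE]
  bins <- matrix(bin_ratio(as.vector(ratios)), nrow(ratios),
                 dimnames = dimnames(ratios))
  list(bins = bins, ratios = ratios,
       gene_dendrogram = gen, sample_dendrogram = sam)
}

#' Write a fingerprint table
#'
#' Long-format TSV: `sample_id`, `gene`, `ratio`, `censor`, `bin`.
#'
#' @param profiles list of `rdh_ratio_profile`s.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_fingerprint <- function(profiles, path) {
  rows <- lapply(profiles, function(p) {
    data.frame(sample_id = p$sample_id, gene = p$ratios$gene,
               ratio = p$ratios$ratio, censor = p$ratios$status,
               bin = bin_ratio(p$ratios$ratio), stringsAsFactors = FALSE)
  })
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a fingerprint table back into profiles
#'
#' @param path TSV written by [write_fingerprint()].
#' @return list of `rdh_ratio_profile`s.
#' @export
read_fingerprint <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  lapply(split(tab, tab$sample_id), function(s) {
    structure(list(sample_id = s$sample_id[1],
                   ratios = data.frame(gene = s$gene, ratio = s$ratio,
                                       status = s$censor,
                                       stringsAsFactors = FALSE),
                   dhc_16s_copies = NA_real_, metadata = list()),
              class = "rdh_ratio_profile")
  })
}
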