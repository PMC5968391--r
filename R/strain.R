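# Minimum-strain inference from rdhA/16S ratio fingerprints.
#
# Model: each D. mccartyi strain carries a binary complement of panel
# genes and one 16S copy; a sample's ratio vector is then
# content %*% abundances with abundances on the unit simplex. The minimum
# number of strain columns that explains the observed vector within an
# absolute residual tolerance epsilon is the model-based minimum strain
# count. Assumptions: one 16S copy per genome, at most one copy of each
# panel gene per genome, panel completeness.
#
# Lower bound: k strains generate at most 2^k - 1 distinct positive
# subset sums of abundances, so L distinct ratio levels force
# k >= ceil(log2(L + 1)).
#
# Feasibility of a candidate gene->strain-subset assignment is decided by
# sum-constrained least squares with positivity and max-abs residual
# checked post hoc (a sufficient test; see the methods vignette).

#' Inference configuration
#'
#' @param tau_log10 level-merging tolerance in log10 units (default 0.3,
#'   about 2-fold).
#' @param epsilon absolute ratio residual tolerance (default 0.05).
#' @param k_max largest strain count searched exactly (default 5).
#' @param r_min Pearson threshold for co-variation (default 0.9).
#' @return an object of class `rdh_infer_config`.
#' @export
inference_config <- function(tau_log10 = 0.3, epsilon = 0.05, k_max = 5,
                             r_min = 0.9) {
  stopifnot(tau_log10 > 0, epsilon > 0, epsilon < 0.5, k_max >= 1)
  structure(list(tau_log10 = tau_log10, epsilon = epsilon,
                 k_max = as.integer(k_max), r_min = r_min),
            class = "rdh_infer_config")
}

defined_ratios <- function(profile) {
  r <- profile$ratios
  ok <- r$status == "ok" & !is.na(r$ratio)
  setNames(r$ratio[ok], r$gene[ok])
}

#' Distinct abundance levels in a ratio profile
#'
#' Greedy grouping of the defined ratios, in descending order, into levels
#' whose max/min span stays within `10^tau_log10`; the representative is
#' the geometric mean of the members. Censored genes are excluded.
#'
#' @param profile an `rdh_ratio_profile`.
#' @param cfg an [inference_config()].
#' @return object of class `rdh_level_set`: list `levels` of
#'   `(representative, members)` sorted descending, and count `L`.
#' @export
ratio_levels <- function(profile, cfg = inference_config()) {
  r <- sort(defined_ratios(profile), decreasing = TRUE)
  levels <- list()
  if (length(r)) {
    span <- 10^cfg$tau_log10
    cur_max <- r[1]; members <- r[1]
    for (x in r[-1]) {
      if (cur_max / x <= span) {
        members <- c(members, x)
      } else {
        levels[[length(levels) + 1L]] <-
          list(representative = geomean(members), members = members)
        cur_max <- x; members <- x
      }
    }
    levels[[length(levels) + 1L]] <-
      list(representative = geomean(members), members = members)
  }
  structure(list(levels = levels, L = length(levels)),
            class = "rdh_level_set")
}

#' Lower bound on the number of co-existing strains
#'
#' `ceil(log2(L + 1))` for `L` distinct ratio levels: k strains yield at
#' most `2^k - 1` distinct positive subset sums of their abundances.
#'
#' @param levels an `rdh_level_set` (or integer level count).
#' @return integer lower bound.
#' @export
min_strain_lower_bound <- function(levels) {
  L <- if (inherits(levels, "rdh_level_set")) levels$L else as.integer(levels)
  if (L <= 0) return(0L)
  as.integer(ceiling(log2(L + 1)))
}

# --- decomposition search ---------------------------------------------------

# sum-constrained least squares: minimize |M a - r|^2 s.t. sum(a) = 1.
# Returns NULL when the solution leaves the open simplex or the per-gene
# max-abs residual exceeds eps.
solve_abundances <- function(M, r, gene_rows, gene_r, eps) {
  k <- ncol(M)
  A <- rbind(2 * crossprod(M), rep(1, k))
  A <- cbind(A, c(rep(1, k), 0))
  b <- c(2 * crossprod(M, r), 1)
  a <- tryCatch(solve(A, b)[seq_len(k)], error = function(e) NULL)
  if (is.null(a)) return(NULL)
  if (any(a <= 1e-9)) return(NULL)
  resid <- max(abs(gene_rows %*% a - gene_r))
  if (resid > eps + 1e-9) return(NULL)
  list(abundances = as.numeric(a), residual = as.numeric(resid))
}

# bitmask -> binary row over k strains
mask_row <- function(mask, k) as.integer(bitwAnd(mask, bitwShiftL(1L, 0:(k - 1))) != 0L)

#' Minimum-strain decomposition of a ratio profile
#'
#' Exact desk-scale search: for k = 1, 2, ..., `k_max`, every assignment of
#' each gene to a non-empty subset of k strains is enumerated (genes whose
#' ratios agree within `epsilon/2` are tied to the same subset to keep the
#' search small; strain-relabeling symmetry is broken canonically). For
#' each assignment the abundance vector on the simplex is fitted and the
#' model accepted when all abundances are positive and the max-abs
#' residual over genes is at most `epsilon`. The smallest feasible k is
#' returned; among models at that k, the smallest residual wins, ties
#' going to the lexicographically smallest content matrix. Censored genes
#' are carried as all-zero content rows (absence satisfies their
#' upper-bound constraint); ratios above 1 are clipped to `1 + epsilon`
#' with a warning.
#'
#' @param profile an `rdh_ratio_profile` with at most 12 defined genes.
#' @param cfg an [inference_config()].
#' @return object of class `rdh_strain_model`: `k` (NA when no model at
#'   `k_max` fits; then `reported_k` is `">= k_max+1"`), `content`
#'   (genes x k binary matrix), `abundances`, `residual`, `lower_bound`,
#'   `feasible`.
#' @export
min_strain_decomposition <- function(profile, cfg = inference_config()) {
  r_all <- defined_ratios(profile)
  censored_genes <- profile$ratios$gene[profile$ratios$status == "below_detection"]
  if (length(r_all) == 0) stop("no defined ratios to decompose")
  if (length(r_all) > 12) stop("exact search supports at most 12 defined genes")
  if (any(r_all > 1)) {
    warning("ratios > 1 clipped to 1 + epsilon (possible cross-amplification)")
    r_all[r_all > 1] <- 1 + cfg$epsilon
  }
  lb <- min_strain_lower_bound(ratio_levels(profile, cfg))

  # dedup genes into groups with near-identical ratios (within epsilon/2)
  ordg <- order(r_all, decreasing = TRUE)
  vals <- r_all[ordg]
  grp <- integer(length(vals)); g <- 0L; gmax <- -Inf
  for (i in seq_along(vals)) {
    if (g == 0L || gmax - vals[i] > cfg$epsilon / 2) {
      g <- g + 1L; gmax <- vals[i]
    }
    grp[i] <- g
  }
  n_grp <- g
  grp_r <- vapply(split(vals, grp), mean, numeric(1))        # group targets
  gene_of_grp <- split(names(vals), grp)

  best <- NULL
  feasible_k <- NA_integer_

  match_gene_grp <- rep(seq_len(n_grp),
                        times = vapply(gene_of_grp, length, 1L))
  gene_r <- vals

  for (k in seq_len(cfg$k_max)) {
    masks <- seq_len(2^k - 1)
    rows_by_mask <- t(vapply(masks, mask_row, integer(k), k = k))

    # DFS over groups. Strain-relabeling symmetry is broken by requiring
    # the content-matrix columns (read top-down over groups) to be in
    # strictly decreasing binary order; `eq` tracks adjacent column pairs
    # still tied, so order violations prune early and ties remaining at
    # the leaf (duplicate columns) are rejected. Partial least squares
    # prunes assignments whose already-fixed rows cannot be met within
    # epsilon.
    assign <- integer(n_grp)
    recurse <- function(pos, eq) {
      for (mask in masks) {
        bits <- rows_by_mask[mask, ]
        eq2 <- eq
        violated <- FALSE
        if (k > 1) {
          for (s in which(eq)) {
            if (bits[s] < bits[s + 1L]) { violated <- TRUE; break }
            if (bits[s] > bits[s + 1L]) eq2[s] <- FALSE
          }
        }
        if (violated) next
        assign[pos] <<- mask
        pm <- rows_by_mask[assign[seq_len(pos)], , drop = FALSE]
        if (!partial_feasible(pm, grp_r[seq_len(pos)], k, cfg$epsilon)) next
        if (pos == n_grp) {
          if (any(eq2)) next            # duplicate strain columns
          M <- rows_by_mask[assign, , drop = FALSE]
          gr <- M[match_gene_grp, , drop = FALSE]
          sol <- solve_abundances(M, grp_r, gr, gene_r, cfg$epsilon)
          if (!is.null(sol)) {
            cand <- list(content = gr, abundances = sol$abundances,
                         residual = sol$residual)
            if (is.null(best) || sol$residual < best$residual - 1e-12 ||
                (abs(sol$residual - best$residual) <= 1e-12 &&
                   content_key(gr) < content_key(best$content))) {
              best <<- cand
            }
          }
        } else {
          recurse(pos + 1L, eq2)
        }
      }
    }
    best <- NULL
    recurse(1L, rep(TRUE, max(k - 1L, 0L)))
    if (!is.null(best)) { feasible_k <- k; break }
  }

  make_content <- function(content, k) {
    genes <- c(names(vals), censored_genes)
    m <- matrix(0L, length(genes), k,
                dimnames = list(genes, paste0("strain", seq_len(k))))
    if (!is.null(content)) m[seq_len(nrow(content)), ] <- content
    m
  }

  if (is.na(feasible_k)) {
    return(structure(list(
      k = NA_integer_, reported_k = paste0(">= ", cfg$k_max + 1L),
      content = NULL, abundances = NULL, residual = NA_real_,
      lower_bound = lb, feasible = FALSE, epsilon = cfg$epsilon),
      class = "rdh_strain_model"))
  }
  structure(list(
    k = feasible_k, reported_k = as.character(feasible_k),
    content = make_content(best$content, feasible_k),
    abundances = best$abundances, residual = best$residual,
    lower_bound = lb, feasible = TRUE, epsilon = cfg$epsilon),
    class = "rdh_strain_model")
}

content_key <- function(m) paste(as.integer(t(m)), collapse = "")

# cheap partial feasibility bound: the unconstrained least-squares SSE on
# the rows assigned so far lower-bounds any completion's SSE, and any
# point with max-abs residual <= eps has SSE <= p * eps^2. Pruning on the
# SSE (not on the LS fit's own max-abs, which is not a bound) is safe.
partial_feasible <- function(M, r, k, eps) {
  fit <- tryCatch(qr.solve(crossprod(M) + diag(1e-10, k), crossprod(M, r)),
                  error = function(e) NULL)
  if (is.null(fit)) return(TRUE)
  sse <- sum((M %*% fit - r)^2)
  sse <= nrow(M) * (eps + 1e-9)^2
}

#' @export
print.rdh_strain_model <- function(x, ...) {
  cat("Model-based minimum strain count:", x$reported_k,
      sprintf("(lower bound %d, residual %.4f)\n", x$lower_bound,
              if (is.na(x$residual)) NaN else x$residual))
  if (x$feasible) {
    cat("Abundances:", paste(sprintf("%.3f", x$abundances), collapse = ", "),
        "\n")
  }
  cat("Assumptions: one 16S copy per genome, one copy per rdhA per genome,",
      "panel completeness.\n")
  invisible(x)
}

#' Co-localization candidate gene groups
#'
#' Gene pairs whose log10 ratios co-vary (Pearson `r >= r_min`) at the
#' same magnitude (median |delta log10| <= `tau_log10`) across shared
#' samples are linked; maximal groups are the single-linkage components.
#' Pairs sharing fewer than 3 samples are skipped. Pairs of constant,
#' equal trajectories count as co-varying (r is undefined but the
#' magnitude criterion decides).
#'
#' @param profiles list of `rdh_ratio_profile`s (>= 3 samples).
#' @param cfg an [inference_config()].
#' @return list with `groups` (list of character vectors, size >= 2) and
#'   `pairs` (data frame of qualifying pairs with r and median offset).
#' @export
colocalization_candidates <- function(profiles, cfg = inference_config()) {
  pm <- profile_matrix(profiles)
  lg <- log10(pm$ratio)
  lg[pm$status != "ok"] <- NA_real_
  genes <- rownames(lg)
  if (ncol(lg) < 3) stop("need at least 3 samples")
  pairs <- list()
  edges <- list()
  for (i in seq_len(length(genes) - 1L)) {
    for (j in seq.int(i + 1L, length(genes))) {
      sh <- which(!is.na(lg[i, ]) & !is.na(lg[j, ]))
      if (length(sh) < 3) next
      xi <- lg[i, sh]; xj <- lg[j, sh]
      med_off <- median(abs(xi - xj))
      const_i <- stats::sd(xi) < 1e-12; const_j <- stats::sd(xj) < 1e-12
      if (const_i && const_j) {
        r <- 1  # flat, compared on magnitude only
      } else if (const_i || const_j) {
        next
      } else {
        r <- cor(xi, xj)
      }
      if (r >= cfg$r_min && med_off <= cfg$tau_log10) {
        pairs[[length(pairs) + 1L]] <- data.frame(
          gene_a = genes[i], gene_b = genes[j], r = r,
          median_abs_dlog10 = med_off, n_shared = length(sh),
          stringsAsFactors = FALSE)
        edges[[length(edges) + 1L]] <- c(i, j)
      }
    }
  }
  # single-linkage components over qualifying pairs
  parent <- seq_along(genes)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (e in edges) parent[find(e[1])] <- find(e[2])
  roots <- vapply(seq_along(genes), find, 1L)
  groups <- split(genes, roots)
  groups <- unname(groups[vapply(groups, length, 1L) >= 2])
  list(groups = groups,
       pairs = if (length(pairs)) do.call(rbind, pairs) else
         data.frame(gene_a = character(0), gene_b = character(0),
                    r = numeric(0), median_abs_dlog10 = numeric(0),
                    n_shared = integer(0)))
}

#' JSON export of strain inference over samples
#'
#' @param models named list of `rdh_strain_model`s (per sample).
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_strain_models <- function(models, path) {
  out <- lapply(models, function(m) {
    list(k = if (is.na(m$k)) NULL else m$k,
         reported_k = m$reported_k,
         lower_bound = m$lower_bound,
         residual = if (is.na(m$residual)) NULL else m$residual,
         abundances = m$abundances,
         content = if (is.null(m$content)) NULL else
           apply(m$content, 1, paste, collapse = ""),
         note = paste("model-based minimum; assumptions: one 16S copy per",
                      "genome, one copy per rdhA per genome, panel",
                      "completeness"))
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
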