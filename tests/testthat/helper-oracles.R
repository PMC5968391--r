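# Independent oracles used by the property tests. Each deliberately takes
# a different computational route than the package implementation.

# --- exhaustive global-alignment enumerator (affine gaps) -------------------
# Maximum score over all global alignments; gap of length L costs
# open + L * ext; terminal gaps are penalized. Exponential: sequences <= 8.
brute_align_score <- function(a, b, sub, alphabet, open, ext) {
  ea <- match(strsplit(a, "")[[1]], alphabet)
  eb <- match(strsplit(b, "")[[1]], alphabet)
  n <- length(ea); m <- length(eb)
  rec <- function(i, j, prev) {
    if (i > n && j > m) return(0)
    best <- -Inf
    if (i <= n && j <= m) {
      best <- max(best, sub[ea[i], eb[j]] + rec(i + 1, j + 1, "d"))
    }
    if (i <= n) {
      cost <- ext + if (prev == "u") 0 else open
      best <- max(best, -cost + rec(i + 1, j, "u"))
    }
    if (j <= m) {
      cost <- ext + if (prev == "l") 0 else open
      best <- max(best, -cost + rec(i, j + 1, "l"))
    }
    best
  }
  rec(1, 1, "none")
}

random_nt <- function(len) paste(sample(c("A", "C", "G", "T"), len,
                                        replace = TRUE), collapse = "")

# --- brute-force transitive closure for ortholog grouping -------------------
# Reachability by repeated boolean matrix multiplication.
brute_components <- function(pid, threshold) {
  adj <- pid > threshold
  diag(adj) <- TRUE
  reach <- adj
  repeat {
    nxt <- (reach %*% reach) > 0
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  # canonical partition: each item labeled by smallest reachable index
  apply(reach, 1, function(row) min(which(row)))
}

# --- naive O(n^3) UPGMA oracle ----------------------------------------------
# Cluster distances recomputed from the ORIGINAL matrix as the plain mean
# over all cross pairs (equivalent to the size-weighted recurrence but a
# different computation). Tie-break: lowest active index pair.
naive_upgma <- function(d) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))        # member index sets
  ids <- -seq_len(n)
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  for (step in seq_len(n - 1)) {
    m <- length(clusters)
    best <- NULL; bestd <- Inf
    for (i in seq_len(m - 1)) {
      for (j in seq.int(i + 1, m)) {
        dd <- mean(d[clusters[[i]], clusters[[j]]])
        if (dd < bestd - 1e-12) { bestd <- dd; best <- c(i, j) }
      }
    }
    i <- best[1]; j <- best[2]
    merge[step, ] <- sort(c(ids[i], ids[j]))
    height[step] <- bestd
    newc <- c(clusters[[i]], clusters[[j]])
    keep <- setdiff(seq_len(m), c(i, j))
    clusters <- c(clusters[keep], list(newc))
    ids <- c(ids[keep], step)
  }
  list(merge = merge, height = height)
}

random_dist <- function(n) {
  d <- matrix(0, n, n)
  d[upper.tri(d)] <- runif(n * (n - 1) / 2, 0.05, 1)
  d <- d + t(d)
  dimnames(d) <- list(paste0("i", 1:n), paste0("i", 1:n))
  d
}

# --- independent Pearson (textbook sum formula) -----------------------------
pearson_sums <- function(x, y) {
  n <- length(x)
  (n * sum(x * y) - sum(x) * sum(y)) /
    sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
}

# --- exhaustive strain-decomposition oracle ---------------------------------
# Enumerates EVERY binary content matrix genes x k (2^(G*k)), k = 1..k_max,
# solving abundances by variable elimination (a_k = 1 - sum of others),
# a different algebraic route than the package's Lagrange system.
oracle_solve <- function(M, r) {
  k <- ncol(M)
  if (k == 1) {
    a <- 1
  } else {
    B <- M[, -k, drop = FALSE] - M[, k]
    cc <- r - M[, k]
    sol <- tryCatch(qr.solve(crossprod(B) + diag(1e-12, k - 1),
                             crossprod(B, cc)),
                    error = function(e) NULL)
    if (is.null(sol)) return(NULL)
    a <- c(sol, 1 - sum(sol))
  }
  if (any(a <= 1e-9)) return(NULL)
  list(a = a, resid = max(abs(M %*% a - r)))
}

oracle_min_k <- function(r, eps, k_max = 3) {
  G <- length(r)
  for (k in seq_len(k_max)) {
    n_mat <- 2^(G * k)
    for (code in 0:(n_mat - 1)) {
      bits <- as.integer(intToBits(code))[seq_len(G * k)]
      M <- matrix(bits, G, k)
      cols <- apply(M, 2, paste, collapse = "")
      if (anyDuplicated(cols)) next
      sol <- oracle_solve(M, r)
      # same boundary convention as the implementation: eps + 1e-9
      if (!is.null(sol) && sol$resid <= eps + 1e-9) return(k)
    }
  }
  NA_integer_
}

# quick builder for profiles used across strain tests
prof <- function(ratios, sample_id = "s1", status = NULL) {
  ratio_profile(sample_id, ratios, status)
}

# shared noiseless community generator for recovery tests: k strains on a
# 6-gene panel with pairwise abundance gaps >= 0.15
recovery_instance <- function(seed) {
  set.seed(seed)
  k <- sample(1:3, 1)
  repeat {
    a <- sort(runif(k), decreasing = TRUE)
    a <- a / sum(a)
    if (k == 1 || min(abs(diff(a))) >= 0.15 && min(a) >= 0.15) break
  }
  panel <- paste0("g", 1:6)
  repeat {
    content <- matrix(sample(0:1, 6 * k, replace = TRUE), 6, k,
                      dimnames = list(panel, NULL))
    # a private marker gene per strain keeps the instance identifiable
    # (its ratio pins that strain's abundance)
    for (s in seq_len(k)) {
      content[s, ] <- 0L; content[s, s] <- 1L
    }
    cols <- apply(content, 2, paste, collapse = "")
    if (!anyDuplicated(cols)) break
  }
  ratios <- drop(content %*% a)
  list(k = k, a = a, content = content,
       profile = prof(setNames(ifelse(ratios == 0, NA, ratios), panel)))
}
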