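# Ortholog-group assignment from pairwise identities.
#
# Groups are connected components of the graph whose edges join pairs with
# PID strictly above the threshold (single linkage: the classification
# admits chains). Components of size one stay "ungrouped". A reference
# registry lets known sequences pin their published OG numbers; new groups
# continue numbering past the largest reference label, ordered by their
# alphabetically smallest member id. The minimum within-group PID is
# recorded per OG so a complete-linkage audit is possible.

#' All-pairs percent-identity matrix
#'
#' Aligns every pair in the set and records PID; symmetric with a unit
#' diagonal.
#'
#' @param seqs an `rdh_seqset` with at least two sequences.
#' @param params an [align_params()] object (default chosen by molecule).
#' @return a symmetric numeric matrix with sequence ids as dimnames.
#' @export
pid_matrix <- function(seqs, params = NULL) {
  stopifnot(inherits(seqs, "rdh_seqset"))
  n <- length(seqs)
  if (n < 2) stop("need at least 2 sequences")
  ids <- names(seqs)
  m <- diag(1, n)
  dimnames(m) <- list(ids, ids)
  for (i in seq_len(n - 1)) {
    for (j in seq.int(i + 1, n)) {
      al <- tryCatch(
        global_align(seqs[i], seqs[j], params),
        error = function(e) stop("alignment failed for pair (", ids[i], ", ",
                                 ids[j], "): ", conditionMessage(e)))
      m[i, j] <- m[j, i] <- al$pid
    }
  }
  m
}

parse_og_number <- function(label) {
  num <- suppressWarnings(as.integer(sub("^OG\\s*", "", label)))
  num
}

#' Assign sequences to ortholog groups
#'
#' @param m a symmetric PID matrix in `[0, 1]` with unit diagonal and
#'   sequence ids as dimnames.
#' @param threshold PID threshold; pairs strictly above it are linked
#'   (default 0.90, i.e. the >90 percent identity rule).
#' @param reference optional registry mapping known sequence ids to OG
#'   labels: a named character vector or a data frame with columns
#'   `sequence_id` and `og_label`. Labels are numbers, optionally prefixed
#'   `"OG"`.
#' @return an object of class `rdh_og_assignment` with fields
#'   `membership` (named character: id -> label), `registry` (per-OG member
#'   ids, provenance `"reference"`/`"new"`, and minimum within-OG PID),
#'   `ungrouped` (ids), `threshold`.
#' @export
assign_ortholog_groups <- function(m, threshold = 0.90, reference = NULL) {
  if (!is.matrix(m) || !isTRUE(all.equal(m, t(m), tolerance = 1e-12))) {
    stop("PID matrix must be symmetric")
  }
  if (any(m < 0 | m > 1)) stop("PID values must lie in [0, 1]")
  if (!(threshold > 0 && threshold < 1)) stop("threshold outside (0, 1)")
  ids <- rownames(m)
  if (is.null(ids)) stop("PID matrix needs sequence ids as dimnames")
  n <- length(ids)

  if (is.data.frame(reference)) {
    reference <- setNames(as.character(reference$og_label),
                          reference$sequence_id)
  }

  # connected components over edges PID > threshold (strict)
  adj <- m > threshold
  diag(adj) <- FALSE
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }

  groups <- split(seq_len(n), comp)
  singletons <- vapply(groups, length, 1L) == 1L
  ungrouped <- ids[unlist(groups[singletons], use.names = FALSE)]
  groups <- groups[!singletons]
  # deterministic group order: alphabetically smallest member id
  if (length(groups)) {
    first_id <- vapply(groups, function(g) min(ids[g]), character(1))
    groups <- groups[order(first_id)]
  }

  max_ref <- 0L
  if (!is.null(reference) && length(reference)) {
    nums <- parse_og_number(reference)
    if (anyNA(nums)) stop("unparseable reference OG label: '",
                          reference[which(is.na(nums))[1L]], "'")
    max_ref <- max(nums)
  }

  membership <- character(0)
  registry <- list()
  next_new <- max_ref + 1L
  for (g in groups) {
    members <- ids[g]
    sub <- m[members, members, drop = FALSE]
    min_pid <- min(sub[upper.tri(sub)])
    ref_labels <- unique(reference[members[members %in% names(reference)]])
    if (length(ref_labels) > 1L) {
      stop("ortholog-group conflict: members {",
           paste(members, collapse = ", "),
           "} carry reference labels {",
           paste(ref_labels, collapse = ", "), "}")
    }
    if (length(ref_labels) == 1L) {
      label <- paste0("OG", parse_og_number(ref_labels))
      provenance <- "reference"
    } else {
      label <- paste0("OG", next_new)
      next_new <- next_new + 1L
      provenance <- "new"
    }
    membership[members] <- label
    registry[[label]] <- list(members = members, provenance = provenance,
                              min_pid = min_pid)
  }

  structure(list(membership = membership, registry = registry,
                 ungrouped = ungrouped, threshold = threshold),
            class = "rdh_og_assignment")
}

#' @export
print.rdh_og_assignment <- function(x, ...) {
  cat("Ortholog assignment at PID >", x$threshold, ":",
      length(x$registry), "groups,", length(x$ungrouped), "ungrouped\n")
  invisible(x)
}

#' Write an ortholog membership table
#'
#' @param og an `rdh_og_assignment`.
#' @param path output TSV path; columns `sequence_id`, `og_label`
#'   (`"ungrouped"` for singletons), `provenance`, `min_og_pid`.
#' @return `path`, invisibly.
#' @export
write_og_table <- function(og, path) {
  stopifnot(inherits(og, "rdh_og_assignment"))
  rows <- lapply(names(og$registry), function(lab) {
    r <- og$registry[[lab]]
    data.frame(sequence_id = r$members, og_label = lab,
               provenance = r$provenance, min_og_pid = r$min_pid)
  })
  if (length(og$ungrouped)) {
    rows <- c(rows, list(data.frame(sequence_id = og$ungrouped,
                                    og_label = "ungrouped",
                                    provenance = "", min_og_pid = NA_real_)))
  }
  tab <- do.call(rbind, rows)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
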