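# Ortholog grouping, NJ trees, midpoint rooting, Newick round trips.

sym_pid <- function(vals, ids) {
  n <- length(ids)
  m <- diag(1, n); dimnames(m) <- list(ids, ids)
  m[upper.tri(m)] <- vals
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  m
}

test_that("pid_matrix agrees with per-pair alignment", {
  set.seed(3)
  s <- sequence_set(setNames(vapply(1:4, function(i) random_nt(30), ""),
                             paste0("s", 1:4)), "nt")
  m <- pid_matrix(s)
  expect_true(isSymmetric(m))
  expect_equal(unname(diag(m)), rep(1, 4))
  expect_equal(m["s1", "s3"], global_align(s["s1"], s["s3"])$pid)
  # identical sequences give off-diagonal 1
  s2 <- sequence_set(c(a = "ACGTACGT", b = "ACGTACGT"), "nt")
  expect_equal(pid_matrix(s2)["a", "b"], 1)
})

test_that("single-linkage grouping with strict > threshold", {
  m <- sym_pid(c(0.92, 0.88, 0.91), c("A", "B", "C"))  # AB, AC, BC
  og <- assign_ortholog_groups(m, 0.90)
  expect_length(og$registry, 1)
  expect_setequal(og$registry[[1]]$members, c("A", "B", "C"))
  expect_equal(og$registry[[1]]$min_pid, 0.88)

  # all below threshold -> all ungrouped; PID exactly 0.90 does not link
  m2 <- sym_pid(c(0.90, 0.6, 0.6), c("A", "B", "C"))
  og2 <- assign_ortholog_groups(m2, 0.90)
  expect_length(og2$registry, 0)
  expect_setequal(og2$ungrouped, c("A", "B", "C"))

  expect_error(assign_ortholog_groups(m, 1.2), "threshold")
})

test_that("reference registry labels propagate; conflicts error", {
  m <- sym_pid(c(0.95, 0.2, 0.2, 0.2, 0.2, 0.95), c("A", "B", "C", "D"))
  og <- assign_ortholog_groups(m, 0.9, reference = c(A = "OG8"))
  expect_equal(unname(og$membership["B"]), "OG8")
  # the new group continues past the max reference label
  expect_equal(unname(og$membership["C"]), "OG9")
  expect_equal(og$registry[["OG9"]]$provenance, "new")

  expect_error(
    assign_ortholog_groups(m, 0.9, reference = c(A = "OG8", B = "OG5")),
    "conflict")
})

test_that("OG assignment equals brute-force transitive closure (200 graphs)", {
  set.seed(99)
  for (rep in 1:200) {
    n <- sample(4:10, 1)
    ids <- paste0("q", seq_len(n))
    vals <- runif(n * (n - 1) / 2, 0.6, 1)
    m <- sym_pid(vals, ids)
    og <- assign_ortholog_groups(m, 0.9)
    comp <- brute_components(m, 0.9)
    # same partition: map each id to its component set
    got <- lapply(seq_len(n), function(i) {
      lab <- og$membership[ids[i]]
      if (is.na(lab)) ids[i] else sort(og$registry[[lab]]$members)
    })
    want <- lapply(seq_len(n), function(i) sort(ids[comp == comp[i]]))
    want <- lapply(want, function(w) if (length(w) == 1) w else w)
    for (i in seq_len(n)) {
      if (length(want[[i]]) == 1) {
        expect_true(ids[i] %in% og$ungrouped)
      } else {
        expect_equal(got[[i]], want[[i]])
      }
    }
  }
})

test_that("grouping is invariant to input order and refines with threshold", {
  set.seed(5)
  ids <- paste0("z", 1:8)
  m <- sym_pid(runif(28, 0.7, 1), ids)
  og1 <- assign_ortholog_groups(m, 0.9)
  perm <- sample(8)
  og2 <- assign_ortholog_groups(m[perm, perm], 0.9)
  expect_equal(og1$membership[order(names(og1$membership))],
               og2$membership[order(names(og2$membership))])

  # partition refinement: groups at 0.95 are subsets of groups at 0.90
  og95 <- assign_ortholog_groups(m, 0.95)
  for (lab in names(og95$registry)) {
    members <- og95$registry[[lab]]$members
    labs90 <- unique(og1$membership[members])
    expect_length(labs90, 1)
  }
})

test_that("NJ three-point formulas and tie determinism", {
  d <- matrix(c(0, .2, .4, .2, 0, .4, .4, .4, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(d)
  bl <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(bl[c("A", "B", "C")], c(A = 0.1, B = 0.1, C = 0.3))

  # equal distances: deterministic result, all branches equal
  de <- matrix(0.5, 4, 4); diag(de) <- 0
  dimnames(de) <- list(letters[1:4], letters[1:4])
  t1 <- nj_tree(de); t2 <- nj_tree(de)
  expect_equal(ape::write.tree(t1), ape::write.tree(t2))

  expect_error(nj_tree(d[1:2, 1:2]), "at least 3")
  dneg <- d; dneg[1, 2] <- dneg[2, 1] <- -0.1
  expect_error(nj_tree(dneg), "negative")
})

test_that("NJ recovers additive trees exactly (topology and lengths)", {
  set.seed(21)
  for (rep in 1:20) {
    n <- sample(4:8, 1)
    true <- ape::rtree(n, br = function(k) runif(k, 0.1, 1))
    d <- ape::cophenetic.phylo(true)
    rec <- nj_tree(d)
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(true), ape::unroot(rec))), 0)
    drec <- ape::cophenetic.phylo(rec)[rownames(d), colnames(d)]
    expect_equal(drec, d, tolerance = 1e-8)
  }
})

test_that("midpoint rooting balances the two farthest leaves", {
  # 2-leaf special case
  t2 <- ape::read.tree(text = "(A:0.3,B:0.1);")
  r2 <- midpoint_root(t2)
  expect_equal(unname(leaf_depths(r2)), c(0.2, 0.2))

  set.seed(13)
  for (rep in 1:10) {
    tr <- ape::unroot(ape::rtree(sample(4:8, 1),
                                 br = function(k) runif(k, 0.1, 1)))
    rooted <- midpoint_root(tr)
    dep <- leaf_depths(rooted)
    # independent check: max depth is half the tree diameter
    diam <- max(ape::cophenetic.phylo(tr))
    expect_equal(max(dep), diam / 2, tolerance = 1e-9)
    two <- sort(dep, decreasing = TRUE)[1:2]
    expect_lt(abs(two[1] - two[2]), 1e-9)
  }
})

test_that("Newick writing: format, quoting, and round trips", {
  tr <- ape::read.tree(text = "(A:0.1,B:0.1,C:0.3);")
  f <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tr, f)
  expect_equal(readLines(f), "(A:0.100000,B:0.100000,C:0.300000);")

  # metacharacter-bearing label survives a round trip (quoted)
  tr$tip.label[1] <- "KB1-14/vcrA oddly named"
  write_newick(tr, f)
  back <- read_newick(f)
  expect_setequal(back$tip.label, tr$tip.label)

  set.seed(31)
  for (rep in 1:5) {
    t0 <- ape::rtree(6)
    write_newick(t0, f)
    t1 <- read_newick(f)
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(t0), ape::unroot(t1))), 0)
    expect_equal(sort(t1$edge.length), sort(round(t0$edge.length, 6)),
                 tolerance = 1e-9)
  }
})
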