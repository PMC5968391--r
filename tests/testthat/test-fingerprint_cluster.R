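# Ratio fingerprints, censoring, bins, Pearson/UPGMA clustering.

mk_meas <- function(sample_id, targets, copies, censored = FALSE,
                    mdl = 1e3) {
  data.frame(sample_id = sample_id, target = targets,
             copies_per_unit = copies, unit = "copies/mL",
             censored = rep_len(censored, length(targets)),
             mdl_per_unit = mdl, qc_flags = "", stringsAsFactors = FALSE)
}

test_that("ratio computation and censoring semantics", {
  m <- mk_meas("s1", c("Dhc16S", "vcrA", "bvcA"), c(1e8, 6e7, NA),
               censored = c(FALSE, FALSE, TRUE))
  p <- compute_ratios(m)
  expect_equal(p$ratios$ratio[p$ratios$gene == "vcrA"], 0.6)
  expect_equal(p$ratios$status[p$ratios$gene == "bvcA"], "below_detection")
  expect_true(is.na(p$ratios$ratio[p$ratios$gene == "bvcA"]))

  # 16S below MDL -> whole profile undefined
  m2 <- mk_meas("s1", c("Dhc16S", "vcrA"), c(NA, 6e7),
                censored = c(TRUE, FALSE))
  p2 <- compute_ratios(m2)
  expect_true(all(p2$ratios$status == "undefined"))

  expect_error(compute_ratios(mk_meas("s1", "vcrA", 1)), "missing 16S")

  # scale invariance: multiplying all copies by a constant leaves ratios
  m3 <- m; m3$copies_per_unit <- m3$copies_per_unit * 7.5
  expect_equal(compute_ratios(m3)$ratios$ratio, p$ratios$ratio)
})

test_that("bin edges are lower-inclusive with nd for censored", {
  expect_equal(bin_ratio(0.35), "0.1_to_0.6")
  expect_equal(bin_ratio(0.6), "gt_0.6")          # edge rule
  expect_equal(bin_ratio(c(0.1, 0.01, 0.001)),
               c("0.1_to_0.6", "0.01_to_0.1", "0.001_to_0.01"))
  expect_equal(bin_ratio(5e-4), "lt_0.001")
  expect_equal(bin_ratio(NA), "nd")
  expect_error(bin_ratio(-0.1), "negative")
})

test_that("Pearson similarity matches the textbook formula", {
  # 3 genes x 4 samples toy table
  ratios <- rbind(g1 = c(0.9, 0.7, 0.1, 0.05),
                  g2 = c(0.5, 0.4, 0.02, 0.01),
                  g3 = c(0.01, 0.02, 0.6, 0.9))
  profiles <- lapply(1:4, function(j) {
    ratio_profile(paste0("s", j), ratios[, j])
  })
  ps <- pearson_similarity(profiles, "samples")
  lg <- log10(ratios)
  for (i in 1:3) for (j in (i + 1):4) {
    expect_equal(ps$similarity[i, j], pearson_sums(lg[, i], lg[, j]),
                 tolerance = 1e-12)
  }
  expect_equal(unname(diag(ps$similarity)), rep(1, 4))

  # identical profiles -> r = 1, distance 0
  two <- list(ratio_profile("a", ratios[, 1]), ratio_profile("b", ratios[, 1]))
  expect_equal(pearson_similarity(two, "samples")$distance["a", "b"], 0,
               tolerance = 1e-12)

  # log-space mirrored profiles -> r = -1, distance 2
  mirr <- list(ratio_profile("a", c(g1 = 1e-1, g2 = 1e-2, g3 = 1e-3)),
               ratio_profile("b", c(g1 = 1e-3, g2 = 1e-2, g3 = 1e-1)))
  expect_equal(pearson_similarity(mirr, "samples")$distance["a", "b"], 2,
               tolerance = 1e-12)

  # scaling one profile's ratios shifts logs -> r unchanged
  sc <- list(ratio_profile("a", ratios[, 1]),
             ratio_profile("b", ratios[, 2] * 3.7),
             ratio_profile("c", ratios[, 3]))
  ps2 <- pearson_similarity(sc, "samples")
  base <- pearson_similarity(profiles[1:3], "samples")
  expect_equal(unname(ps2$similarity), unname(base$similarity),
               tolerance = 1e-12)
})

test_that("UPGMA: worked merge, oracle equivalence, ultrametric output", {
  d <- matrix(c(0, .1, .5, .1, 0, .5, .5, .5, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  u <- upgma(d)
  expect_equal(u$height, c(0.1, 0.5))
  expect_equal(u$merge[1, ], c(-2L, -1L))
  expect_equal(u$similarity_percent, c(90, 50))

  set.seed(41)
  for (rep in 1:50) {
    n <- sample(3:7, 1)
    dd <- random_dist(n)
    got <- upgma(dd)
    want <- naive_upgma(dd)
    expect_equal(got$merge, want$merge)
    expect_equal(got$height, want$height, tolerance = 1e-9)
    # heights monotone, cophenetic matrix ultrametric
    expect_true(all(diff(got$height) >= -1e-12))
    cop <- as.matrix(stats::cophenetic(got))
    viol <- 0
    for (a in 1:n) for (b in 1:n) for (cc in 1:n) {
      viol <- max(viol, cop[a, b] - max(cop[a, cc], cop[b, cc]))
    }
    expect_lte(viol, 1e-9)
  }

  # ultrametric input is a fixed point
  um <- matrix(c(0, .2, .8, .2, 0, .8, .8, .8, 0), 3, 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  uu <- upgma(um)
  expect_equal(as.matrix(stats::cophenetic(uu))[c("a", "b", "c"),
                                                c("a", "b", "c")], um)
  expect_error(upgma(um[1, 1, drop = FALSE]), "at least 2")
})

test_that("heatmap table is invariant to input order", {
  set.seed(43)
  ratios <- matrix(10^runif(24, -3, 0), 6, 4,
                   dimnames = list(paste0("g", 1:6), paste0("s", 1:4)))
  profiles <- lapply(colnames(ratios), function(j) {
    ratio_profile(j, ratios[, j])
  })
  h1 <- heatmap_table(profiles)
  h2 <- heatmap_table(rev(profiles))
  expect_identical(h1$bins, h2$bins)
  expect_equal(h1$ratios, h2$ratios)
  expect_true(all(dim(h1$bins) == c(6, 4)))
})

test_that("fingerprint TSV round trip", {
  profiles <- list(
    ratio_profile("s1", c(vcrA = 0.9, bvcA = NA, tceA = 0.05)),
    ratio_profile("s2", c(vcrA = 0.2, bvcA = 0.7, tceA = NA)))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_fingerprint(profiles, f)
  back <- read_fingerprint(f)
  expect_equal(back$s1$ratios$ratio, profiles[[1]]$ratios$ratio)
  expect_equal(back$s2$ratios$status, profiles[[2]]$ratios$status)
})
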