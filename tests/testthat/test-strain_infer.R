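# Strain-count inference: levels, lower bound, exact decomposition,
# co-localization.

test_that("ratio levels respect the within-level span invariant", {
  lv <- ratio_levels(prof(c(a = 1.0, b = 0.95, c = 0.5, d = 0.05)))
  expect_equal(lv$L, 3)
  span <- 10^inference_config()$tau_log10
  for (l in lv$levels) {
    expect_lte(max(l$members) / min(l$members), span)
  }
  expect_equal(lv$levels[[1]]$representative, sqrt(1.0 * 0.95),
               tolerance = 1e-12)

  expect_equal(ratio_levels(prof(c(a = 1, b = 0.99, c = 1.01)))$L, 1)
  empty <- prof(c(a = NA, b = NA))
  expect_equal(ratio_levels(empty)$L, 0)
})

test_that("lower bound is ceil(log2(L+1)); k=2 yields at most 3 levels", {
  expect_equal(min_strain_lower_bound(1), 1L)
  expect_equal(min_strain_lower_bound(3), 2L)
  expect_equal(min_strain_lower_bound(4), 3L)
  expect_equal(min_strain_lower_bound(7), 3L)
  expect_equal(min_strain_lower_bound(8), 4L)
  # subset-sum argument for k = 2: a1, a2, a1+a2 are the only positive sums
  a <- c(0.7, 0.3)
  sums <- unique(c(a[1], a[2], sum(a)))
  expect_lte(length(sums), 3)
})

test_that("worked decomposition {1.0, 0.6, 0.4} at eps 0.05", {
  p <- prof(c(g1 = 1.0, g2 = 0.6, g3 = 0.4))
  m <- min_strain_decomposition(p)
  expect_equal(m$k, 2L)
  expect_equal(sort(m$abundances), c(0.4, 0.6), tolerance = 1e-9)
  # g1 in both strains; g2 and g3 in one each
  expect_equal(unname(rowSums(m$content)[c("g1", "g2", "g3")]), c(2, 1, 1))
  expect_lte(m$residual, 0.05)
  # k = 1 is infeasible at this epsilon
  m1 <- min_strain_decomposition(p, inference_config(k_max = 1))
  expect_false(m1$feasible)
  expect_equal(m1$reported_k, ">= 2")
})

test_that("all-ones profile is a single strain", {
  m <- min_strain_decomposition(prof(c(a = 1, b = 1, c = 1)))
  expect_equal(m$k, 1L)
  expect_equal(m$abundances, 1, tolerance = 1e-9)
})

test_that("five-level instance agrees with the exhaustive oracle", {
  r <- c(g1 = 1.0, g2 = 0.7, g3 = 0.5, g4 = 0.3, g5 = 0.2)
  m <- min_strain_decomposition(prof(r))
  k_oracle <- oracle_min_k(unname(r), eps = 0.05, k_max = 5)
  expect_equal(m$k, k_oracle)
  expect_lte(m$residual, 0.05)
  # k - 1 proven infeasible
  m_less <- min_strain_decomposition(prof(r), inference_config(k_max = m$k - 1))
  expect_false(m_less$feasible)
})

test_that("decomposition equals the exhaustive oracle on random instances", {
  set.seed(51)
  for (rep in 1:6) {
    G <- sample(3:5, 1)
    # grid with >= 0.05 spacing keeps package-side deduplication inert
    r <- sample(seq(0.05, 1, by = 0.05), G)
    names(r) <- paste0("g", seq_len(G))
    m <- min_strain_decomposition(prof(r), inference_config(k_max = 3))
    k_oracle <- oracle_min_k(unname(r), eps = 0.05, k_max = 3)
    expect_equal(m$k, k_oracle, label = paste("ratios", paste(r, collapse = ",")))
    if (!is.na(k_oracle)) expect_lte(m$residual, 0.05 + 1e-9)
  }
})

test_that("model invariants: residual bound, simplex, lower bound <= k", {
  set.seed(53)
  for (rep in 1:15) {
    inst <- recovery_instance(1000 + rep)
    m <- min_strain_decomposition(inst$profile)
    expect_true(m$feasible)
    expect_lte(m$residual, m$epsilon)
    expect_equal(sum(m$abundances), 1, tolerance = 1e-9)
    expect_true(all(m$abundances > 0))
    expect_lte(m$lower_bound, m$k)
    # no two strain columns identical
    cols <- apply(m$content, 2, paste, collapse = "")
    expect_false(anyDuplicated(cols) > 0)
  }
})

test_that("noiseless synthetic communities: k and abundances recovered", {
  ok_k <- 0; ok_a <- 0; n <- 20
  for (rep in 1:n) {
    inst <- recovery_instance(2000 + rep)
    m <- min_strain_decomposition(inst$profile)
    if (identical(m$k, inst$k)) ok_k <- ok_k + 1
    if (m$feasible &&
        length(m$abundances) == inst$k &&
        max(abs(sort(m$abundances) - sort(inst$a))) <= 0.02) ok_a <- ok_a + 1
  }
  expect_equal(ok_k, n)
  expect_equal(ok_a, n)
})

test_that("shrinking epsilon never decreases k", {
  set.seed(57)
  for (rep in 1:8) {
    r <- sample(seq(0.05, 1, by = 0.05), sample(3:5, 1))
    names(r) <- paste0("g", seq_along(r))
    k_loose <- min_strain_decomposition(prof(r), inference_config(epsilon = 0.1))
    k_tight <- min_strain_decomposition(prof(r), inference_config(epsilon = 0.03))
    kl <- if (k_loose$feasible) k_loose$k else Inf
    kt <- if (k_tight$feasible) k_tight$k else Inf
    expect_gte(kt, kl)
  }
})

test_that("ratios above one are clipped with a warning", {
  p <- prof(c(a = 1.3, b = 0.5))
  expect_warning(m <- min_strain_decomposition(p), "clipped")
  expect_true(m$feasible)
})

test_that("censored genes become all-zero content rows, never zeros", {
  p <- prof(c(a = 1.0, b = NA))
  m <- min_strain_decomposition(p)
  expect_equal(m$k, 1L)
  expect_equal(unname(m$content["b", ]), 0L)
})

test_that("co-localization: identical trajectories group, offsets do not", {
  traj <- c(0.8, 0.4, 0.1, 0.05, 0.3, 0.6)
  profiles <- lapply(seq_along(traj), function(j) {
    ratio_profile(paste0("s", j),
                  c(a = traj[j], b = traj[j],          # co-located pair
                    c = traj[j] / 10,                  # correlated, 10x offset
                    d = rev(traj)[j]))                 # anti-correlated
  })
  cc <- colocalization_candidates(profiles)
  expect_equal(cc$groups, list(c("a", "b")))
  expect_false("c" %in% unlist(cc$groups))
  expect_false("d" %in% unlist(cc$groups))
})

test_that("co-localization recovers a co-carried pair from noisy simulation", {
  set.seed(61)
  traj <- 10^runif(6, -1.5, 0)
  profiles <- lapply(1:6, function(j) {
    noise <- function() 10^rnorm(1, 0, 0.05)
    ratio_profile(paste0("s", j),
                  c(a = traj[j] * noise(), b = traj[j] * noise(),
                    e = 10^runif(1, -1.5, 0)))
  })
  cc <- colocalization_candidates(profiles)
  expect_true(any(vapply(cc$groups, function(g) all(c("a", "b") %in% g),
                         logical(1))))
})
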