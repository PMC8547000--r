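test_that("yule trees have the right shape and depth expectation", {
  expect_error(simulate_tree(1), ">= 2")
  cherry <- simulate_tree(2, seed = 1)
  dep <- ape::node.depth.edgelength(cherry)[1:2]
  expect_equal(dep[1], dep[2])
  t1 <- simulate_tree(64, seed = 5)
  t2 <- simulate_tree(64, seed = 5)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  expect_true(ape::is.rooted(t1))
  expect_true(ape::is.binary(t1))

  # analytic Yule oracle: E[depth] = sum_{k=2..n} 1/(lambda k)
  set.seed(42)
  n <- 16; lambda <- 2
  dep <- replicate(500, {
    tr <- simulate_tree(n, lambda)
    max(ape::node.depth.edgelength(tr)[seq_len(n)])
  })
  expect_equal(mean(dep), sum(1 / (lambda * (2:n))), tolerance = 0.05)
})

test_that("BM traits honour rate and seed and the cherry variance law", {
  tr <- balanced4()
  expect_error(simulate_trait_bm(tr, rate = -1), "non-negative")
  z0 <- simulate_trait_bm(tr, rate = 0, seed = 1)
  expect_true(all(z0 == z0[1]))
  expect_identical(simulate_trait_bm(tr, 1, seed = 3),
                   simulate_trait_bm(tr, 1, seed = 3))
  # Var(tipA - tipB) = 2 * rate * branch_length for a cherry
  cherry <- ape::read.tree(text = "(A:0.5,B:0.5);")
  set.seed(9)
  rate <- 3
  diffs <- replicate(2000, { z <- simulate_trait_bm(cherry, rate); z["A"] - z["B"] })
  expect_equal(var(diffs), 2 * rate * 0.5, tolerance = 0.12)
})

test_that("binary traits have exact prevalence; threshold-BM states are clumped", {
  tr <- simulate_tree(64, seed = 2)
  x <- simulate_binary_trait(tr, "random", prevalence = 0.5, seed = 1)
  expect_equal(sum(x), 32)
  expect_identical(simulate_binary_trait(tr, "threshold_bm", seed = 4),
                   simulate_binary_trait(tr, "threshold_bm", seed = 4))
  expect_error(simulate_binary_trait(tr, "random", prevalence = 1e-4), "< 1")

  skip_if_not_installed("phangorn")
  # parsimony-change oracle: clumped states need fewer changes
  set.seed(11)
  pars <- function(x) {
    dat <- phangorn::phyDat(matrix(x, ncol = 1,
                                   dimnames = list(names(x), NULL)),
                            type = "USER", levels = 0:1)
    phangorn::parsimony(tr, dat)
  }
  p_rand <- replicate(100, pars(simulate_binary_trait(tr, "random")))
  p_bm <- replicate(100, pars(simulate_binary_trait(tr, "threshold_bm")))
  expect_lt(mean(p_bm), mean(p_rand))
})

test_that("gradient metacommunity kernels behave as stated", {
  # neutral, deep sequencing: all samples converge on the same SAD
  cfg <- simulation_config(n_samples = 6, n_otus = 50, regime = "neutral",
                           depth = 2e5, seed = 3)
  ds <- simulate_gradient_metacommunity(cfg)
  bc <- bray_curtis(ds$community)
  expect_lt(mean(bc[upper.tri(bc)]), 0.05)

  # selection with huge niche breadth reduces to neutral-scale dissimilarity
  cfg_wide <- simulation_config(n_samples = 6, n_otus = 50, regime = "selection",
                                niche_sigma = 1e6, depth = 2e5, seed = 3)
  bc_wide <- bray_curtis(simulate_gradient_metacommunity(cfg_wide)$community)
  expect_lt(mean(bc_wide[upper.tri(bc_wide)]), 0.05)

  # selection: dissimilarity grows with gradient separation (Monte-Carlo
  # over seeds, Spearman of mean BC vs gradient distance)
  rho <- vapply(1:10, function(s) {
    cfg <- simulation_config(n_samples = 10, n_otus = 200, regime = "selection",
                             depth = 5000, seed = s)
    ds <- simulate_gradient_metacommunity(cfg)
    bc <- bray_curtis(ds$community)
    dg <- as.matrix(dist(ds$env$env$EC))
    ut <- upper.tri(bc)
    cor(bc[ut], dg[ut], method = "spearman")
  }, 0)
  expect_gt(mean(rho), 0.5)
  expect_true(all(rho > 0))
})

test_that("function data links incidence, abundance and phylogeny", {
  cfg <- simulation_config(n_samples = 12, n_otus = 40, regime = "selection",
                           depth = 5000, seed = 8)
  ds <- simulate_gradient_metacommunity(cfg)

  # a universal function with no noise tracks total relative abundance (== 1)
  fd <- simulate_function_data(ds, n_functions = 1, background = 1.1,
                               noise_sd = 0, seed = 1)
  expect_true(all(fd$incidence == 1))
  expect_equal(unname(fd$measurements[, 1]), rep(1, 12))

  # clade-restricted function: samples lacking the clade score ~ noise
  set.seed(2)
  inc <- matrix(0L, 40, 1, dimnames = list(ds$tree$tip.label, "f"))
  clade <- ape::extract.clade(ds$tree, 45)$tip.label
  inc[clade, 1] <- 1L
  P <- ds$community$rel_abund
  lacking <- rowSums(P[, clade, drop = FALSE]) == 0
  meas <- P %*% inc
  if (any(lacking)) expect_true(all(abs(meas[lacking, 1]) < 1e-12))

  # clade-gain annotations are phylogenetically clustered relative to a
  # label-shuffled control (mean pairwise distance among carriers)
  D <- cophenetic_matrix(ds$tree)
  mpd_carriers <- function(fd) {
    mean(vapply(seq_len(ncol(fd$incidence)), function(f) {
      c_idx <- which(fd$incidence[, f] == 1)
      if (length(c_idx) < 2) return(NA_real_)
      sub <- D[c_idx, c_idx]
      mean(sub[upper.tri(sub)])
    }, 0), na.rm = TRUE)
  }
  m_clade <- mean(vapply(1:15, function(s)
    mpd_carriers(simulate_function_data(ds, 5, sharing = "clade", seed = s)), 0))
  m_unif <- mean(vapply(1:15, function(s)
    mpd_carriers(simulate_function_data(ds, 5, sharing = "uniform", seed = s)), 0))
  expect_lt(m_clade, m_unif)
})
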