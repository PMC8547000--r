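test_that("ecological preference traits follow Spearman correlations", {
  ec <- c(1, 3, 5, 7, 9, 11)
  counts <- rbind(c(1, 10), c(2, 8), c(3, 6), c(4, 4), c(5, 2), c(6, 1))
  cm <- toy_cm(counts, otus = c("up", "down"))
  pref <- ecological_preference(cm, data.frame(EC = ec), "EC", min_occupancy = 5)
  expect_equal(pref$rho[pref$otu_id == "up"], 1)
  expect_identical(pref$label[pref$otu_id == "up"], "positive")
  expect_identical(pref$label[pref$otu_id == "down"], "negative")

  # occupancy floor excludes sparse OTUs
  counts2 <- cbind(counts, sparse = c(0, 0, 0, 0, 1, 2))
  cm2 <- toy_cm(counts2, otus = c("up", "down", "sparse"))
  pref2 <- ecological_preference(cm2, data.frame(EC = ec), "EC", min_occupancy = 5)
  expect_false("sparse" %in% pref2$otu_id)

  # rank-formula oracle (no ties): rho = 1 - 6 sum(d^2) / (n(n^2-1))
  a <- c(30, 10, 40, 15, 50, 90)
  # constant filler OTU so the focal relative abundance varies monotonely in a
  cmr <- toy_cm(cbind(a, 100), otus = c("x", "filler"))
  pref3 <- ecological_preference(cmr, data.frame(EC = ec), "EC", min_occupancy = 5)
  d <- rank(a) - rank(ec)
  expect_equal(pref3$rho[pref3$otu_id == "x"],
               1 - 6 * sum(d^2) / (6 * (36 - 1)), tolerance = 1e-12)
})

test_that("Blomberg's K matches the matrix oracle and its invariances", {
  tr <- balanced4()
  x <- c(A = 1, B = 2, C = 4, D = 7)
  # frozen value from hand-built C = [[2,1,0,0],[1,2,0,0],[0,0,2,1],[0,0,1,2]]
  expect_equal(blomberg_k(tr, x, n_perm = 0)$k, 1.2193548387, tolerance = 1e-9)
  # affine invariance
  expect_equal(blomberg_k(tr, 3 * x - 10, n_perm = 0)$k,
               blomberg_k(tr, x, n_perm = 0)$k, tolerance = 1e-12)
  expect_error(blomberg_k(tr, c(A = 1, B = 1, C = 1, D = 1)), "constant")
  expect_error(blomberg_k(tr, x[1:3]), ">= 4")
})

test_that("K is calibrated: BM near 1, white noise below with high p", {
  set.seed(31)
  tr <- simulate_tree(48)
  k_bm <- replicate(100, blomberg_k(tr, simulate_trait_bm(tr), n_perm = 0)$k)
  expect_equal(mean(k_bm), 1, tolerance = 0.1)
  wn <- replicate(100, {
    x <- setNames(rnorm(48), tr$tip.label)
    res <- blomberg_k(tr, x, n_perm = 99)
    c(res$k, res$p)
  })
  expect_lt(mean(wn[1, ]), 1)
  expect_gte(mean(wn[2, ] > 0.05), 0.9)
})

test_that("Fritz-Purvis D behaves at its anchors and is state-symmetric", {
  set.seed(33)
  tr <- simulate_tree(32)
  # perfectly clumped trait (one whole clade) is more conserved than BM: D < 0
  clade <- ape::extract.clade(tr, 34)$tip.label
  while (length(clade) < 6 || length(clade) > 26) {
    tr <- simulate_tree(32)
    clade <- ape::extract.clade(tr, 34)$tip.label
  }
  x <- setNames(as.integer(tr$tip.label %in% clade), tr$tip.label)
  dres <- fritz_purvis_d(tr, x, n_perm = 400, n_bm = 400, seed = 1)
  expect_lt(dres$d, 0)
  # 0 <-> 1 label swap leaves D unchanged (|differences| construction)
  d_swap <- fritz_purvis_d(tr, 1L - x, n_perm = 400, n_bm = 400, seed = 1)
  expect_equal(d_swap$d, dres$d, tolerance = 0.1)
  expect_error(fritz_purvis_d(tr, setNames(rep(1L, 32), tr$tip.label)),
               "both states")
})

test_that("the -D+1 transform is exact and involutive", {
  expect_equal(transform_d(1), 0)
  expect_equal(transform_d(0), 1)
  expect_equal(transform_d(-0.5), 1.5)
  for (d in c(-2, 0.3, 1.7)) expect_equal(transform_d(transform_d(d)), d)
})

test_that("sister-clade difference sums are exact on a hand tree", {
  # ((A,B),(C,D)): trait (1,1,0,0) -> node diffs |1-1| + |0-0| + |1-0| = 1
  tr <- balanced4()
  x <- matrix(c(1, 1, 0, 0), 4, 1, dimnames = list(c("A", "B", "C", "D"), NULL))
  expect_equal(saltrare:::sum_sister_diff(tr, x), 1)
  x2 <- matrix(c(1, 0, 1, 0), 4, 1, dimnames = list(c("A", "B", "C", "D"), NULL))
  expect_equal(saltrare:::sum_sister_diff(tr, x2), 2)   # 1 + 1 + |0.5-0.5|
})

test_that("signal profiles contrast BM-structured and noise preferences", {
  set.seed(35)
  cfg <- simulation_config(n_samples = 24, n_otus = 60, regime = "selection",
                           depth = 8000, niche_sigma = 4, seed = 35)
  ds <- simulate_gradient_metacommunity(cfg)
  prof <- signal_profile(ds$community, ds$tree, ds$env, variables = "EC",
                         subcommunity = "all", n_perm = 49, n_bm = 199,
                         seed = 35)
  expect_equal(nrow(prof), 1)
  expect_false(is.na(prof$k))
  # BM-evolved niche optima leave signal in the EC preference trait:
  # K should beat the typical white-noise K on the same tree
  pref <- ecological_preference(ds$community, ds$env, "EC")
  wn_k <- mean(replicate(20, {
    x <- setNames(rnorm(nrow(pref)), pref$otu_id)
    blomberg_k(ds$tree, x, n_perm = 0)$k
  }))
  expect_gt(prof$k, wn_k)
  # restricting to a tiny taxon subset yields undefined cells
  prof2 <- signal_profile(ds$community, ds$tree, ds$env, variables = "EC",
                          taxon_subset = ds$tree$tip.label[1:3])
  expect_true(is.na(prof2$k))
  # deterministic under fixed seed
  prof3 <- signal_profile(ds$community, ds$tree, ds$env, variables = "EC",
                          subcommunity = "all", n_perm = 49, n_bm = 199,
                          seed = 35)
  expect_identical(prof3$k, prof$k)
  expect_identical(prof3$d, prof$d)
})
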