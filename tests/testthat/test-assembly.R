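test_that("betaNTI matches the enumerated label-shuffle null", {
  D <- cophenetic_matrix(balanced4())
  # singleton pair {A} vs {C}: null betaMNTD is the distance between two
  # distinct random tips: mean 10/3, sd sqrt(8/9); obs = 4
  cm <- toy_cm(rbind(c(1, 0, 0, 0), c(0, 0, 1, 0)), otus = colnames(D))
  res <- beta_nti(cm, D, n_nulls = 9999, seed = 1)
  expect_equal(res$beta_nti[1, 2], (4 - 10 / 3) / sqrt(8 / 9),
               tolerance = 0.15 / 0.7)
  expect_equal(res$beta_nti[1, 2], res$beta_nti[2, 1])
  # identical communities: shuffle-invariant, undefined
  cm_id <- toy_cm(rbind(c(1, 1, 0, 0), c(1, 1, 0, 0)), otus = colnames(D))
  expect_true(is.na(beta_nti(cm_id, D, n_nulls = 99, seed = 1)$beta_nti[1, 2]))
  # seed reproducibility
  r1 <- beta_nti(cm, D, n_nulls = 199, seed = 9)
  r2 <- beta_nti(cm, D, n_nulls = 199, seed = 9)
  expect_identical(r1$beta_nti, r2$beta_nti)
})

test_that("RC_bray hits the exact extremes", {
  # identical full-pool communities: obs BC = 0, every null draw reallocates
  # reads, so null BC > 0 and RC = -1
  cm <- toy_cm(rbind(c(500, 500, 500), c(500, 500, 500)))
  rc <- raup_crick_bray(cm, n_nulls = 499, seed = 2)
  expect_equal(rc$rc_bray, -1)
  # disjoint halves of a wide pool: obs BC = 1, nulls share taxa a.s.
  set.seed(3)
  m <- matrix(0L, 2, 40)
  m[1, 1:20] <- rpois(20, 20) + 1L
  m[2, 21:40] <- rpois(20, 20) + 1L
  rc2 <- raup_crick_bray(toy_cm(m), n_nulls = 499, seed = 4)
  expect_equal(rc2$bray_curtis, 1)
  expect_equal(rc2$rc_bray, 1)
})

test_that("RC_bray matches full enumeration on a 3-OTU metacommunity", {
  counts <- rbind(c(3L, 1L, 0L), c(0L, 2L, 2L))
  cm <- toy_cm(counts)
  occ <- unname(occupancy(cm))
  relab <- colSums(counts) / sum(counts)
  exact <- rc_exact(counts, occ, relab, 1, 2)
  mc <- raup_crick_bray(cm, n_nulls = 9999, seed = 11)$rc_bray
  expect_lt(abs(mc - exact), 0.05)
})

test_that("pair classification follows the decision rules exactly", {
  expect_identical(classify_pair(2.5, 0.3), "variable_selection")
  expect_identical(classify_pair(-2.5, 0.99), "homogeneous_selection")
  expect_identical(classify_pair(1.0, 0.99), "dispersal_limitation")
  expect_identical(classify_pair(1.0, -0.99), "homogenizing_dispersal")
  expect_identical(classify_pair(0.0, 0.0), "undominated")
  # boundaries: |bNTI| = 2 is stochastic side; |RC| = 0.95 is undominated
  expect_identical(classify_pair(2.0, 0.0), "undominated")
  expect_identical(classify_pair(-2.0, 0.96), "dispersal_limitation")
  expect_identical(classify_pair(1.5, 0.95), "undominated")
  expect_identical(classify_pair(1.5, -0.95), "undominated")
  expect_true(is.na(classify_pair(NA, 0.5)))
})

test_that("process fractions sum to one with exact aggregates", {
  labs <- rep("variable_selection", 10)
  pf <- process_fractions(labs)
  expect_equal(unname(pf$aggregates["deterministic"]), 1)
  five <- c("variable_selection", "homogeneous_selection",
            "dispersal_limitation", "homogenizing_dispersal", "undominated")
  pf5 <- process_fractions(five)
  expect_true(all(pf5$fractions == 0.2))
  expect_equal(unname(pf5$aggregates["stochastic"]), 0.6)
  expect_equal(unname(pf5$aggregates["homogenizing"]), 0.4)
  expect_equal(unname(pf5$aggregates["differentiating"]), 0.4)
  # property over random label sets
  set.seed(5)
  for (i in 1:20) {
    labs <- sample(five, 50, replace = TRUE)
    pf <- process_fractions(labs)
    expect_equal(sum(pf$fractions), 1, tolerance = 1e-9)
    expect_equal(unname(pf$aggregates["deterministic"] + pf$aggregates["stochastic"]), 1)
    expect_equal(unname(pf$aggregates["homogenizing"] + pf$aggregates["differentiating"]),
                 1 - unname(pf$fractions["undominated"]))
  }
  expect_error(process_fractions(c(NA, NA)), "zero classified")
})

test_that("env Mantel table flags constants and finds strong signals", {
  set.seed(6)
  e <- data.frame(EC = 1:8, flat = rep(2, 8))
  bnti <- as.matrix(dist(e$EC)) * 0.5
  res <- env_mantel(bnti, e, n_perm = 199)
  expect_equal(res$mantel_r[res$variable == "EC"], 1, tolerance = 1e-9)
  expect_lt(res$p[res$variable == "EC"], 0.05)
  expect_identical(res$flag[res$variable == "flat"], "constant variable")
})

test_that("salinity bins separate shifted betaNTI distributions", {
  set.seed(8)
  n <- 40
  ec <- c(runif(n / 2, 0, 2), runif(n / 2, 10, 19))
  # construct a betaNTI matrix whose within-bin pairs differ by ~2 sd
  bnti <- matrix(NA_real_, n, n)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    lo <- ec[i] < 5 && ec[j] < 5
    hi <- ec[i] >= 5 && ec[j] >= 5
    v <- rnorm(1, mean = if (hi) 2 else 0, sd = 1)
    bnti[i, j] <- bnti[j, i] <- v
  }
  res <- salinity_bin_analysis(bnti, ec, n_bins = 2)
  expect_lt(res$pairwise$p[1], 0.05)
  expect_lt(res$kruskal$p, 0.05)
  # bin membership invariant to sample order
  perm <- sample(n)
  res_p <- salinity_bin_analysis(bnti[perm, perm], ec[perm], n_bins = 2)
  expect_identical(res_p$bins, res$bins[perm])
  expect_error(salinity_bin_analysis(bnti, rep(1, n), n_bins = 2), "bins")
})

test_that("selection-regime synthetic data recovers variable selection", {
  # single-seed sanity check; the 20-seed version lives in the acceptance suite
  fr <- recover_fractions("selection", 101)
  expect_identical(names(which.max(fr$fractions)), "variable_selection")
  expect_equal(sum(fr$fractions), 1, tolerance = 1e-9)
})
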