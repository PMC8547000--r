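test_that("correlations match hand computation including ties", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(cor_test(x, x)$statistic, 1)
  expect_equal(cor_test(x, -x)$statistic, -1)
  expect_true(is.na(cor_test(x, rep(2, 5))$statistic))
  # spearman with one tie: average ranks by hand
  a <- c(3, 1, 4, 1, 5, 9); b <- c(2, 7, 1, 8, 2, 8)
  expect_equal(cor_test(a, b, "spearman")$statistic,
               cor(rank(a), rank(b)), tolerance = 1e-12)
  # property: spearman == pearson on ranks, random instances with ties
  set.seed(61)
  for (i in 1:20) {
    u <- sample(1:5, 10, TRUE); v <- sample(1:5, 10, TRUE)
    if (sd(u) == 0 || sd(v) == 0) next
    expect_equal(cor_test(u, v, "spearman")$statistic,
                 cor(rank(u), rank(v)), tolerance = 1e-12)
  }
})

test_that("Mantel test matches exhaustive enumeration and vegan", {
  set.seed(62)
  m <- matrix(runif(16), 4); D1 <- as.matrix(dist(m))
  m2 <- m + matrix(rnorm(16, 0, 0.3), 4); D2 <- as.matrix(dist(m2))
  res <- mantel_test(D1, D2, n_perm = 9999, seed = 1)
  expect_lt(abs(res$p - mantel_exact_p(D1, D2)), 0.02)
  expect_equal(mantel_test(D1, D1, n_perm = 99)$statistic, 1)
  expect_error(mantel_test(D1, matrix(1:16, 4)), "symmetric")
  r1 <- mantel_test(D1, D2, n_perm = 199, seed = 4)
  expect_identical(r1$p, mantel_test(D1, D2, n_perm = 199, seed = 4)$p)
  skip_if_not_installed("vegan")
  vg <- vegan::mantel(D1, D2, permutations = 99)
  expect_equal(res$statistic, unname(vg$statistic), tolerance = 1e-12)
})

test_that("PERMANOVA matches the trace formula, vegan and enumeration", {
  set.seed(63)
  y <- matrix(rnorm(10), 5, 2)
  D <- as.matrix(dist(y))
  cv <- c(0.2, 1.1, 0.5, 2.0, 1.4)
  res <- permanova(D, cv, n_perm = 9999, seed = 2)
  # hand trace computation
  A <- -0.5 * D^2; J <- diag(5) - matrix(0.2, 5, 5); G <- J %*% A %*% J
  X <- cbind(1, cv); H <- X %*% solve(t(X) %*% X) %*% t(X)
  ssa <- sum(diag(H %*% G %*% H))
  ssr <- sum(diag((diag(5) - H) %*% G %*% (diag(5) - H)))
  expect_equal(res$statistic, (ssa / 1) / (ssr / 3), tolerance = 1e-9)
  expect_equal(res$r_squared, ssa / (ssa + ssr), tolerance = 1e-9)
  expect_true(res$r_squared >= 0 && res$r_squared <= 1)
  expect_lt(abs(res$p - permanova_exact_p(D, cv)), 0.02)
  expect_error(permanova(D, rep(1, 5)), "constant")
  skip_if_not_installed("vegan")
  ad <- vegan::adonis2(as.dist(D) ~ cv, permutations = 49)
  expect_equal(res$statistic, ad$F[1], tolerance = 1e-9)
  expect_equal(res$r_squared, ad$R2[1], tolerance = 1e-9)
})

test_that("two well-separated groups give an extreme PERMANOVA p", {
  y <- c(0, 0.1, 0.2, 10, 10.1, 10.2)
  D <- as.matrix(dist(y))
  g <- factor(rep(c("a", "b"), each = 3))
  res <- permanova(D, g, n_perm = 1999, seed = 5)
  expect_gt(res$statistic, 100)
  # permutations preserving the 3/3 split: 2 * 3! * 3! / 6! = 1/10 of them
  expect_equal(res$p, 0.1, tolerance = 0.3)
})

test_that("Wilcoxon rank-sum: exact enumeration and ties", {
  res <- wilcoxon_rank_sum(c(1, 2), c(3, 4), alternative = "less")
  expect_equal(res$p, 1 / 6)
  expect_identical(res$method, "exact")
  same <- wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p, 1)
  expect_error(wilcoxon_rank_sum(numeric(0), 1:3), "empty")
  # power at a 2 sd shift, n = 30/30
  set.seed(64)
  hits <- vapply(1:40, function(i)
    wilcoxon_rank_sum(rnorm(30), rnorm(30, 2))$p < 0.05, TRUE)
  expect_gte(mean(hits), 0.95)
})

test_that("Kruskal-Wallis matches the hand rank formula", {
  g <- list(c(1, 3, 5, 7), c(2, 4, 6, 8), c(10, 11, 12, 13))
  res <- kruskal_wallis(g)
  vals <- unlist(g); r <- rank(vals); n <- length(vals)
  Rj <- tapply(r, rep(1:3, each = 4), sum)
  H <- 12 / (n * (n + 1)) * sum(Rj^2 / 4) - 3 * (n + 1)
  expect_equal(res$statistic, H, tolerance = 1e-9)  # no ties, no correction
  expect_true(is.na(kruskal_wallis(list(c(1, 1), c(1, 1)))$statistic))
  expect_error(kruskal_wallis(list(1:3)), ">= 2 groups")
  # 2-group agreement with wilcoxon at alpha = 0.05
  set.seed(65)
  agree <- vapply(1:50, function(i) {
    a <- rnorm(12); b <- rnorm(12, sample(c(0, 1.5), 1))
    (kruskal_wallis(list(a, b))$p < 0.05) == (wilcoxon_rank_sum(a, b)$p < 0.05)
  }, TRUE)
  expect_gte(mean(agree), 0.9)
})

test_that("OLS regression matches the normal equations", {
  x <- c(0.5, 1.5, 2, 4, 9); y <- c(1, 0.8, 1.4, 2.2, 4.4)
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  fit <- ols_regression(x, y)
  expect_equal(c(fit$intercept, fit$slope), unname(beta[, 1]), tolerance = 1e-12)
  expect_equal(ols_regression(x, 2 * x + 1)$r_squared, 1)
  expect_equal(ols_regression(c(-1, 0, 1), c(1, -2, 1))$slope, 0)
  expect_error(ols_regression(rep(1, 5), y), "constant")
})

test_that("the env/diversity summary table assembles correctly", {
  set.seed(66)
  env <- data.frame(EC = 1:6, pH = rnorm(6))
  alpha <- list(shannon = 1:6 + rnorm(6, 0, 0.01))
  bnti <- as.matrix(dist(1:6))
  tab <- diversity_env_table(env, alpha, bnti, n_perm = 99, seed = 1)
  expect_equal(nrow(tab), 2 * 2)   # 2 variables x (1 metric + mantel)
  ec_row <- tab[tab$variable == "EC" & tab$metric == "shannon", ]
  expect_gt(ec_row$statistic, 0.99)
  mant <- tab[tab$variable == "EC" & tab$metric == "beta_nti", ]
  expect_equal(mant$statistic, 1, tolerance = 1e-9)
})
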