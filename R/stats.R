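#' Pearson / Spearman correlation with two-sided p
#'
#' Spearman is Pearson on average ranks; p-values use the t approximation.
#'
#' @param x,y numeric vectors, length >= 3.
#' @param method `"pearson"` or `"spearman"`.
#' @return list: `statistic` (r), `p`, `n`, `method`.
#' @export
cor_test <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop("length mismatch")
  if (length(x) < 3) stop("need n >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(statistic = NA_real_, p = NA_real_, n = length(x),
                method = method, flag = "constant input"))
  }
  if (method == "spearman") { x <- rank(x); y <- rank(y) }
  r <- stats::cor(x, y)
  n <- length(x)
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tt), df = n - 2)
  list(statistic = r, p = min(p, 1), n = n, method = method)
}

#' Mantel test between two distance matrices
#'
#' Correlation over the vectorized upper triangles; significance by jointly
#' permuting rows and columns of `D2`. The permutation p uses the
#' `(extreme + 1) / (n_perm + 1)` estimator counting permutations with r at
#' least the observed value (one-sided,
#' positive association, the convention for distance-matrix tests).
#'
#' @param D1,D2 symmetric matrices of equal size (n >= 4).
#' @param method correlation method.
#' @param n_perm number of permutations (default 999).
#' @param seed optional integer seed.
#' @return list: `statistic` (Mantel r), `p`, `n`, `n_permutations`, `method`.
#' @export
mantel_test <- function(D1, D2, method = c("pearson", "spearman"),
                        n_perm = 999, seed = NULL) {
  method <- match.arg(method)
  for (D in list(D1, D2))
    if (!isSymmetric(unname(as.matrix(D)), tol = 1e-8)) stop("matrix not symmetric")
  D1 <- as.matrix(D1); D2 <- as.matrix(D2)
  if (!all(dim(D1) == dim(D2))) stop("dimension mismatch")
  n <- nrow(D1)
  if (n < 4) stop("need n >= 4 samples")
  if (!is.null(seed)) set.seed(seed)
  ut <- upper.tri(D1)
  v1 <- D1[ut]
  if (stats::sd(v1) == 0 || stats::sd(D2[ut]) == 0)
    return(list(statistic = NA_real_, p = NA_real_, n = n,
                n_permutations = n_perm, method = method, flag = "constant distances"))
  corfun <- if (method == "spearman") function(a, b) stats::cor(rank(a), rank(b))
            else stats::cor
  r_obs <- corfun(v1, D2[ut])
  hits <- 0L
  for (b in seq_len(n_perm)) {
    pm <- sample.int(n)
    if (corfun(v1, D2[pm, pm][ut]) >= r_obs - 1e-12) hits <- hits + 1L
  }
  list(statistic = r_obs, p = (hits + 1) / (n_perm + 1), n = n,
       n_permutations = n_perm, method = method)
}

#' Single-factor PERMANOVA (distance-based pseudo-F)
#'
#' Gower-centers the squared distance matrix (`G = -0.5 J A J` with
#' `A = D^2`), builds the hat matrix from the covariate and computes
#' `pseudo-F = [tr(HGH)/df1] / [tr((I-H)G(I-H))/df2]`; p by permuting the
#' covariate rows.
#'
#' @param D distance matrix (n >= 4).
#' @param covariate numeric or factor of length n.
#' @param n_perm permutations (default 999).
#' @param seed optional integer seed.
#' @return list: `statistic` (pseudo-F), `r_squared`, `p`, `df`, `n`,
#'   `n_permutations`.
#' @export
permanova <- function(D, covariate, n_perm = 999, seed = NULL) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (n < 4) stop("need n >= 4 samples")
  if (length(unique(covariate)) < 2) stop("constant covariate")
  if (!is.null(seed)) set.seed(seed)
  A <- -0.5 * D^2
  J <- diag(n) - matrix(1 / n, n, n)
  G <- J %*% A %*% J
  X <- if (is.numeric(covariate)) cbind(1, covariate) else
    stats::model.matrix(~covariate)
  df1 <- qr(X)$rank - 1
  df2 <- n - qr(X)$rank
  fstat <- function(Xm) {
    H <- Xm %*% solve(crossprod(Xm), t(Xm))
    ssa <- sum(diag(H %*% G %*% H))
    ssr <- sum(diag((diag(n) - H) %*% G %*% (diag(n) - H)))
    c(F = (ssa / df1) / (ssr / df2), R2 = ssa / (ssa + ssr))
  }
  obs <- fstat(X)
  hits <- 0L
  for (b in seq_len(n_perm)) {
    if (fstat(X[sample.int(n), , drop = FALSE])[1] >= obs[1] - 1e-12)
      hits <- hits + 1L
  }
  list(statistic = unname(obs[1]), r_squared = unname(obs[2]),
       p = (hits + 1) / (n_perm + 1), df = c(df1, df2), n = n,
       n_permutations = n_perm)
}

#' Wilcoxon rank-sum test
#'
#' Exact p when the smaller group has <= 8 observations and there are no
#' ties; normal approximation with tie correction (no continuity correction)
#' otherwise.
#'
#' @param x,y numeric vectors.
#' @param alternative `"two.sided"`, `"less"` or `"greater"`.
#' @return list: `statistic` (rank-sum W of x), `p`, `n`, `method`.
#' @export
wilcoxon_rank_sum <- function(x, y, alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  if (!length(x) || !length(y)) stop("empty group")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- min(length(x), length(y)) <= 8 && !ties
  wt <- suppressWarnings(stats::wilcox.test(x, y, alternative = alternative,
                                            exact = exact, correct = FALSE))
  list(statistic = unname(wt$statistic), p = wt$p.value,
       n = c(length(x), length(y)),
       method = if (exact) "exact" else "normal approximation")
}

#' Kruskal-Wallis test
#' @param groups list of numeric vectors (>= 2 groups).
#' @return list: `statistic` (H with tie correction), `p`, `df`, `n`.
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2) stop("need >= 2 groups")
  if (any(!lengths(groups))) stop("empty group")
  vals <- unlist(groups)
  if (length(unique(vals)) == 1)
    return(list(statistic = NA_real_, p = NA_real_, df = length(groups) - 1,
                n = length(vals), flag = "all values identical"))
  g <- factor(rep(seq_along(groups), lengths(groups)))
  kt <- stats::kruskal.test(vals, g)
  list(statistic = unname(kt$statistic), p = kt$p.value,
       df = unname(kt$parameter), n = length(vals))
}

#' Ordinary least-squares regression of y on x
#' @param x,y numeric vectors (n >= 3).
#' @return list: `slope`, `intercept`, `r_squared`, `p` (two-sided slope t
#'   test), `n`.
#' @export
ols_regression <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  if (length(x) < 3) stop("need n >= 3")
  if (stats::sd(x) == 0) stop("constant predictor")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  p <- if (nrow(sm$coefficients) == 2) sm$coefficients[2, 4] else NA_real_
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = sm$r.squared, p = p, n = length(x))
}

#' Environment vs diversity / assembly summary table
#'
#' For every environmental variable: Pearson correlation against each alpha
#' diversity metric and a Mantel test of the variable's Euclidean pairwise
#' distance against the betaNTI matrix.
#'
#' @param env env_table or data.frame of environmental variables.
#' @param alpha named list/data.frame of per-sample diversity vectors.
#' @param bnti optional betaNTI matrix for the Mantel column.
#' @param n_perm Mantel permutations.
#' @param seed optional integer seed.
#' @return long data.frame: `variable`, `metric`, `statistic`, `p`, `method`.
#' @export
diversity_env_table <- function(env, alpha, bnti = NULL, n_perm = 999, seed = NULL) {
  if (inherits(env, "env_table")) env <- env$env
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  for (v in names(env)) {
    for (m in names(alpha)) {
      ct <- cor_test(env[[v]], alpha[[m]])
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, metric = m, statistic = ct$statistic, p = ct$p,
        method = "pearson")
    }
    if (!is.null(bnti)) {
      dd <- as.matrix(stats::dist(env[[v]]))
      ok <- !apply(is.na(bnti), 1, all)
      mt <- mantel_test(bnti[ok, ok], dd[ok, ok], n_perm = n_perm)
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, metric = "beta_nti", statistic = mt$statistic, p = mt$p,
        method = "mantel")
    }
  }
  do.call(rbind, rows)
}
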