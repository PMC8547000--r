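#' Per-OTU ecological preference traits
#'
#' For each OTU with occupancy at least `min_occupancy` samples, the Spearman
#' correlation between its relative abundance and an environmental variable
#' across samples is the continuous preference trait; OTUs with significant
#' correlations (raw p < alpha) are labelled `positive`/`negative`
#' preferred (e.g. high- vs low-salinity-preferred for EC), others `none`.
#'
#' @param cm subcommunity [community_matrix()].
#' @param env env_table or data.frame.
#' @param variable environmental variable name.
#' @param alpha significance level for the binary label (default 0.05).
#' @param min_occupancy minimum number of occupied samples (default 5).
#' @return data.frame: `otu_id`, `rho`, `p`, `label`; OTUs failing the
#'   occupancy floor or with constant abundance are omitted.
#' @export
ecological_preference <- function(cm, env, variable, alpha = 0.05,
                                  min_occupancy = 5) {
  if (inherits(env, "env_table")) env <- env$env
  e <- env[[variable]]
  if (is.null(e)) stop("unknown variable: ", variable)
  occ_n <- colSums(cm$counts > 0)
  keep <- which(occ_n >= min_occupancy)
  rows <- lapply(keep, function(i) {
    a <- cm$rel_abund[, i]
    if (stats::sd(a) == 0) return(NULL)
    ct <- cor_test(a, e, method = "spearman")
    if (is.na(ct$statistic)) return(NULL)
    lab <- if (ct$p < alpha) (if (ct$statistic > 0) "positive" else "negative") else "none"
    data.frame(otu_id = cm$otu_ids[i], rho = ct$statistic, p = ct$p,
               label = lab, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(otu_id = character(), rho = numeric(),
                                      p = numeric(), label = character())
  out
}

#' Blomberg's K with a permutation test
#'
#' `K` compares the observed trait variance ratio to its Brownian-motion
#' expectation on the tree: with `C` the phylogenetic covariance matrix of
#' the trait-bearing tips and `a = (1'C^-1 x)/(1'C^-1 1)` the phylogenetic
#' mean,
#' `K = [(x-a)'(x-a) / (x-a)'C^-1(x-a)] / [(tr C - n/(1'C^-1 1)) / (n-1)]`.
#' K = 1 is the BM expectation; K near 0 means no signal. The permutation p
#' shuffles tip labels and uses the variance of phylogenetically independent
#' contrasts as test statistic (low observed variance = signal).
#'
#' @param tree `phylo`; pruned internally to `names(trait)`.
#' @param trait named numeric vector on >= 4 tips; non-constant.
#' @param n_perm tip shuffles for the p-value (default 999); 0 skips the test.
#' @param seed optional integer seed.
#' @return list: `k`, `p`, `n`, `n_permutations`.
#' @export
blomberg_k <- function(tree, trait, n_perm = 999, seed = NULL) {
  if (is.null(names(trait))) stop("trait must be named by tip label")
  trait <- trait[!is.na(trait)]
  if (length(trait) < 4) stop("need >= 4 trait-bearing tips")
  if (stats::sd(trait) == 0) stop("constant trait")
  tree <- ape::keep.tip(tree, names(trait))
  x <- trait[tree$tip.label]
  n <- length(x)
  C <- ape::vcv.phylo(tree)
  Ci <- tryCatch(solve(C), error = function(e)
    stop("singular phylogenetic covariance (zero-length cherry?): ",
         conditionMessage(e)))
  one <- rep(1, n)
  denom1 <- drop(one %*% Ci %*% one)
  a <- drop(one %*% Ci %*% x) / denom1
  dev <- x - a
  obs_ratio <- drop(crossprod(dev)) / drop(dev %*% Ci %*% dev)
  exp_ratio <- (sum(diag(C)) - n / denom1) / (n - 1)
  k <- obs_ratio / exp_ratio
  p <- NA_real_
  if (n_perm > 0) {
    if (!is.null(seed)) set.seed(seed)
    picvar <- function(v) stats::var(ape::pic(v, tree))
    obs <- picvar(x)
    hits <- 0L
    for (b in seq_len(n_perm)) {
      if (picvar(stats::setNames(sample(x), names(x))) <= obs + 1e-12)
        hits <- hits + 1L
    }
    p <- (hits + 1) / (n_perm + 1)
  }
  list(k = k, p = p, n = n, n_permutations = n_perm)
}

# Sum over internal nodes of |successive-average differences| of daughter
# values, tips to root (the Fritz-Purvis sister-clade difference sum).
# X: n_tips x R matrix of tip values (columns are replicates). Polytomies
# contribute the sum over successive pairwise averages of their children in
# canonical order (children sorted by smallest descendant tip label).
sum_sister_diff <- function(tree, X) {
  X <- as.matrix(X)
  n_tip <- length(tree$tip.label)
  tr <- ape::reorder.phylo(tree, "postorder")
  X <- X[tr$tip.label, , drop = FALSE]
  n_node <- n_tip + tr$Nnode
  children <- vector("list", n_node)
  for (e in seq_len(nrow(tr$edge)))
    children[[tr$edge[e, 1]]] <- c(children[[tr$edge[e, 1]]], tr$edge[e, 2])
  # canonical ordering key: smallest tip label (alphabetical) below each node
  minlab <- character(n_node)
  minlab[seq_len(n_tip)] <- tr$tip.label
  V <- matrix(0, n_node, ncol(X))
  V[seq_len(n_tip), ] <- X
  total <- numeric(ncol(X))
  nodes_postorder <- unique(tr$edge[, 1])   # parents appear after children
  for (nd in nodes_postorder) {
    kids <- children[[nd]]
    kids <- kids[order(minlab[kids])]
    minlab[nd] <- minlab[kids[1]]
    v <- V[kids[1], ]
    for (i in seq_along(kids)[-1]) {
      total <- total + abs(v - V[kids[i], ])
      v <- (v + V[kids[i], ]) / 2
    }
    V[nd, ] <- v
  }
  total
}

#' Fritz-Purvis D for a binary trait
#'
#' The observed sister-clade difference sum is scaled between its expectation
#' under a uniform shuffle of states (D = 1, no signal) and under
#' Brownian-threshold evolution at the observed prevalence (D = 0, clumped):
#' `D = (Sd_obs - mean Sd_BM) / (mean Sd_rand - mean Sd_BM)`.
#'
#' @param tree `phylo`; pruned internally to `names(trait)`.
#' @param trait named 0/1 vector with both states present, >= 4 tips.
#' @param n_perm shuffle references (default 1000).
#' @param n_bm threshold-BM references (default 1000).
#' @param seed optional integer seed.
#' @return list: `d`, `one_minus_d`, `sd_obs`, `mean_rand`, `mean_bm`, `n`.
#' @export
fritz_purvis_d <- function(tree, trait, n_perm = 1000, n_bm = 1000, seed = NULL) {
  if (is.null(names(trait))) stop("trait must be named by tip label")
  trait <- trait[!is.na(trait)]
  if (length(unique(trait)) < 2) stop("trait must have both states")
  if (length(trait) < 4) stop("need >= 4 trait-bearing tips")
  if (!is.null(seed)) set.seed(seed)
  tree <- ape::keep.tip(tree, names(trait))
  x <- trait[tree$tip.label]
  n <- length(x)
  k <- sum(x == 1)
  sd_obs <- sum_sister_diff(tree, matrix(x, n, 1, dimnames = list(names(x), NULL)))
  shuf <- matrix(0, n, n_perm, dimnames = list(names(x), NULL))
  for (b in seq_len(n_perm)) shuf[sample.int(n, k), b] <- 1
  mean_rand <- mean(sum_sister_diff(tree, shuf))
  Z <- bm_tips_matrix(tree, rate = 1, n_rep = n_bm)
  B <- apply(Z, 2, function(z) {
    out <- numeric(n)
    out[order(z, decreasing = TRUE)[seq_len(k)]] <- 1
    out
  })
  rownames(B) <- rownames(Z)
  mean_bm <- mean(sum_sister_diff(tree, B))
  d <- (sd_obs - mean_bm) / (mean_rand - mean_bm)
  list(d = unname(d), one_minus_d = unname(1 - d), sd_obs = unname(sd_obs),
       mean_rand = mean_rand, mean_bm = mean_bm, n = n)
}

#' Transform D to -D + 1 (so larger = more conserved, 0 = no signal)
#' @param d Fritz-Purvis D value(s).
#' @return `1 - d`.
#' @export
transform_d <- function(d) 1 - d

#' Phylogenetic signal profile over environmental variables
#'
#' For one subcommunity: builds preference traits per variable, computes
#' Blomberg's K on the Spearman-rho trait and Fritz-Purvis D (reported as
#' -D+1) on the binary preference trait (1 = significantly positively
#' correlated, 0 = other trait-bearing OTUs). Cells with fewer than 4 usable
#' taxa, or a single binary state, are reported as NA.
#'
#' @param cm subcommunity [community_matrix()].
#' @param tree `phylo` covering the OTUs.
#' @param env env_table or data.frame.
#' @param variables variables to profile (default: all env columns).
#' @param subcommunity label recorded in the output.
#' @param taxon_subset optional character vector of OTU ids to restrict to
#'   (e.g. one phylum) before trait construction.
#' @param alpha,min_occupancy see [ecological_preference()].
#' @param n_perm,n_bm reference counts for the signal statistics.
#' @param seed optional integer seed.
#' @return data.frame: `variable`, `subcommunity`, `n_taxa`, `k`, `k_p`,
#'   `d`, `one_minus_d`.
#' @export
signal_profile <- function(cm, tree, env, variables = NULL,
                           subcommunity = "community", taxon_subset = NULL,
                           alpha = 0.05, min_occupancy = 5,
                           n_perm = 999, n_bm = 1000, seed = NULL) {
  if (inherits(env, "env_table")) env <- env$env
  if (is.null(variables)) variables <- names(env)
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(taxon_subset)) {
    keep <- intersect(cm$otu_ids, taxon_subset)
    if (length(keep) < 4)
      return(data.frame(variable = variables, subcommunity = subcommunity,
                        n_taxa = length(keep), k = NA_real_, k_p = NA_real_,
                        d = NA_real_, one_minus_d = NA_real_))
    cm <- community_matrix(cm$counts[, keep, drop = FALSE])
  }
  rows <- lapply(variables, function(v) {
    pref <- ecological_preference(cm, env, v, alpha, min_occupancy)
    out <- data.frame(variable = v, subcommunity = subcommunity,
                      n_taxa = nrow(pref), k = NA_real_, k_p = NA_real_,
                      d = NA_real_, one_minus_d = NA_real_)
    if (nrow(pref) >= 4) {
      cont <- stats::setNames(pref$rho, pref$otu_id)
      if (stats::sd(cont) > 0) {
        bk <- blomberg_k(tree, cont, n_perm = n_perm)
        out$k <- bk$k; out$k_p <- bk$p
      }
      bin <- stats::setNames(as.integer(pref$label == "positive"), pref$otu_id)
      if (length(unique(bin)) == 2) {
        fd <- fritz_purvis_d(tree, bin, n_perm = n_bm, n_bm = n_bm)
        out$d <- fd$d; out$one_minus_d <- fd$one_minus_d
      }
    }
    out
  })
  do.call(rbind, rows)
}
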