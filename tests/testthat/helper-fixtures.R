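# Shared fixtures and independent oracles (built in code, never stored).

balanced4 <- function() ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")

toy_cm <- function(counts, samples = NULL, otus = NULL) {
  m <- as.matrix(counts)
  if (!is.null(samples)) rownames(m) <- samples
  if (!is.null(otus)) colnames(m) <- otus
  if (is.null(rownames(m))) rownames(m) <- paste0("S", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("OTU_", seq_len(ncol(m)))
  community_matrix(m)
}

# a classification-sized community reproducing the published richness
# census: 70 abundant, 1979 intermediate, 11400 rare OTUs in one sample
census_cm <- function() {
  counts <- c(rep(15000L, 70), rep(3000L, 1979), rep(264L, 11400))
  toy_cm(matrix(counts, nrow = 1))
}

# graph shortest-path oracle for cophenetic distances (Floyd-Warshall on the
# tree's node graph)
fw_cophenetic <- function(tree) {
  n <- length(tree$tip.label) + tree$Nnode
  d <- matrix(Inf, n, n); diag(d) <- 0
  for (e in seq_len(nrow(tree$edge))) {
    i <- tree$edge[e, 1]; j <- tree$edge[e, 2]
    d[i, j] <- d[j, i] <- tree$edge.length[e]
  }
  for (k in seq_len(n)) for (i in seq_len(n)) {
    dd <- d[i, k] + d[k, ]
    lower <- dd < d[i, ]
    d[i, lower] <- dd[lower]
  }
  out <- d[seq_along(tree$tip.label), seq_along(tree$tip.label)]
  dimnames(out) <- list(tree$tip.label, tree$tip.label)
  out
}

# brute-force MNTD oracle
bf_mntd <- function(abund, D, weighted) {
  pres <- which(abund > 0)
  nd <- vapply(pres, function(i) min(D[i, setdiff(pres, i)]), 0)
  if (weighted) sum(abund[pres] / sum(abund[pres]) * nd) else mean(nd)
}

# exact Raup-Crick for a tiny metacommunity by full enumeration of the
# two-step null (sequential weighted draw without replacement, one read per
# drawn taxon, remaining reads multinomial by relative abundance)
rc_exact <- function(counts, occ, relab, k, l) {
  n_otu <- ncol(counts)
  subset_prob <- function(set, w) {
    pr <- 0
    for (ord in list(set, rev(set))) {
      p <- 1; left <- sum(w)
      for (i in ord) { p <- p * w[i] / left; left <- left - w[i] }
      pr <- pr + p
    }
    pr
  }
  comm_dist <- function(rich, reads) {
    sets <- utils::combn(n_otu, rich, simplify = FALSE)
    out <- list()
    for (s in sets) {
      ps <- subset_prob(s, occ)
      m <- reads - rich
      pvec <- relab[s] / sum(relab[s])
      allocs <- as.matrix(expand.grid(rep(list(0:m), rich)))
      allocs <- allocs[rowSums(allocs) == m, , drop = FALSE]
      for (r in seq_len(nrow(allocs))) {
        pa <- stats::dmultinom(allocs[r, ], prob = pvec)
        cnt <- numeric(n_otu); cnt[s] <- 1 + allocs[r, ]
        out[[length(out) + 1]] <- list(p = ps * pa, rel = cnt / sum(cnt))
      }
    }
    out
  }
  bc <- function(p1, p2) 1 - sum(pmin(p1, p2))
  obs <- bc(counts[k, ] / sum(counts[k, ]), counts[l, ] / sum(counts[l, ]))
  d1 <- comm_dist(sum(counts[k, ] > 0), sum(counts[k, ]))
  d2 <- comm_dist(sum(counts[l, ] > 0), sum(counts[l, ]))
  below <- 0; equal <- 0
  for (a in d1) for (b in d2) {
    v <- bc(a$rel, b$rel)
    w <- a$p * b$p
    if (v < obs - 1e-12) below <- below + w
    else if (v <= obs + 1e-12) equal <- equal + w
  }
  2 * ((below + 0.5 * equal) - 0.5)
}

# exhaustive-permutation Mantel p (one-sided, r >= observed)
mantel_exact_p <- function(D1, D2, method = "pearson") {
  n <- nrow(D1)
  ut <- upper.tri(D1)
  corfun <- if (method == "spearman") function(a, b) stats::cor(rank(a), rank(b)) else stats::cor
  v1 <- D1[ut]
  r_obs <- corfun(v1, D2[ut])
  perms <- perm_all(n)
  hits <- sum(apply(perms, 1, function(pm) corfun(v1, D2[pm, pm][ut]) >= r_obs - 1e-12))
  hits / nrow(perms)
}

perm_all <- function(n) {
  if (n == 1) return(matrix(1))
  sub <- perm_all(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

# exhaustive-permutation PERMANOVA p
permanova_exact_p <- function(D, covariate) {
  n <- nrow(D)
  fstat <- function(cv) {
    A <- -0.5 * D^2
    J <- diag(n) - matrix(1 / n, n, n)
    G <- J %*% A %*% J
    X <- cbind(1, cv)
    H <- X %*% solve(crossprod(X), t(X))
    ssa <- sum(diag(H %*% G %*% H))
    ssr <- sum(diag((diag(n) - H) %*% G %*% (diag(n) - H)))
    ssa / ssr
  }
  obs <- fstat(covariate)
  perms <- perm_all(n)
  mean(apply(perms, 1, function(pm) fstat(covariate[pm]) >= obs - 1e-12))
}

# desk-scaled assembly recovery run used by module and acceptance tests:
# the stated world is 90 samples x 800 OTUs; classification uses a 24-sample
# even subset, 99 nulls and 120 pairs, which is unbiased for the fractions.
recover_fractions <- function(regime, seed) {
  cfg <- simulation_config(n_samples = 90, n_otus = 800, regime = regime,
                           seed = seed)
  ds <- simulate_gradient_metacommunity(cfg)
  keep <- round(seq(1, 90, length.out = 24))
  sub <- community_matrix(ds$community$counts[keep, ])
  D <- cophenetic_matrix(ds$tree)
  assembly_analysis(sub, D, n_nulls = 99, rc_lazy = TRUE, max_pairs = 120,
                    seed = seed)$fractions
}
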