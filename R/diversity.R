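#' Shannon diversity (natural log)
#'
#' `H = -sum(p_i * log(p_i))` over non-zero entries of the renormalized
#' abundance vector, in nats.
#'
#' @param p abundance (or count) vector, non-negative, not all zero; or a
#'   [community_matrix()], in which case a per-sample vector is returned.
#' @return numeric H >= 0.
#' @export
shannon_index <- function(p) {
  if (inherits(p, "community_matrix"))
    return(apply(p$rel_abund, 1, shannon_index))
  if (any(p < 0)) stop("abundances must be non-negative")
  s <- sum(p)
  if (s == 0) stop("all-zero sample")
  q <- p[p > 0] / s
  -sum(q * log(q))
}

#' Cophenetic (patristic) distance matrix of a tree
#'
#' @param tree `phylo` with branch lengths.
#' @param otu_ids optional ordering/subset of tip labels for the returned
#'   matrix.
#' @return symmetric matrix of path-length distances, zero diagonal.
#' @export
cophenetic_matrix <- function(tree, otu_ids = NULL) {
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  D <- ape::cophenetic.phylo(tree)
  if (!is.null(otu_ids)) {
    missing <- setdiff(otu_ids, rownames(D))
    if (length(missing))
      stop("OTU(s) not in tree: ", paste(utils::head(missing, 5), collapse = ", "))
    D <- D[otu_ids, otu_ids, drop = FALSE]
  }
  D
}

# weights matrix used by the MNTD family: rel abund (weighted) or
# 1/richness incidence (unweighted), rows = samples, cols = taxa in D order
mntd_weights <- function(cm, D, weighted) {
  P <- cm$rel_abund[, rownames(D), drop = FALSE]
  if (!weighted) {
    inc <- (cm$counts[, rownames(D), drop = FALSE] > 0) * 1
    rich <- rowSums(inc)
    P <- sweep(inc, 1, pmax(rich, 1), "/")
  }
  P
}

#' Observed mean nearest-taxon distance of one community
#'
#' For each present taxon, the distance to its nearest other present taxon;
#' MNTD is the abundance-weighted sum (weighted) or plain mean (unweighted).
#'
#' @param abund named abundance vector (names are tip labels), or a vector
#'   aligned with `rownames(D)`.
#' @param D cophenetic matrix.
#' @param weighted abundance-weighted (default TRUE).
#' @return MNTD, or `NA` with a warning when fewer than 2 taxa are present.
#' @export
mntd_observed <- function(abund, D, weighted = TRUE) {
  if (!is.null(names(abund))) abund <- abund[rownames(D)]
  pres <- which(abund > 0)
  if (length(pres) < 2) {
    warning("MNTD undefined for < 2 taxa")
    return(NA_real_)
  }
  sub <- D[pres, pres, drop = FALSE]
  diag(sub) <- Inf
  nd <- apply(sub, 1, min)
  if (weighted) {
    w <- abund[pres] / sum(abund[pres])
    sum(w * nd)
  } else mean(nd)
}

#' Standardized effect size of MNTD (SES.MNTD)
#'
#' Null model: shuffle the taxa labels of the cophenetic matrix and recompute
#' MNTD; `SES = (MNTD_obs - mean_null) / sd_null` (sample sd). Negative
#' values indicate phylogenetic clustering.
#'
#' @param cm a [community_matrix()] (all samples are processed at once).
#' @param D cophenetic matrix covering the community's OTUs.
#' @param n_nulls number of label shuffles (default 999).
#' @param weighted abundance-weighted MNTD (default TRUE).
#' @param seed optional integer seed.
#' @return data.frame per sample: `sample_id`, `mntd_obs`, `null_mean`,
#'   `null_sd`, `ses_mntd` (NA where the null sd is zero), `n_nulls`.
#' @export
ses_mntd <- function(cm, D, n_nulls = 999, weighted = TRUE, seed = NULL) {
  if (n_nulls < 1) stop("n_nulls must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  W <- mntd_weights(cm, D, weighted)
  res <- cpp_ses_mntd(D, W, as.integer(n_nulls))
  sd0 <- res$null_sd < 1e-12
  ses <- (res$obs - res$null_mean) / res$null_sd
  ses[sd0] <- NA_real_
  data.frame(sample_id = cm$sample_ids, mntd_obs = res$obs,
             null_mean = res$null_mean, null_sd = res$null_sd,
             ses_mntd = ses, n_nulls = n_nulls)
}

#' Between-community mean nearest-taxon distance (betaMNTD)
#'
#' `0.5 * (sum_i p_ik min_j d(i,j) + sum_j p_jl min_i d(j,i))` where i runs
#' over taxa of sample k and j over taxa of sample l; a taxon present in both
#' contributes 0 on both sides.
#'
#' @param cm a [community_matrix()].
#' @param D cophenetic matrix.
#' @param weighted abundance-weighted (default TRUE).
#' @return symmetric sample x sample matrix with zero diagonal.
#' @export
beta_mntd <- function(cm, D, weighted = TRUE) {
  if (any(rowSums(cm$counts) == 0)) stop("empty sample(s)")
  W <- mntd_weights(cm, D, weighted)
  B <- cpp_beta_mntd(D, W)
  dimnames(B) <- list(cm$sample_ids, cm$sample_ids)
  B
}

#' Bray-Curtis dissimilarity between all sample pairs
#'
#' `BC = 1 - sum(min(p_k, p_l))` on per-sample relative abundances
#' (equivalently half the L1 distance).
#'
#' @param cm a [community_matrix()] or a samples x taxa relative-abundance
#'   matrix.
#' @return symmetric matrix in `[0, 1]`.
#' @export
bray_curtis <- function(cm) {
  P <- if (inherits(cm, "community_matrix")) cm$rel_abund else
    sweep(cm, 1, rowSums(cm), "/")
  n <- nrow(P)
  B <- matrix(0, n, n, dimnames = list(rownames(P), rownames(P)))
  for (k in seq_len(n - 1)) {
    for (l in (k + 1):n) {
      B[k, l] <- B[l, k] <- 1 - sum(pmin(P[k, ], P[l, ]))
    }
  }
  B
}
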