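#' Phylogenetic turnover null model (betaNTI) for all sample pairs
#'
#' The null shuffles taxa labels across the tips of the cophenetic matrix
#' (one joint shuffle of all tree labels per replicate, shared across pairs)
#' and recomputes betaMNTD;
#' `betaNTI = (betaMNTD_obs - mean_null) / sd_null` (sample sd). Pairs whose
#' null sd is ~0 (e.g. identical communities) are returned as `NA`.
#'
#' @param cm a [community_matrix()].
#' @param D cophenetic matrix over the community's OTUs (full tree labels
#'   define the shuffle pool).
#' @param n_nulls null replicates (default 999).
#' @param weighted abundance-weighted betaMNTD (default TRUE).
#' @param seed optional integer seed.
#' @return list with matrices `beta_mntd` (observed), `beta_nti`,
#'   `null_mean`, `null_sd`; `NA` on the diagonal of `beta_nti`.
#' @export
beta_nti <- function(cm, D, n_nulls = 999, weighted = TRUE, seed = NULL) {
  if (n_nulls < 1) stop("n_nulls must be >= 1")
  if (any(rowSums(cm$counts) == 0)) stop("empty sample(s)")
  if (!is.null(seed)) set.seed(seed)
  W <- mntd_weights(cm, D, weighted)
  res <- cpp_beta_nti(D, W, as.integer(n_nulls))
  bnti <- (res$obs - res$null_mean) / res$null_sd
  bnti[res$null_sd < 1e-12] <- NA_real_
  diag(bnti) <- NA_real_
  nm <- list(cm$sample_ids, cm$sample_ids)
  dimnames(res$obs) <- dimnames(bnti) <- dimnames(res$null_mean) <-
    dimnames(res$null_sd) <- nm
  list(beta_mntd = res$obs, beta_nti = bnti,
       null_mean = res$null_mean, null_sd = res$null_sd, n_nulls = n_nulls)
}

#' Bray-Curtis Raup-Crick null model (RC_bray)
#'
#' Each null replicate rebuilds both communities from the metacommunity:
#' observed richness taxa are drawn without replacement with probability
#' proportional to occupancy; each drawn taxon receives one read and the
#' remaining reads are allocated multinomially with probability proportional
#' to dataset-wide relative abundance. `RC_raw` is the fraction of null
#' Bray-Curtis values below the observed one (ties half-weighted) and
#' `RC_bray = 2 (RC_raw - 0.5)` in `[-1, 1]`.
#'
#' @param cm a [community_matrix()] (counts define depth structure).
#' @param pairs optional 2-column matrix of sample index pairs; default all
#'   pairs.
#' @param n_nulls null replicates per pair (default 999).
#' @param seed optional integer seed.
#' @param occupancy_weights,abundance_weights optional overrides for the
#'   draw and allocation probabilities (default: occupancy and dataset-wide
#'   relative abundance).
#' @return data.frame: `sample_i`, `sample_j`, `bray_curtis`, `rc_bray`.
#' @export
raup_crick_bray <- function(cm, pairs = NULL, n_nulls = 999, seed = NULL,
                            occupancy_weights = NULL, abundance_weights = NULL) {
  if (n_nulls < 1) stop("n_nulls must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  n <- length(cm$sample_ids)
  if (is.null(pairs)) {
    pairs <- t(utils::combn(n, 2))
  }
  pairs <- matrix(as.integer(pairs), ncol = 2)
  occ <- if (is.null(occupancy_weights)) occupancy(cm) else occupancy_weights
  relab <- if (is.null(abundance_weights))
    colSums(cm$counts) / sum(cm$counts) else abundance_weights
  rich <- rowSums(cm$counts > 0)
  meta_rich <- sum(occ > 0)
  if (any(rich[unique(c(pairs))] > meta_rich))
    stop("sample richness exceeds metacommunity richness")
  rc <- cpp_rc_bray(cm$counts, occ, relab, pairs, as.integer(n_nulls), 1e-12)
  bc <- bray_curtis(cm)
  data.frame(sample_i = cm$sample_ids[pairs[, 1]],
             sample_j = cm$sample_ids[pairs[, 2]],
             bray_curtis = bc[pairs], rc_bray = rc)
}

#' Assign the assembly process of one sample pair
#'
#' Selection first: `betaNTI > 2` is variable selection, `betaNTI < -2`
#' homogeneous selection. With `|betaNTI| <= 2` (boundary inclusive),
#' `RC > 0.95` is dispersal limitation, `RC < -0.95` homogenizing dispersal,
#' and `|RC| <= 0.95` (boundary inclusive) undominated.
#'
#' @param bnti,rc numeric vectors (recycled pairwise).
#' @return character vector of process labels; `NA` propagates.
#' @export
classify_pair <- function(bnti, rc) {
  out <- rep(NA_character_, max(length(bnti), length(rc)))
  bnti <- rep_len(bnti, length(out)); rc <- rep_len(rc, length(out))
  ok <- !is.na(bnti)
  out[ok & bnti > 2] <- "variable_selection"
  out[ok & bnti < -2] <- "homogeneous_selection"
  sto <- ok & abs(bnti) <= 2
  out[sto & !is.na(rc) & rc > 0.95] <- "dispersal_limitation"
  out[sto & !is.na(rc) & rc < -0.95] <- "homogenizing_dispersal"
  out[sto & !is.na(rc) & abs(rc) <= 0.95] <- "undominated"
  out
}

#' Process fractions and their stochastic/deterministic aggregates
#'
#' Fractions are over classified (non-NA) pairs. Aggregates:
#' deterministic = variable + homogeneous selection; stochastic = the rest;
#' homogenizing = homogeneous selection + homogenizing dispersal;
#' differentiating = variable selection + dispersal limitation.
#'
#' @param labels character vector of process labels (NA allowed).
#' @return list with `fractions` (named, sums to 1), `aggregates`,
#'   `n_classified`, `n_undefined`.
#' @export
process_fractions <- function(labels) {
  lev <- c("variable_selection", "homogeneous_selection",
           "dispersal_limitation", "homogenizing_dispersal", "undominated")
  ok <- labels[!is.na(labels)]
  if (!length(ok)) stop("zero classified pairs")
  bad <- setdiff(unique(ok), lev)
  if (length(bad)) stop("unknown process label(s): ", paste(bad, collapse = ", "))
  f <- table(factor(ok, levels = lev)) / length(ok)
  f <- stats::setNames(as.numeric(f), lev)
  det <- unname(f["variable_selection"] + f["homogeneous_selection"])
  agg <- c(deterministic = det,
           stochastic = 1 - det,   # exact complement identity
           homogenizing = unname(f["homogeneous_selection"] + f["homogenizing_dispersal"]),
           differentiating = unname(f["variable_selection"] + f["dispersal_limitation"]))
  list(fractions = f, aggregates = agg, n_classified = length(ok),
       n_undefined = sum(is.na(labels)))
}

#' Full pairwise assembly analysis
#'
#' Runs [beta_nti()] on all pairs, then [raup_crick_bray()]; with
#' `rc_lazy = TRUE` RC is only computed for pairs that need it
#' (`|betaNTI| <= 2`), a pure optimisation since selection takes precedence
#' in [classify_pair()].
#'
#' @param cm a [community_matrix()].
#' @param D cophenetic matrix.
#' @param n_nulls null replicates for both null models.
#' @param weighted abundance weighting for betaMNTD.
#' @param rc_lazy skip RC for pairs already classified as selection.
#' @param max_pairs optionally classify only a random subset of sample pairs
#'   of this size (unbiased for the process fractions; a desk-scale
#'   optimisation).
#' @param seed optional integer seed.
#' @return list with the `pairs` data.frame (`sample_i`, `sample_j`,
#'   `beta_mntd`, `beta_nti`, `bray_curtis`, `rc_bray`, `process`) and the
#'   [process_fractions()] summary.
#' @export
assembly_analysis <- function(cm, D, n_nulls = 999, weighted = TRUE,
                              rc_lazy = FALSE, max_pairs = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  bn <- beta_nti(cm, D, n_nulls = n_nulls, weighted = weighted)
  n <- length(cm$sample_ids)
  idx <- t(utils::combn(n, 2))
  if (!is.null(max_pairs) && max_pairs < nrow(idx))
    idx <- idx[sample.int(nrow(idx), max_pairs), , drop = FALSE]
  bnti <- bn$beta_nti[idx]
  need_rc <- if (rc_lazy) which(!is.na(bnti) & abs(bnti) <= 2) else seq_len(nrow(idx))
  rc <- rep(NA_real_, nrow(idx))
  bc <- bray_curtis(cm)[idx]
  if (length(need_rc)) {
    rcdf <- raup_crick_bray(cm, pairs = idx[need_rc, , drop = FALSE],
                            n_nulls = n_nulls)
    rc[need_rc] <- rcdf$rc_bray
  }
  pairs <- data.frame(sample_i = cm$sample_ids[idx[, 1]],
                      sample_j = cm$sample_ids[idx[, 2]],
                      beta_mntd = bn$beta_mntd[idx], beta_nti = bnti,
                      bray_curtis = bc, rc_bray = rc,
                      process = classify_pair(bnti, rc),
                      stringsAsFactors = FALSE)
  list(pairs = pairs, fractions = process_fractions(pairs$process),
       n_nulls = n_nulls)
}

#' Mantel tests of betaNTI against each environmental variable
#'
#' Environmental pairwise distance is Euclidean (`|E_k - E_l|` for a single
#' variable).
#'
#' @param bnti betaNTI matrix.
#' @param env env_table or data.frame of environmental variables.
#' @param n_perm Mantel permutations.
#' @param seed optional integer seed.
#' @return data.frame: `variable`, `mantel_r`, `p`, `flag`.
#' @export
env_mantel <- function(bnti, env, n_perm = 999, seed = NULL) {
  if (inherits(env, "env_table")) env <- env$env
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(names(env), function(v) {
    if (stats::sd(env[[v]]) == 0)
      return(data.frame(variable = v, mantel_r = NA_real_, p = NA_real_,
                        flag = "constant variable"))
    dd <- as.matrix(stats::dist(env[[v]]))
    mt <- mantel_test(bnti, dd, n_perm = n_perm)
    data.frame(variable = v, mantel_r = mt$statistic, p = mt$p, flag = "")
  })
  do.call(rbind, rows)
}

#' betaNTI by salinity bins
#'
#' Samples are binned by EC quantiles; betaNTI of within-bin pairs is
#' summarized, with a Kruskal-Wallis omnibus test and pairwise Wilcoxon
#' rank-sum tests across bins. Bins with fewer than 2 samples are dropped
#' with a warning.
#'
#' @param bnti betaNTI matrix (samples in EC order of `ec`).
#' @param ec per-sample EC values.
#' @param n_bins number of quantile bins (default 4).
#' @return list: `per_bin` summary data.frame, `kruskal` result, `pairwise`
#'   data.frame of Wilcoxon p-values, `bins` (per-sample bin assignment).
#' @export
salinity_bin_analysis <- function(bnti, ec, n_bins = 4) {
  if (n_bins < 2) stop("n_bins must be >= 2")
  if (length(unique(ec)) < n_bins) stop("EC values do not support ", n_bins, " bins")
  br <- stats::quantile(ec, probs = seq(0, 1, length.out = n_bins + 1))
  if (anyDuplicated(br)) stop("EC quantiles are not distinct; fewer bins needed")
  bins <- cut(ec, breaks = br, include.lowest = TRUE, labels = FALSE)
  vals <- list()
  for (b in sort(unique(bins))) {
    members <- which(bins == b)
    if (length(members) < 2) {
      warning("bin ", b, " has < 2 samples; dropped")
      next
    }
    sub <- bnti[members, members]
    vals[[as.character(b)]] <- sub[upper.tri(sub)]
  }
  vals <- lapply(vals, function(v) v[!is.na(v)])
  vals <- vals[lengths(vals) > 0]
  if (length(vals) < 2) stop("fewer than 2 usable bins")
  per_bin <- data.frame(bin = names(vals), n_pairs = lengths(vals),
                        mean_bnti = vapply(vals, mean, 0),
                        median_bnti = vapply(vals, stats::median, 0))
  kw <- kruskal_wallis(vals)
  combos <- utils::combn(names(vals), 2)
  pw <- apply(combos, 2, function(cc) {
    wilcoxon_rank_sum(vals[[cc[1]]], vals[[cc[2]]])$p
  })
  pairwise <- data.frame(bin_i = combos[1, ], bin_j = combos[2, ], p = pw)
  list(per_bin = per_bin, kruskal = kw, pairwise = pairwise, bins = bins)
}
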