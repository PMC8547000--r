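# Internal machinery for threshold indicator taxon analysis. Candidates are
# midpoints between consecutive distinct sorted environmental values that
# leave at least min_split samples on each side. The per-candidate indicator
# value on side g is IndVal_g = 100 * A_g * B_g with A_g the side's share of
# the two group mean abundances and B_g the side's occurrence frequency.

titan_candidates <- function(env, min_split) {
  ord <- order(env)
  es <- env[ord]
  n <- length(es)
  k <- which(es[-n] < es[-1])           # split after position k
  k <- k[k >= min_split & (n - k) >= min_split]
  list(ord = ord, split_at = k, cp = (es[k] + es[k + 1]) / 2, n = n)
}

# a_sorted: abundance sorted by env order. Returns per-candidate IndVal on
# both sides.
indval_curves <- function(a_sorted, cand) {
  k <- cand$split_at
  n <- cand$n
  cumA <- cumsum(a_sorted)
  cumO <- cumsum(a_sorted > 0)
  meanL <- cumA[k] / k
  meanR <- (cumA[n] - cumA[k]) / (n - k)
  tot <- meanL + meanR
  AL <- ifelse(tot > 0, meanL / tot, 0)
  AR <- ifelse(tot > 0, meanR / tot, 0)
  BL <- cumO[k] / k
  BR <- (cumO[n] - cumO[k]) / (n - k)
  list(low = 100 * AL * BL, high = 100 * AR * BR)
}

#' IndVal change point of one taxon along an environmental gradient
#'
#' The taxon's change point is the candidate maximizing the larger of the two
#' side IndVals; ties go to the lowest candidate, and a side tie goes to the
#' decreasing (`z-`) side.
#'
#' @param abund per-sample abundance vector of the taxon.
#' @param env per-sample environmental values.
#' @param min_split minimum samples on each side of a candidate (default 5).
#' @return list: `change_point`, `indval` (in `[0,100]`), `side` (`"z-"` for
#'   taxa peaking on the low side / decreasing along the gradient, `"z+"`
#'   increasing), `candidates`.
#' @export
indval_changepoint <- function(abund, env, min_split = 5) {
  n <- length(env)
  if (length(abund) != n) stop("length mismatch")
  if (n < 2 * min_split) stop("too few samples for min_split = ", min_split)
  if (length(unique(env)) < 2) stop("environmental values all equal")
  if (all(abund == 0)) stop("taxon absent everywhere")
  cand <- titan_candidates(env, min_split)
  if (!length(cand$cp)) stop("no valid candidates (too many tied env values)")
  cv <- indval_curves(abund[cand$ord], cand)
  iv <- pmax(cv$low, cv$high)
  best <- which.max(iv)                  # which.max takes the first (lowest) tie
  side <- if (cv$low[best] >= cv$high[best]) "z-" else "z+"
  list(change_point = cand$cp[best], indval = iv[best], side = side,
       candidates = cand$cp)
}

#' Permutation z-score of a taxon's maximal IndVal
#'
#' Environmental values are permuted across samples (`n_perm` times), the
#' maximal IndVal is recomputed each time, and
#' `z = (IndVal_obs - mean_perm) / sd_perm`,
#' `p = (#\{perm >= obs\} + 1) / (n_perm + 1)`.
#'
#' @inheritParams indval_changepoint
#' @param n_perm permutations (default 250).
#' @param seed optional integer seed.
#' @return list: `z` (NA if the permutation sd is 0), `p`, `indval`,
#'   `change_point`, `side`.
#' @export
taxon_z <- function(abund, env, min_split = 5, n_perm = 250, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  obs <- indval_changepoint(abund, env, min_split)
  cand <- titan_candidates(env, min_split)
  perm_max <- vapply(seq_len(n_perm), function(b) {
    cv <- indval_curves(sample(abund)[cand$ord], cand)
    max(pmax(cv$low, cv$high))
  }, 0)
  m <- mean(perm_max); s <- stats::sd(perm_max)
  z <- if (s < 1e-12) NA_real_ else (obs$indval - m) / s
  p <- (sum(perm_max >= obs$indval - 1e-12) + 1) / (n_perm + 1)
  c(obs[c("change_point", "indval", "side")], list(z = z, p = p))
}

#' Bootstrap purity and reliability of a taxon's response
#'
#' Samples are resampled with replacement `n_boot` times; purity is the
#' fraction of replicates whose response direction matches the full-data
#' direction, reliability the fraction whose permutation p is at most
#' `alpha`. Replicates whose environmental draw cannot support a split are
#' skipped and counted.
#'
#' @inheritParams taxon_z
#' @param n_boot bootstrap replicates (default 500).
#' @param alpha significance level for reliability (default 0.05).
#' @param n_perm permutations inside each replicate.
#' @return list: `purity`, `reliability`, `pure_and_reliable`, `n_used`,
#'   `n_skipped`.
#' @export
bootstrap_purity_reliability <- function(abund, env, min_split = 5,
                                         n_boot = 500, alpha = 0.05,
                                         n_perm = 250, seed = NULL) {
  if (n_boot < 1) stop("n_boot must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  full <- indval_changepoint(abund, env, min_split)
  match_side <- 0L; signif <- 0L; used <- 0L; skipped <- 0L
  for (b in seq_len(n_boot)) {
    idx <- sample.int(length(env), replace = TRUE)
    eb <- env[idx]; ab <- abund[idx]
    res <- tryCatch(taxon_z(ab, eb, min_split, n_perm), error = function(e) NULL)
    if (is.null(res)) { skipped <- skipped + 1L; next }
    used <- used + 1L
    if (res$side == full$side) match_side <- match_side + 1L
    if (res$p <= alpha) signif <- signif + 1L
  }
  if (!used) stop("all bootstrap replicates degenerate")
  purity <- match_side / used
  reliability <- signif / used
  list(purity = purity, reliability = reliability,
       pure_and_reliable = purity >= 0.95 && reliability >= 0.95,
       n_used = used, n_skipped = skipped)
}

#' Per-taxon threshold analysis over a community
#'
#' Runs [indval_changepoint()], [taxon_z()] and
#' [bootstrap_purity_reliability()] for every taxon (on within-subcommunity
#' relative abundances) against one environmental variable.
#'
#' @param cm subcommunity [community_matrix()].
#' @param env per-sample values of one environmental variable.
#' @param min_split,n_perm,n_boot,alpha see the per-taxon functions.
#' @param seed optional integer seed.
#' @return data.frame per taxon: `otu_id`, `change_point`, `indval`, `side`,
#'   `z`, `p`, `purity`, `reliability`, `pure_and_reliable`.
#' @export
titan_analysis <- function(cm, env, min_split = 5, n_perm = 250, n_boot = 500,
                           alpha = 0.05, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(seq_along(cm$otu_ids), function(i) {
    a <- cm$rel_abund[, i]
    if (all(a == 0)) return(NULL)
    tz <- tryCatch(taxon_z(a, env, min_split, n_perm), error = function(e) NULL)
    if (is.null(tz)) return(NULL)
    bt <- bootstrap_purity_reliability(a, env, min_split, n_boot, alpha, n_perm)
    data.frame(otu_id = cm$otu_ids[i], change_point = tz$change_point,
               indval = tz$indval, side = tz$side, z = tz$z, p = tz$p,
               purity = bt$purity, reliability = bt$reliability,
               pure_and_reliable = bt$pure_and_reliable,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no analysable taxa")
  out
}

#' Community-level sum(z) thresholds and environmental breadth
#'
#' For every candidate change point, the z-scores of the side-specific
#' IndVals of pure-and-reliable taxa are summed separately over `z-` and
#' `z+` taxa; the community change points are the argmax of the two curves
#' (ties to the lowest candidate) and the breadth is their separation.
#'
#' @param cm subcommunity [community_matrix()].
#' @param env per-sample environmental values.
#' @param taxa result of [titan_analysis()] for the same inputs.
#' @param min_split,n_perm as in the per-taxon analysis.
#' @param seed optional integer seed.
#' @return list: `candidates`, `sumz_neg`, `sumz_pos`, `cp_neg`, `cp_pos`,
#'   `breadth`, `n_neg`, `n_pos`.
#' @export
community_thresholds <- function(cm, env, taxa, min_split = 5, n_perm = 250,
                                 seed = NULL) {
  qual <- taxa[taxa$pure_and_reliable & !is.na(taxa$z), ]
  if (!nrow(qual))
    stop("no pure-and-reliable taxa (", nrow(taxa), " analysed)")
  if (!is.null(seed)) set.seed(seed)
  cand <- titan_candidates(env, min_split)
  nc <- length(cand$cp)
  sumz <- list("z-" = numeric(nc), "z+" = numeric(nc))
  for (r in seq_len(nrow(qual))) {
    a <- cm$rel_abund[, qual$otu_id[r]]
    side <- qual$side[r]
    pick <- function(cv) if (side == "z-") cv$low else cv$high
    obs_curve <- pick(indval_curves(a[cand$ord], cand))
    perm <- matrix(0, n_perm, nc)
    for (b in seq_len(n_perm))
      perm[b, ] <- pick(indval_curves(sample(a)[cand$ord], cand))
    mu <- colMeans(perm)
    sdv <- apply(perm, 2, stats::sd)
    zc <- ifelse(sdv < 1e-12, 0, (obs_curve - mu) / sdv)
    sumz[[side]] <- sumz[[side]] + zc
  }
  cp_neg <- if (any(qual$side == "z-")) cand$cp[which.max(sumz[["z-"]])] else NA_real_
  cp_pos <- if (any(qual$side == "z+")) cand$cp[which.max(sumz[["z+"]])] else NA_real_
  list(candidates = cand$cp, sumz_neg = sumz[["z-"]], sumz_pos = sumz[["z+"]],
       cp_neg = cp_neg, cp_pos = cp_pos,
       breadth = abs(cp_pos - cp_neg),
       n_neg = sum(qual$side == "z-"), n_pos = sum(qual$side == "z+"))
}

#' Environmental breadth profile over variables
#'
#' Runs the full threshold analysis per environmental variable and reports
#' the community sum(z) breadth together with the 5th-95th percentile range
#' of individual pure-and-reliable change points (a secondary breadth
#' descriptor).
#'
#' @param cm subcommunity [community_matrix()].
#' @param env env_table or data.frame.
#' @param variables environmental variables (default all).
#' @param subcommunity label recorded in the output.
#' @param ... passed to [titan_analysis()].
#' @param seed optional integer seed.
#' @return data.frame: `variable`, `subcommunity`, `breadth`, `cp_neg`,
#'   `cp_pos`, `cp_p5`, `cp_p95`, `taxon_range`, `n_pure_reliable`.
#' @export
environmental_breadth_profile <- function(cm, env, variables = NULL,
                                          subcommunity = "community",
                                          seed = NULL, ...) {
  if (inherits(env, "env_table")) env <- env$env
  if (is.null(variables)) variables <- names(env)
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(variables, function(v) {
    out <- data.frame(variable = v, subcommunity = subcommunity,
                      breadth = NA_real_, cp_neg = NA_real_, cp_pos = NA_real_,
                      cp_p5 = NA_real_, cp_p95 = NA_real_,
                      taxon_range = NA_real_, n_pure_reliable = 0L)
    res <- tryCatch({
      taxa <- titan_analysis(cm, env[[v]], ...)
      ct <- community_thresholds(cm, env[[v]], taxa)
      qual <- taxa[taxa$pure_and_reliable, ]
      qs <- stats::quantile(qual$change_point, c(0.05, 0.95))
      out$breadth <- ct$breadth; out$cp_neg <- ct$cp_neg; out$cp_pos <- ct$cp_pos
      out$cp_p5 <- qs[1]; out$cp_p95 <- qs[2]
      out$taxon_range <- qs[2] - qs[1]
      out$n_pure_reliable <- nrow(qual)
      out
    }, error = function(e) out)
    res
  })
  do.call(rbind, rows)
}
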