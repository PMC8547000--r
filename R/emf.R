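#' Z-score ecosystem multifunctionality index
#'
#' Each function column is standardized to mean 0, sd 1 (sample sd) across
#' samples; the per-sample EMF score is the mean of its standardized function
#' values. With the full function set present, EMF itself averages to 0 over
#' samples.
#'
#' @param fm samples x functions numeric matrix/data.frame (>= 2 samples).
#' @return list: `emf` (named per-sample vector), `z` (standardized matrix).
#' @export
zscore_multifunctionality <- function(fm) {
  fm <- as.matrix(fm)
  if (nrow(fm) < 2) stop("need >= 2 samples")
  sds <- apply(fm, 2, stats::sd)
  if (any(sds == 0))
    stop("constant function column(s): ",
         paste(colnames(fm)[sds == 0], collapse = ", "))
  z <- scale(fm)
  emf <- rowMeans(z)
  list(emf = stats::setNames(emf, rownames(fm)), z = z[, , drop = FALSE])
}

#' Functional redundancy index (FRI) from per-OTU annotations
#'
#' A documented surrogate for reference-database redundancy scores: for
#' sample s and function f with capable present taxa C,
#' `FRI(s,f) = sum_{i in C} p_is * mean_{j in C, j != i} d(i,j)` where p is
#' within-sample relative abundance and d the cophenetic distance. A
#' function with zero or one capable present taxon scores 0.
#'
#' @param cm subcommunity [community_matrix()].
#' @param D cophenetic matrix covering the subcommunity's OTUs.
#' @param incidence OTU x function 0/1 matrix covering the subcommunity.
#' @return samples x functions FRI matrix (all entries >= 0).
#' @export
functional_redundancy_index <- function(cm, D, incidence) {
  incidence <- as.matrix(incidence)
  missing <- setdiff(cm$otu_ids, rownames(incidence))
  if (length(missing))
    stop("OTU(s) missing from incidence: ",
         paste(utils::head(missing, 5), collapse = ", "))
  inc <- incidence[cm$otu_ids, , drop = FALSE]
  D <- D[cm$otu_ids, cm$otu_ids, drop = FALSE]
  P <- cm$rel_abund
  out <- matrix(0, nrow(P), ncol(inc),
                dimnames = list(cm$sample_ids, colnames(inc)))
  for (f in seq_len(ncol(inc))) {
    cap <- which(inc[, f] > 0)
    if (length(cap) < 2) next
    Dsub <- D[cap, cap, drop = FALSE]
    for (s in seq_len(nrow(P))) {
      pres <- cap[P[s, cap] > 0]
      if (length(pres) < 2) next
      loc <- match(pres, cap)
      dsub <- Dsub[loc, loc, drop = FALSE]
      dbar <- (rowSums(dsub)) / (length(pres) - 1)
      out[s, f] <- sum(P[s, pres] * dbar)
    }
  }
  out
}

#' Census of exclusive and shared functions between two subcommunities
#'
#' A function is present in a subcommunity when at least one member OTU
#' carries it.
#'
#' @param inc_a,inc_b OTU x function incidence matrices restricted to each
#'   subcommunity (same function columns).
#' @return list: `only_a`, `only_b`, `shared` counts and the function name
#'   sets.
#' @export
unique_functions <- function(inc_a, inc_b) {
  fa <- colnames(inc_a)[colSums(inc_a) > 0]
  fb <- colnames(inc_b)[colSums(inc_b) > 0]
  list(only_a = length(setdiff(fa, fb)), only_b = length(setdiff(fb, fa)),
       shared = length(intersect(fa, fb)),
       functions_a = fa, functions_b = fb)
}

#' Per-function log2 redundancy ratio between two subcommunities
#'
#' `log2((mean_s FRI_A(s,f) + eps) / (mean_s FRI_B(s,f) + eps))`; positive
#' values mean the function is more redundant in A.
#'
#' @param fri_a,fri_b samples x functions FRI matrices with matching columns.
#' @param eps pseudocount; default half the smallest positive FRI observed.
#' @return named numeric vector per function.
#' @export
function_log_ratio <- function(fri_a, fri_b, eps = NULL) {
  ma <- colMeans(fri_a); mb <- colMeans(fri_b)
  if (is.null(eps)) {
    pos <- c(ma[ma > 0], mb[mb > 0])
    eps <- if (length(pos)) min(pos) / 2 else 1e-6
  }
  if (eps <= 0) stop("eps must be positive")
  log2((ma + eps) / (mb + eps))
}

#' Regression of EMF dissimilarity on FRI dissimilarity
#'
#' For every sample pair, x is the distance between FRI vectors (Euclidean
#' by default, Bray-Curtis optional) and y = |EMF_k - EMF_l|. Because pair
#' observations share samples, the OLS p is complemented by a Mantel-style
#' permutation p (sample labels permuted jointly in both matrices' second
#' argument).
#'
#' @param fri samples x functions FRI matrix.
#' @param emf per-sample EMF vector.
#' @param distance `"euclidean"` or `"bray"`.
#' @param n_perm permutations for the Mantel-style p.
#' @param seed optional integer seed.
#' @return list: `slope`, `intercept`, `r_squared`, `p_ols`, `p_perm`, `n`.
#' @export
fri_emf_regression <- function(fri, emf, distance = c("euclidean", "bray"),
                               n_perm = 999, seed = NULL) {
  distance <- match.arg(distance)
  if (nrow(fri) < 3) stop("need >= 3 samples")
  if (!is.null(seed)) set.seed(seed)
  Dx <- if (distance == "euclidean") as.matrix(stats::dist(fri)) else
    bray_curtis(sweep(pmax(fri, 0), 1, pmax(rowSums(fri), 1e-300), "/"))
  Dy <- as.matrix(stats::dist(emf))
  ut <- upper.tri(Dx)
  if (stats::sd(Dx[ut]) == 0)
    return(list(slope = NA_real_, r_squared = NA_real_, p_ols = NA_real_,
                p_perm = NA_real_, n = nrow(fri), flag = "constant FRI distances"))
  fit <- ols_regression(Dx[ut], Dy[ut])
  mt <- mantel_test(Dx, Dy, n_perm = n_perm)
  list(slope = fit$slope, intercept = fit$intercept,
       r_squared = fit$r_squared, p_ols = fit$p, p_perm = mt$p, n = nrow(fri))
}

#' Regression of EMF on an alpha-diversity vector
#'
#' @param diversity per-sample diversity metric (Shannon or SES.MNTD).
#' @param emf per-sample EMF vector.
#' @return [ols_regression()] result (EMF regressed on diversity).
#' @export
diversity_emf_regression <- function(diversity, emf) {
  ok <- !is.na(diversity) & !is.na(emf)
  if (sum(ok) < 3) stop("need >= 3 complete samples")
  if (stats::sd(diversity[ok]) == 0) stop("constant predictor")
  ols_regression(diversity[ok], emf[ok])
}
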