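#' Simulate a pure-birth (Yule) phylogeny
#'
#' Lineages split at exponential waiting times with per-lineage rate
#' `birth_rate`; the process starts from two root lineages and stops once
#' `n_tips` lineages exist, after which all pendant edges are extended by one
#' final exponential epoch so that the expected root-to-tip depth is
#' `sum(1/(birth_rate * k))` for k = 2..n_tips.
#'
#' @param n_tips number of tips (>= 2).
#' @param birth_rate per-lineage speciation rate (> 0).
#' @param seed optional integer seed.
#' @return rooted bifurcating `phylo` tree with tips `OTU_1..OTU_n`.
#' @export
simulate_tree <- function(n_tips, birth_rate = 1, seed = NULL) {
  if (n_tips < 2) stop("n_tips must be >= 2")
  if (birth_rate <= 0) stop("birth_rate must be positive")
  if (!is.null(seed)) set.seed(seed)
  # grow as a table of active lineages; each holds its pending edge start time
  n_nodes <- 2L * n_tips - 1L
  edge <- matrix(0L, n_nodes - 1L, 2)
  edge_len <- numeric(n_nodes - 1L)
  parent_of <- integer(n_nodes)
  birth_time <- numeric(n_nodes)
  root <- n_tips + 1L
  next_internal <- root
  # active lineages carry (parent node id, time born)
  act_parent <- c(root, root)
  act_born <- c(0, 0)
  t_now <- 0
  free_tip <- 1L
  edges <- list()
  k <- 2L
  while (k < n_tips) {
    t_now <- t_now + stats::rexp(1, rate = birth_rate * k)
    i <- sample.int(k, 1)
    next_internal <- next_internal + 1L
    edges[[length(edges) + 1L]] <- c(act_parent[i], next_internal,
                                     t_now - act_born[i])
    act_parent[i] <- next_internal
    act_born[i] <- t_now
    act_parent <- c(act_parent, next_internal)
    act_born <- c(act_born, t_now)
    k <- k + 1L
  }
  t_now <- t_now + stats::rexp(1, rate = birth_rate * k)
  for (i in seq_len(k)) {
    edges[[length(edges) + 1L]] <- c(act_parent[i], free_tip, t_now - act_born[i])
    free_tip <- free_tip + 1L
  }
  em <- do.call(rbind, edges)
  tree <- list(edge = matrix(as.integer(em[, 1:2]), ncol = 2),
               edge.length = em[, 3],
               tip.label = paste0("OTU_", seq_len(n_tips)),
               Nnode = n_tips - 1L)
  class(tree) <- "phylo"
  tree <- ape::reorder.phylo(tree, "cladewise")
  tree
}

#' Simulate a continuous trait under Brownian motion
#'
#' Root-to-tip accumulation of independent Normal(0, rate * branch_length)
#' increments; the root value is 0.
#'
#' @param tree `phylo` with branch lengths.
#' @param rate BM rate (variance per unit branch length, >= 0).
#' @param seed optional integer seed.
#' @return named numeric vector over tips.
#' @export
simulate_trait_bm <- function(tree, rate = 1, seed = NULL) {
  if (rate < 0) stop("rate must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  drop(bm_tips_matrix(tree, rate, 1))
}

# Vectorised BM simulation: returns an n_tips x n_rep matrix of tip values.
# Preorder pass: value(child) = value(parent) + Normal(0, rate * edge length).
bm_tips_matrix <- function(tree, rate, n_rep) {
  tree <- ape::reorder.phylo(tree, "cladewise")
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  vals <- matrix(0, n_node, n_rep)
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    sdv <- sqrt(rate * tree$edge.length[e])
    inc <- if (sdv > 0) stats::rnorm(n_rep, 0, sdv) else numeric(n_rep)
    vals[ch, ] <- vals[p, ] + inc
  }
  out <- vals[seq_len(n_tip), , drop = FALSE]
  rownames(out) <- tree$tip.label
  out
}

#' Simulate a binary trait on tips
#'
#' `random` shuffles a fixed-prevalence 0/1 vector uniformly across tips;
#' `threshold_bm` evolves a BM trait and marks the top `prevalence` fraction
#' of tips, producing phylogenetically clumped states.
#'
#' @param tree `phylo`.
#' @param mode `"random"` or `"threshold_bm"`.
#' @param prevalence fraction of tips in state 1 (0 < prevalence < 1).
#' @param seed optional integer seed.
#' @return named integer (0/1) vector over tips.
#' @export
simulate_binary_trait <- function(tree, mode = c("random", "threshold_bm"),
                                  prevalence = 0.5, seed = NULL) {
  mode <- match.arg(mode)
  if (prevalence <= 0 || prevalence >= 1) stop("prevalence must be in (0,1)")
  n <- length(tree$tip.label)
  k <- round(prevalence * n)
  if (k < 1) stop("prevalence * n_tips < 1")
  if (!is.null(seed)) set.seed(seed)
  x <- integer(n)
  if (mode == "random") {
    x[sample.int(n, k)] <- 1L
  } else {
    z <- simulate_trait_bm(tree, rate = 1)
    x[order(z, decreasing = TRUE)[seq_len(k)]] <- 1L
  }
  names(x) <- tree$tip.label
  x
}

#' Simulation configuration for the gradient metacommunity generator
#'
#' Defaults state the emulated study system: 90 samples on a salinity
#' gradient spanning 0.09-19.91 dS/m, a strongly skewed lognormal species
#' abundance distribution, Gaussian niche kernels with optima evolved under
#' Brownian motion on the tree (selection), exponential distance decay on a
#' 1-D transect (dispersal), and multinomial sequencing at 20,000 reads per
#' sample.
#'
#' @param n_samples number of samples (>= 2).
#' @param n_otus number of OTUs / tree tips.
#' @param gradient_min,gradient_max environmental gradient range (dS/m).
#' @param regime `"selection"`, `"dispersal"`, `"neutral"` or `"mixed"`.
#' @param niche_sigma Gaussian niche breadth in gradient units.
#' @param sad_meanlog,sad_sdlog lognormal SAD parameters.
#' @param birth_rate Yule tree rate.
#' @param bm_rate BM rate for niche-optimum evolution.
#' @param depth sequencing depth (reads per sample).
#' @param decay_scale e-folding distance of dispersal decay on the unit
#'   transect.
#' @param seed integer seed.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(n_samples = 90, n_otus = 800,
                              gradient_min = 0.09, gradient_max = 19.91,
                              regime = c("selection", "dispersal", "neutral", "mixed"),
                              niche_sigma = 2.5, sad_meanlog = 0, sad_sdlog = 2,
                              birth_rate = 1, bm_rate = 1, depth = 20000,
                              decay_scale = 0.1, seed = 1) {
  regime <- match.arg(regime)
  if (n_samples < 2) stop("n_samples must be >= 2")
  if (gradient_min >= gradient_max) stop("gradient min must be < max")
  if (niche_sigma <= 0) stop("niche_sigma must be positive")
  if (sad_sdlog <= 0) stop("sad_sdlog must be positive")
  structure(as.list(environment()), class = "simulation_config")
}

#' Simulate a gradient-structured metacommunity
#'
#' Samples are placed evenly on the gradient. Expected abundance of OTU i in
#' sample s is its lognormal base abundance multiplied by a regime kernel:
#' selection uses a Gaussian niche `exp(-(E_s - mu_i)^2 / (2 sigma^2))` with
#' optima `mu_i` evolved under BM on the tree (rescaled to the gradient
#' range); dispersal uses exponential decay `exp(-|x_s - h_i| / scale)` on a
#' unit transect whose coordinates are independent of the gradient; neutral
#' uses the base abundance only; mixed multiplies both kernels. Counts are
#' multinomial at the configured depth.
#'
#' @param config a [simulation_config()].
#' @return list of class `synthetic_dataset` with `community`
#'   ([community_matrix()]), `tree`, `env` ([env_table()] without functions),
#'   `truth` (per-OTU niche optima/breadths, transect homes, base
#'   abundances) and `regime`.
#' @export
simulate_gradient_metacommunity <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n <- config$n_samples
  N <- config$n_otus
  E <- seq(config$gradient_min, config$gradient_max, length.out = n)
  x <- seq(0, 1, length.out = n)
  tree <- simulate_tree(N, config$birth_rate)
  base <- stats::rlnorm(N, config$sad_meanlog, config$sad_sdlog)
  z <- simulate_trait_bm(tree, rate = config$bm_rate)
  # rescale the BM trait linearly onto the gradient range
  mu <- config$gradient_min +
    (z - min(z)) / max(max(z) - min(z), .Machine$double.eps) *
      (config$gradient_max - config$gradient_min)
  home <- stats::runif(N)
  lam <- matrix(base, n, N, byrow = TRUE)
  if (config$regime %in% c("selection", "mixed")) {
    kern <- exp(-outer(E, mu, "-")^2 / (2 * config$niche_sigma^2))
    lam <- lam * kern
  }
  if (config$regime %in% c("dispersal", "mixed")) {
    kern <- exp(-abs(outer(x, home, "-")) / config$decay_scale)
    lam <- lam * kern
  }
  counts <- t(vapply(seq_len(n), function(s) {
    p <- lam[s, ]
    stats::rmultinom(1, config$depth, p / sum(p))[, 1]
  }, integer(N)))
  rownames(counts) <- sprintf("S%02d", seq_len(n))
  colnames(counts) <- tree$tip.label
  cm <- community_matrix(counts)
  meta <- data.frame(sample_id = rownames(counts), EC = E, transect = x)
  # fill the remaining environmental variables with gradient-correlated or
  # independent noise so downstream drivers always find the 12 columns
  meta$pH <- 8 - 0.05 * E + stats::rnorm(n, 0, 0.2)
  for (v in c("TC", "TN", "IP", "OP", "TP", "AP", "TK", "AK", "NH4", "NO3"))
    meta[[v]] <- exp(stats::rnorm(n, 0, 0.5))
  env <- suppressWarnings(env_table(meta, community = cm))
  truth <- data.frame(otu_id = tree$tip.label, base_abundance = base,
                      niche_optimum = mu, niche_breadth = config$niche_sigma,
                      transect_home = home)
  structure(list(community = cm, tree = tree, env = env, truth = truth,
                 regime = config$regime, config = config),
            class = "synthetic_dataset")
}

#' Simulate per-OTU function annotations and per-sample function measurements
#'
#' Functions are gained on random clades (all descendant tips of a randomly
#' chosen internal node carry the function, plus a small background rate), so
#' membership is phylogenetically correlated. Per-sample measurements are
#' abundance-weighted sums of capable OTUs plus Gaussian noise.
#'
#' @param dataset a `synthetic_dataset`.
#' @param n_functions number of functions (>= 1).
#' @param sharing `"clade"` (default) or `"uniform"` (label-shuffled control).
#' @param background per-OTU probability of carrying a function regardless of
#'   clade.
#' @param noise_sd measurement noise standard deviation (on the abundance-sum
#'   scale).
#' @param seed optional integer seed.
#' @return list with `incidence` (OTU x function 0/1 matrix) and
#'   `measurements` (sample x function matrix).
#' @export
simulate_function_data <- function(dataset, n_functions = 17,
                                   sharing = c("clade", "uniform"),
                                   background = 0.02, noise_sd = 0.05,
                                   seed = NULL) {
  sharing <- match.arg(sharing)
  if (n_functions < 1) stop("n_functions must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  tree <- dataset$tree
  n_tip <- length(tree$tip.label)
  internal <- (n_tip + 1L):(n_tip + tree$Nnode)
  inc <- matrix(0L, n_tip, n_functions,
                dimnames = list(tree$tip.label,
                                if (n_functions == 17) default_function_vars()
                                else paste0("fun", seq_len(n_functions))))
  desc <- descendant_tips(tree)
  for (f in seq_len(n_functions)) {
    node <- sample(internal, 1)
    carriers <- desc[[node - n_tip]]
    inc[carriers, f] <- 1L
    inc[stats::runif(n_tip) < background, f] <- 1L
  }
  if (sharing == "uniform") {
    for (f in seq_len(n_functions)) inc[, f] <- sample(inc[, f])
  }
  P <- dataset$community$rel_abund[, rownames(inc), drop = FALSE]
  meas <- P %*% inc
  meas <- meas + matrix(stats::rnorm(length(meas), 0, noise_sd), nrow(meas))
  list(incidence = inc, measurements = meas)
}

# list of tip indices descending from each internal node (index 1 = root)
descendant_tips <- function(tree) {
  n_tip <- length(tree$tip.label)
  tr <- ape::reorder.phylo(tree, "postorder")
  out <- vector("list", tr$Nnode)
  for (e in seq_len(nrow(tr$edge))) {
    p <- tr$edge[e, 1] - n_tip
    ch <- tr$edge[e, 2]
    out[[p]] <- c(out[[p]], if (ch <= n_tip) ch else out[[ch - n_tip]])
  }
  out
}

#' Attach simulated function measurements to a synthetic dataset's env table
#' @param dataset a `synthetic_dataset`.
#' @param fundata result of [simulate_function_data()].
#' @return the dataset with `env$functions` filled in and `incidence` stored.
#' @export
attach_function_data <- function(dataset, fundata) {
  funs <- as.data.frame(fundata$measurements)
  rownames(funs) <- dataset$community$sample_ids
  dataset$env$functions <- funs
  dataset$incidence <- fundata$incidence
  dataset
}
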