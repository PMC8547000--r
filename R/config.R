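#' Run configuration for the full pipeline
#'
#' @param community_path,tree_path,metadata_path input file paths (TSV /
#'   newick / TSV). All three are required unless `simulate = TRUE`.
#' @param incidence_path optional OTU x function incidence TSV enabling the
#'   functional-redundancy stage.
#' @param simulate generate inputs with [simulate_gradient_metacommunity()]
#'   instead of reading files.
#' @param sim_config [simulation_config()] used when `simulate = TRUE`.
#' @param min_reads read filter threshold (default 20).
#' @param rare_thr,abundant_thr classification thresholds (defaults 1e-4,
#'   1e-3).
#' @param n_nulls null-model replicates (default 999).
#' @param n_perm permutation count for tests (default 999).
#' @param n_boot bootstrap replicates (default 500).
#' @param titan_n_perm permutations inside the threshold analysis
#'   (default 250).
#' @param alpha significance level (default 0.05).
#' @param weighted abundance weighting for the MNTD family.
#' @param renormalize renormalize subcommunity relative abundances.
#' @param seed integer seed recorded in every output.
#' @param outdir output directory.
#' @param stages which stages to run.
#' @return list of class `run_config`.
#' @export
run_config <- function(community_path = NULL, tree_path = NULL,
                       metadata_path = NULL, incidence_path = NULL,
                       simulate = FALSE, sim_config = simulation_config(),
                       min_reads = 20, rare_thr = 1e-4, abundant_thr = 1e-3,
                       n_nulls = 999, n_perm = 999, n_boot = 500,
                       titan_n_perm = 250, alpha = 0.05, weighted = TRUE,
                       renormalize = TRUE, seed = 1, outdir = "results",
                       stages = c("classify", "diversity", "assembly",
                                  "signal", "titan", "emf")) {
  if (!(rare_thr > 0 && rare_thr < abundant_thr && abundant_thr < 1))
    stop("need 0 < rare_thr < abundant_thr < 1")
  for (v in c("n_nulls", "n_perm", "n_boot", "titan_n_perm"))
    if (get(v) < 1) stop(v, " must be >= 1")
  if (!simulate) {
    paths <- list(community = community_path, tree = tree_path,
                  metadata = metadata_path)
    for (nm in names(paths)) {
      p <- paths[[nm]]
      if (is.null(p) || !file.exists(p))
        stop("missing input path (", nm, "): ",
             if (is.null(p)) "(unset)" else p)
    }
  }
  structure(as.list(environment()), class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Loads (or simulates) the inputs, applies the read filter and the
#' rare/abundant classification, and runs the enabled stages for the rare
#' and abundant subcommunities. Each stage writes a tab-separated results
#' table to `outdir`; a `manifest.json` records the configuration, seed and
#' package version. Identical config and seed give identical outputs.
#'
#' @param config a [run_config()].
#' @return (invisibly) a list of per-stage in-memory results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  incidence <- NULL
  if (config$simulate) {
    ds <- simulate_gradient_metacommunity(config$sim_config)
    ds <- attach_function_data(ds, simulate_function_data(ds))
    cm <- ds$community; tree <- ds$tree; env <- ds$env
    incidence <- ds$incidence
  } else {
    cm <- stage("io", read_community_table(config$community_path))
    tree <- stage("io", read_newick_tree(config$tree_path))
    env <- stage("io", read_sample_metadata(config$metadata_path, community = cm))
    if (!is.null(config$incidence_path)) {
      df <- utils::read.table(config$incidence_path, header = TRUE, sep = "\t",
                              row.names = 1, check.names = FALSE)
      incidence <- as.matrix(df)
    }
  }
  if (any(!cm$otu_ids %in% tree$tip.label))
    stop("pipeline stage 'io' failed: community OTUs missing from tree")
  results <- list()

  cm <- stage("classify", filter_low_read_otus(cm, config$min_reads))
  cls <- stage("classify", classify_otus(cm, config$rare_thr, config$abundant_thr))
  results$classification <- cls
  write_results_table(cls, file.path(config$outdir, "classification.tsv"))
  write_results_table(richness_shares(cls),
                      file.path(config$outdir, "richness_shares.tsv"))

  subs <- list()
  for (cl in c("rare", "abundant")) {
    if (any(cls$class == cl)) {
      sub <- extract_subcommunity(cm, cls, cl,
                                  renormalize = config$renormalize)
      nz <- rowSums(sub$counts) > 0
      if (!all(nz)) {
        warning(sum(!nz), " sample(s) empty in the ", cl,
                " subcommunity; dropped for that subcommunity")
        sub <- extract_subcommunity(
          community_matrix(cm$counts[nz, , drop = FALSE]), cls, cl,
          renormalize = config$renormalize)
      }
      subs[[cl]] <- sub
    }
  }
  run_stage <- function(nm) nm %in% config$stages

  if (run_stage("diversity") || run_stage("emf") || run_stage("assembly")) {
    div <- list()
    for (cl in names(subs)) {
      sub <- subs[[cl]]
      D <- cophenetic_matrix(tree, sub$otu_ids)
      sh <- shannon_index(sub)
      sm <- stage("diversity",
                  ses_mntd(sub, D, n_nulls = config$n_nulls,
                           weighted = config$weighted))
      div[[cl]] <- data.frame(sample_id = sub$sample_ids, subcommunity = cl,
                              shannon = sh, ses_mntd = sm$ses_mntd,
                              mntd_obs = sm$mntd_obs, seed = config$seed)
    }
    results$diversity <- do.call(rbind, div)
    if (run_stage("diversity"))
      write_results_table(results$diversity,
                          file.path(config$outdir, "diversity.tsv"))
  }

  if (run_stage("assembly")) {
    asm <- list(); frac <- list()
    for (cl in names(subs)) {
      sub <- subs[[cl]]
      D <- cophenetic_matrix(tree, sub$otu_ids)
      res <- stage("assembly",
                   assembly_analysis(sub, D, n_nulls = config$n_nulls,
                                     weighted = config$weighted))
      res$pairs$subcommunity <- cl
      asm[[cl]] <- res$pairs
      frac[[cl]] <- data.frame(subcommunity = cl,
                               process = names(res$fractions$fractions),
                               fraction = as.numeric(res$fractions$fractions),
                               seed = config$seed)
      results$assembly[[cl]] <- res
    }
    write_results_table(do.call(rbind, asm),
                        file.path(config$outdir, "assembly_pairs.tsv"))
    write_results_table(do.call(rbind, frac),
                        file.path(config$outdir, "assembly_fractions.tsv"))
  }

  if (run_stage("signal")) {
    sig <- list()
    for (cl in names(subs)) {
      sig[[cl]] <- stage("signal",
        signal_profile(subs[[cl]], tree, env, subcommunity = cl,
                       alpha = config$alpha, n_perm = config$n_perm))
    }
    results$signal <- do.call(rbind, sig)
    results$signal$seed <- config$seed
    write_results_table(results$signal, file.path(config$outdir, "signal.tsv"))
  }

  if (run_stage("titan")) {
    tit <- list()
    for (cl in names(subs)) {
      tit[[cl]] <- stage("titan",
        environmental_breadth_profile(subs[[cl]], env, subcommunity = cl,
                                      n_perm = config$titan_n_perm,
                                      n_boot = config$n_boot,
                                      alpha = config$alpha))
    }
    results$titan <- do.call(rbind, tit)
    write_results_table(results$titan, file.path(config$outdir, "titan.tsv"))
  }

  if (run_stage("emf") && !is.null(env$functions)) {
    emf <- stage("emf", zscore_multifunctionality(env$functions))
    results$emf <- emf
    emf_rows <- data.frame(sample_id = env$sample_ids, emf = emf$emf,
                           seed = config$seed)
    write_results_table(emf_rows, file.path(config$outdir, "emf.tsv"))
    reg <- list()
    for (cl in names(subs)) {
      dv <- results$diversity[results$diversity$subcommunity == cl, ]
      emf_cl <- emf$emf[dv$sample_id]
      for (m in c("shannon", "ses_mntd")) {
        fit <- tryCatch(diversity_emf_regression(dv[[m]], emf_cl),
                        error = function(e) NULL)
        if (!is.null(fit))
          reg[[paste(cl, m)]] <- data.frame(subcommunity = cl, metric = m,
                                            slope = fit$slope,
                                            r_squared = fit$r_squared,
                                            p = fit$p)
      }
      if (!is.null(incidence)) {
        D <- cophenetic_matrix(tree, subs[[cl]]$otu_ids)
        fri <- stage("emf", functional_redundancy_index(subs[[cl]], D,
                                                        incidence))
        fr <- fri_emf_regression(fri, emf$emf[subs[[cl]]$sample_ids],
                                 n_perm = config$n_perm)
        reg[[paste(cl, "fri")]] <- data.frame(subcommunity = cl, metric = "fri",
                                              slope = fr$slope,
                                              r_squared = fr$r_squared,
                                              p = fr$p_perm)
      }
    }
    if (length(reg))
      write_results_table(do.call(rbind, reg),
                          file.path(config$outdir, "emf_regressions.tsv"))
  }

  manifest <- list(
    seed = config$seed,
    package_version = as.character(utils::packageVersion("saltrare")),
    config = config[!vapply(config, is.function, TRUE)],
    stages = config$stages,
    timestamp_free = TRUE)
  manifest$config$sim_config <- unclass(manifest$config$sim_config)
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  invisible(results)
}
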