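#' Construct a community matrix
#'
#' The central observational object: a samples x OTUs table of non-negative
#' integer read counts together with per-sample relative abundances.
#'
#' @param counts numeric matrix of non-negative integers, samples in rows,
#'   OTUs in columns; dimnames are used as sample and OTU ids.
#' @param sample_ids,otu_ids optional character vectors overriding dimnames.
#' @return An object of class `community_matrix` with elements `counts`,
#'   `rel_abund`, `sample_ids`, `otu_ids`.
#' @export
community_matrix <- function(counts, sample_ids = rownames(counts),
                             otu_ids = colnames(counts)) {
  counts <- as.matrix(counts)
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(counts)))
  if (is.null(otu_ids)) otu_ids <- paste0("OTU_", seq_len(ncol(counts)))
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids: ",
    paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (anyDuplicated(otu_ids)) stop("duplicate OTU ids: ",
    paste(unique(otu_ids[duplicated(otu_ids)]), collapse = ", "))
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("counts must be finite and non-negative")
  if (any(counts != round(counts)))
    stop("counts must be integers")
  storage.mode(counts) <- "double"
  dimnames(counts) <- list(sample_ids, otu_ids)
  tot <- rowSums(counts)
  rel <- counts
  ok <- tot > 0
  rel[ok, ] <- counts[ok, , drop = FALSE] / tot[ok]
  structure(list(counts = counts, rel_abund = rel,
                 sample_ids = sample_ids, otu_ids = otu_ids),
            class = "community_matrix")
}

#' @export
print.community_matrix <- function(x, ...) {
  cat("<community_matrix> ", length(x$sample_ids), " samples x ",
      length(x$otu_ids), " OTUs, ", sum(x$counts), " reads\n", sep = "")
  invisible(x)
}

#' Read an OTU count table
#'
#' Reads a tab-separated count table and auto-detects orientation from the
#' header: a first column named `otu_id`/`OTU_ID`/`#OTU ID`/`OTU` means OTUs
#' are rows (the table is transposed on read); `sample_id`/`sample` means
#' samples are rows. Internally everything is stored samples x OTUs.
#'
#' @param path file path to a TSV table.
#' @param orientation `"auto"` (default), `"samples"` (rows are samples) or
#'   `"otus"` (rows are OTUs).
#' @return a [community_matrix()].
#' @export
read_community_table <- function(path, orientation = c("auto", "samples", "otus")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("no such file: ", path)
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                      comment.char = "", stringsAsFactors = FALSE),
    error = function(e) stop("parse error in ", path, ": ", conditionMessage(e)))
  if (nrow(df) == 0L || ncol(df) < 2L) stop("parse error: empty or malformed table in ", path)
  idcol <- names(df)[1]
  if (orientation == "auto") {
    orientation <- if (tolower(idcol) %in% c("otu_id", "#otu id", "otu", "otuid"))
      "otus" else "samples"
  }
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(!apply(df[, -1, drop = FALSE], 2, function(col) {
      suppressWarnings(all(!is.na(as.numeric(col))))
    }))
    stop("parse error: non-numeric cells in column(s) ",
         paste(names(df)[-1][bad], collapse = ", "))
  }
  if (any(m < 0)) {
    bad <- which(m < 0, arr.ind = TRUE)[1, ]
    stop("parse error: negative count at row ", ids[bad[1]],
         ", column ", colnames(m)[bad[2]])
  }
  rownames(m) <- ids
  if (orientation == "otus") m <- t(m)
  community_matrix(m)
}

#' Write a community matrix back to TSV (samples as rows)
#' @param cm a [community_matrix()].
#' @param path output file path.
#' @export
write_community_table <- function(cm, path) {
  df <- data.frame(sample_id = cm$sample_ids, cm$counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a rooted newick phylogeny
#'
#' @param path newick file.
#' @param root_method what to do with an unrooted tree: `"error"` (default)
#'   or `"midpoint"` (midpoint rooting).
#' @return an [ape::ape-package] `phylo` object, validated: unique tip
#'   labels, branch lengths present and non-negative.
#' @export
read_newick_tree <- function(path, root_method = c("error", "midpoint")) {
  root_method <- match.arg(root_method)
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) stop("newick parse error: ", conditionMessage(e)))
  if (is.null(tree)) stop("newick parse error: unreadable tree in ", path)
  validate_tree(tree, root_method)
}

validate_tree <- function(tree, root_method = "error") {
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip label(s): ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "))
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch length")
  # a pure star (single internal node) is read as a rooted polytomy; a basal
  # polytomy on a structured tree is the newick convention for "unrooted"
  if (!ape::is.rooted(tree) && tree$Nnode > 1) {
    if (root_method == "midpoint") {
      if (!requireNamespace("phangorn", quietly = TRUE))
        stop("midpoint rooting requires the phangorn package")
      tree <- phangorn::midpoint(tree)
    } else {
      stop("tree is unrooted; re-run with root_method = \"midpoint\" to midpoint-root it")
    }
  }
  tree
}

#' Default environmental variable and ecosystem function column names
#'
#' The twelve physicochemical variables (salinity as EC in dS/m, pH, carbon,
#' nitrogen and the phosphorus/potassium pools) and the seventeen ecosystem
#' functions (nutrient pools plus enzyme activities spanning C, N and P
#' cycling) used throughout the pipeline.
#' @return character vector of column names.
#' @export
default_env_vars <- function() {
  c("pH", "EC", "TC", "TN", "IP", "OP", "TP", "AP", "TK", "AK", "NH4", "NO3")
}

#' @rdname default_env_vars
#' @export
default_function_vars <- function() {
  c("TC", "BG", "CBH", "BF", "PhOx",          # C cycling
    "TN", "NH4", "NO3", "Ure", "Ary", "NAG",  # N cycling
    "TP", "AP", "IP", "OP", "Pho", "Phy")     # P cycling
}

#' Read per-sample environmental metadata and ecosystem functions
#'
#' Samples are rows; the first column is the sample id. Columns listed in
#' `env_vars`/`function_vars` are validated (numeric, no missing values);
#' function columns are taken from `F_<name>` columns when present so that
#' nutrient pools (TC, TN, ...) can appear both as environment and as
#' function measurements. Extra columns are carried through with a warning.
#'
#' @param path TSV file.
#' @param env_vars,function_vars column name lists.
#' @param community optional [community_matrix()] whose sample ids must match.
#' @return list of class `env_table` with `sample_ids`, `env` (data.frame),
#'   `functions` (data.frame or NULL), `extra`.
#' @export
read_sample_metadata <- function(path, env_vars = default_env_vars(),
                                 function_vars = default_function_vars(),
                                 community = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  env_table(df, env_vars, function_vars, community)
}

#' Build an env_table from a data.frame
#' @param df data.frame whose first column holds sample ids.
#' @inheritParams read_sample_metadata
#' @export
env_table <- function(df, env_vars = default_env_vars(),
                      function_vars = default_function_vars(),
                      community = NULL) {
  sample_ids <- as.character(df[[1]])
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids in metadata")
  rownames(df) <- sample_ids
  missing_env <- setdiff(env_vars, names(df))
  if (length(missing_env))
    stop("metadata lacks environmental column(s): ", paste(missing_env, collapse = ", "))
  env <- df[, env_vars, drop = FALSE]
  for (v in env_vars) {
    bad <- which(is.na(suppressWarnings(as.numeric(env[[v]]))))
    if (length(bad))
      stop("missing/non-numeric ", v, " for sample(s): ",
           paste(sample_ids[bad], collapse = ", "))
    env[[v]] <- as.numeric(env[[v]])
  }
  if ("EC" %in% env_vars && any(env$EC < 0)) stop("EC must be non-negative")
  fn_cols <- ifelse(paste0("F_", function_vars) %in% names(df),
                    paste0("F_", function_vars),
                    function_vars)
  funs <- NULL
  if (all(fn_cols %in% names(df))) {
    funs <- df[, fn_cols, drop = FALSE]
    names(funs) <- function_vars
    for (v in function_vars) {
      if (any(is.na(funs[[v]]))) stop("missing function value ", v)
      funs[[v]] <- as.numeric(funs[[v]])
    }
  }
  extra <- setdiff(names(df)[-1], c(env_vars, fn_cols))
  if (length(extra))
    warning("extra metadata column(s) carried through: ", paste(extra, collapse = ", "))
  if (!is.null(community)) {
    mism <- c(setdiff(community$sample_ids, sample_ids),
              setdiff(sample_ids, community$sample_ids))
    if (length(mism))
      stop("sample id mismatch with community table: ", paste(mism, collapse = ", "))
    env <- env[community$sample_ids, , drop = FALSE]
    if (!is.null(funs)) funs <- funs[community$sample_ids, , drop = FALSE]
    sample_ids <- community$sample_ids
  }
  structure(list(sample_ids = sample_ids, env = env, functions = funs,
                 extra = df[, extra, drop = FALSE]),
            class = "env_table")
}

#' Write a results table with 6-significant-digit formatting plus a
#' full-precision sidecar (`<path>.full.tsv`).
#' @param df data.frame of results.
#' @param path output TSV path.
#' @export
write_results_table <- function(df, path) {
  pretty <- df
  for (j in seq_along(pretty)) {
    if (is.numeric(pretty[[j]]) && !is.integer(pretty[[j]]))
      pretty[[j]] <- signif(pretty[[j]], 6)
  }
  utils::write.table(pretty, path, sep = "\t", quote = FALSE, row.names = FALSE)
  full <- df
  for (j in seq_along(full)) {
    if (is.numeric(full[[j]]) && !is.integer(full[[j]]))
      full[[j]] <- sprintf("%.17g", full[[j]])
  }
  utils::write.table(full, paste0(path, ".full.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
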