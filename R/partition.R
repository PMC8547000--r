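#' Remove OTUs with fewer than `min_reads` total reads
#'
#' Dataset-wide totals are used; the comparison is strict ("less than"), so
#' an OTU with exactly `min_reads` reads is retained. Relative abundances are
#' recomputed after filtering.
#'
#' @param cm a [community_matrix()].
#' @param min_reads minimum dataset-wide read total (default 20).
#' @return filtered [community_matrix()].
#' @export
filter_low_read_otus <- function(cm, min_reads = 20) {
  if (min_reads < 0) stop("min_reads must be >= 0")
  keep <- colSums(cm$counts) >= min_reads
  if (!any(keep)) stop("all OTUs removed by the read filter")
  community_matrix(cm$counts[, keep, drop = FALSE])
}

#' Classify OTUs as rare / intermediate / abundant
#'
#' Per-OTU dataset-wide relative abundance `r_i` = total reads of OTU i over
#' total reads of all retained OTUs. Strict thresholds: `r_i < rare_thr` is
#' rare, `r_i > abundant_thr` is abundant, everything else (boundaries
#' included) is intermediate. Defaults are 0.01% and 0.1%.
#'
#' @param cm filtered [community_matrix()].
#' @param rare_thr,abundant_thr relative-abundance thresholds with
#'   `0 < rare_thr < abundant_thr < 1`.
#' @return data.frame of class `abundance_classification`: `otu_id`, `reads`,
#'   `rel_abund`, `class`, `occupancy`.
#' @export
classify_otus <- function(cm, rare_thr = 1e-4, abundant_thr = 1e-3) {
  if (!(rare_thr > 0 && rare_thr < abundant_thr && abundant_thr < 1))
    stop("need 0 < rare_thr < abundant_thr < 1")
  reads <- colSums(cm$counts)
  total <- sum(reads)
  if (total == 0) stop("community has zero total reads")
  r <- reads / total
  cls <- ifelse(r < rare_thr, "rare", ifelse(r > abundant_thr, "abundant", "intermediate"))
  out <- data.frame(otu_id = cm$otu_ids, reads = unname(reads),
                    rel_abund = unname(r), class = unname(cls),
                    occupancy = unname(occupancy(cm)),
                    stringsAsFactors = FALSE)
  class(out) <- c("abundance_classification", "data.frame")
  out
}

#' Per-OTU occupancy (fraction of samples where the OTU occurs)
#' @param cm a [community_matrix()].
#' @return named numeric vector in `[0, 1]`.
#' @export
occupancy <- function(cm) {
  colMeans(cm$counts > 0)
}

#' Richness and abundance shares of each class
#'
#' Reports, per class, the number of OTUs, the share of total richness and
#' the share of total reads, as percentages rounded the way field summaries
#' print them (one decimal).
#'
#' @param classification an `abundance_classification`.
#' @return data.frame with `class`, `n_otus`, `richness_share_pct`,
#'   `abundance_share_pct`.
#' @export
richness_shares <- function(classification) {
  n_total <- nrow(classification)
  agg <- lapply(split(classification, classification$class), function(d) {
    data.frame(class = d$class[1], n_otus = nrow(d),
               richness_share_pct = round(100 * nrow(d) / n_total, 1),
               abundance_share_pct = round(100 * sum(d$rel_abund), 1))
  })
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out
}

#' Abundance-occupancy regression within a subcommunity
#'
#' OLS of occupancy on log10(total reads) over the OTUs of one class.
#'
#' @param classification an `abundance_classification`.
#' @param subcommunity `"rare"`, `"intermediate"` or `"abundant"`.
#' @return list with `slope`, `intercept`, `r_squared`, `p`, `n`.
#' @export
abundance_occupancy_regression <- function(classification,
                                           subcommunity = c("rare", "abundant", "intermediate")) {
  subcommunity <- match.arg(subcommunity)
  d <- classification[classification$class == subcommunity, ]
  if (nrow(d) < 3) stop("need >= 3 OTUs in the ", subcommunity, " class")
  ols_regression(log10(d$reads), d$occupancy)
}

#' Extract the community matrix of one abundance class
#'
#' Counts are restricted to the OTUs of the requested class. With
#' `renormalize = TRUE` (default) per-sample relative abundances are
#' recomputed within the subcommunity so diversity statistics act on proper
#' distributions; with `FALSE` the whole-community relative abundances are
#' kept in `rel_abund`.
#'
#' @param cm a [community_matrix()].
#' @param classification an `abundance_classification` for `cm`.
#' @param class which class to extract.
#' @param renormalize renormalize per-sample relative abundances within the
#'   subcommunity.
#' @return a [community_matrix()].
#' @export
extract_subcommunity <- function(cm, classification,
                                 class = c("rare", "intermediate", "abundant"),
                                 renormalize = TRUE) {
  class <- match.arg(class)
  ids <- classification$otu_id[classification$class == class]
  if (!length(ids)) stop("no OTUs in class ", class)
  sub <- community_matrix(cm$counts[, ids, drop = FALSE])
  if (!renormalize) {
    tot <- rowSums(cm$counts)
    sub$rel_abund <- sweep(sub$counts, 1, pmax(tot, 1), "/")
  }
  sub
}
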