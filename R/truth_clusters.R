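#' Build a cluster set from the simulator's ground truth
#'
#' Converts the known cluster membership of a simulated linkage group
#' into a `cluster_set`, the same structure [find_clusters()] estimates
#' from the calls. This is the known-truth route for resampling
#' experiments on noisy simulations: with per-call miscalls, estimated
#' zero-recombination clusters fragment (each miscall breaks exact
#' co-segregation), while the experiment design is defined in terms of
#' the markers that truly share a position.
#'
#' @param truth truth table from [simulate_dh_population()] (or the
#'   `truth` attribute of [sim_lg_genotypes()]), restricted to one LG.
#' @param geno character call matrix carrying the truth's markers (used
#'   for the PIC and missing-fraction columns).
#' @return a `cluster_set` data frame; see [find_clusters()].
#' @export
clusters_from_truth <- function(truth, geno) {
  stopifnot(all(truth$marker %in% colnames(geno)))
  ids <- match(truth$cluster_id, unique(truth$cluster_id))
  sizes <- table(ids)
  cs <- data.frame(marker = truth$marker,
                   cluster_id = sprintf("C%04d", ids),
                   cluster_size = as.integer(sizes[as.character(ids)]),
                   is_coseg = as.integer(sizes[as.character(ids)]) >= 2,
                   pic = compute_pic(geno, truth$marker),
                   missing_frac = colMeans(geno[, truth$marker,
                                                drop = FALSE] == "U"),
                   row.names = NULL, stringsAsFactors = FALSE)
  class(cs) <- c("cluster_set", "data.frame")
  attr(cs, "n_clusters") <- length(unique(ids))
  attr(cs, "n_coseg") <- nrow(cs) - length(unique(ids))
  cs
}
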