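#' Detect co-segregation clusters on a linkage group
#'
#' Co-segregating markers are markers mapping to the same genetic
#' position: pairs with an estimated recombination fraction of exactly
#' zero (no discordant calls among at least `min_informative`
#' pairwise-complete lines). Clusters are the connected components of
#' the zero-recombination graph, so markers that differ only at missing
#' positions fall in the same cluster. A marker is flagged
#' co-segregating when its cluster has two or more members; the
#' bookkeeping count of co-segregating markers on the LG is
#' `total markers - number of clusters` (each cluster contributes its
#' size minus the one delegate that will represent it).
#'
#' @param geno character call matrix.
#' @param lg_markers marker names of one linkage group.
#' @param min_informative minimum pairwise-complete lines for a zero
#'   estimate to count.
#' @param pw optional precomputed [pairwise_linkage()] object.
#' @return a `cluster_set`: data frame marker, cluster_id, cluster_size,
#'   is_coseg, pic, missing_frac; attributes `n_clusters` and `n_coseg`.
#' @export
find_clusters <- function(geno, lg_markers = colnames(geno),
                          min_informative = 20, pw = NULL) {
  if (is.null(pw))
    pw <- pairwise_linkage(geno[, lg_markers, drop = FALSE],
                           min_informative)
  d <- pw$d[lg_markers, lg_markers, drop = FALSE]
  n <- pw$n[lg_markers, lg_markers, drop = FALSE]
  adj <- d == 0 & n >= pw$min_informative
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  member <- igraph::components(g)$membership
  # stable cluster ids in order of first appearance along lg_markers
  ids <- match(member, unique(member))
  sizes <- table(ids)
  cs <- data.frame(marker = lg_markers,
                   cluster_id = sprintf("C%04d", ids),
                   cluster_size = as.integer(sizes[as.character(ids)]),
                   is_coseg = as.integer(sizes[as.character(ids)]) >= 2,
                   pic = compute_pic(geno)[lg_markers],
                   missing_frac = colMeans(geno[, lg_markers,
                                                drop = FALSE] == "U"),
                   row.names = NULL, stringsAsFactors = FALSE)
  class(cs) <- c("cluster_set", "data.frame")
  attr(cs, "n_clusters") <- length(unique(ids))
  attr(cs, "n_coseg") <- nrow(cs) - length(unique(ids))
  cs
}

#' Polymorphism information content of biallelic markers
#'
#' PIC = 1 - p^2 - q^2 with p and q the A and B allele frequencies over
#' non-missing calls; 0.5 is the maximum for a biallelic marker.
#'
#' @param geno character call matrix.
#' @param markers marker names (default all).
#' @return named numeric vector of PIC values; all-missing markers give
#'   NA with a warning.
#' @export
compute_pic <- function(geno, markers = colnames(geno)) {
  sub <- geno[, markers, drop = FALSE]
  n_a <- colSums(sub == "A")
  n_b <- colSums(sub == "B")
  n <- n_a + n_b
  if (any(n == 0)) warning("PIC undefined for all-missing marker(s)")
  p <- ifelse(n > 0, n_a / n, NA_real_)
  pic <- 1 - p^2 - (1 - p)^2
  names(pic) <- markers
  pic
}

#' Select the delegate marker of every cluster
#'
#' The delegate is the most informative member: highest PIC, then
#' lowest missing fraction, remaining ties resolved by a seeded uniform
#' random draw.
#'
#' @param clusters a [find_clusters()] `cluster_set`.
#' @param seed RNG seed for tie-breaking.
#' @return the cluster_set with an `is_delegate` logical column.
#' @export
select_delegates <- function(clusters, seed = 1L) {
  stopifnot(inherits(clusters, "cluster_set"))
  delegate <- with_seed(seed, {
    vapply(split(seq_len(nrow(clusters)), clusters$cluster_id),
           function(rows) {
             cand <- rows[clusters$pic[rows] ==
                            max(clusters$pic[rows], na.rm = TRUE)]
             cand <- cand[clusters$missing_frac[cand] ==
                            min(clusters$missing_frac[cand])]
             if (length(cand) > 1) cand <- sample(cand, 1)
             cand
           }, 0L)
  })
  clusters$is_delegate <- seq_len(nrow(clusters)) %in% delegate
  clusters
}

#' Proportion of co-segregating markers
#'
#' The percentage of an LG's (or genome's) markers that are
#' co-segregating, i.e. `n_coseg / n_total * 100` with
#' `n_coseg = n_total - n_clusters`, rounded to the integer percent in
#' which map summaries are conventionally reported.
#'
#' @param n_coseg count of co-segregating markers (or a `cluster_set`,
#'   from which both counts are taken).
#' @param n_total total marker count.
#' @param digits rounding digits (default 0).
#' @return the percentage.
#' @export
coseg_proportion <- function(n_coseg, n_total = NULL, digits = 0) {
  if (inherits(n_coseg, "cluster_set")) {
    n_total <- nrow(n_coseg)
    n_coseg <- attr(n_coseg, "n_coseg")
  }
  round(100 * n_coseg / n_total, digits)
}

#' Build the skeleton map of a linkage group
#'
#' Orders and maps only the delegate markers (one per co-segregation
#' cluster). Its length `L_sket` is the reference length against which
#' sequential maps are compared.
#'
#' @param geno character call matrix.
#' @param clusters a `cluster_set` with delegates selected (if
#'   `is_delegate` is absent, delegates are selected with `seed`).
#' @param fn mapping function.
#' @param lg_id linkage-group label.
#' @param min_informative minimum informative lines per pair.
#' @param seed delegate tie-break seed when delegates are not yet chosen.
#' @param pw optional precomputed [pairwise_linkage()] object covering
#'   the LG's markers.
#' @return a `genetic_map` of the delegates; an LG with fewer than two
#'   clusters yields a single-marker, zero-length map with a warning.
#' @export
build_skeleton <- function(geno, clusters, fn = c("kosambi", "haldane"),
                           lg_id = "LG1", min_informative = 20,
                           seed = 1L, pw = NULL) {
  fn <- match.arg(fn)
  if (is.null(clusters$is_delegate))
    clusters <- select_delegates(clusters, seed)
  delegates <- clusters$marker[clusters$is_delegate]
  if (length(delegates) < 2) {
    warning("linkage group has fewer than 2 clusters; zero-length skeleton")
    return(build_map(geno, delegates, fn, lg_id, min_informative, pw = pw))
  }
  ord <- order_markers(geno, delegates, min_informative, pw = pw)
  build_map(geno, ord, fn, lg_id, min_informative, pw = pw)
}
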