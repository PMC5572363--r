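#' Pairwise recombination statistics for all marker pairs
#'
#' Computes, for every pair of markers, the number of lines genotyped at
#' both (`n`), the discordant-call count (`d`), the DH recombination
#' fraction estimate `r = d / n`, and the two-sided p-value of the exact
#' binomial test of independence (r = 1/2). All quantities come from two
#' cross-products of the coded call matrix, so the whole-matrix cost is
#' one BLAS call rather than a loop over pairs.
#'
#' @param geno character call matrix (lines x markers, A/B/U).
#' @param min_informative minimum shared non-missing lines for a usable
#'   estimate; pairs below it are flagged uninformative (r and p set to
#'   NA) and treated as unlinked downstream.
#' @return an object of class `pairwise_linkage`: a list of matrices
#'   `r`, `d`, `n`, `p` (markers x markers) plus `min_informative`.
#' @export
pairwise_linkage <- function(geno, min_informative = 20) {
  check_geno(geno)
  x <- geno_numeric(geno)
  obs <- (x != 0) * 1
  n <- crossprod(obs)              # shared non-missing lines
  s <- crossprod(x)                # agreements minus disagreements
  d <- (n - s) / 2                 # discordant counts
  r <- ifelse(n > 0, d / n, NA_real_)
  # exact two-sided binomial test of d ~ Bin(n, 1/2); symmetry makes the
  # doubled smaller tail exact (capped at 1 for the central value)
  p <- matrix(pmin(1, 2 * pbinom(pmin(d, n - d), n, 0.5)),
              nrow(n), ncol(n), dimnames = dimnames(n))
  p[n == 0] <- NA_real_
  bad <- n < min_informative
  r[bad] <- NA_real_
  p[bad] <- NA_real_
  diag(r) <- 0
  diag(p) <- NA_real_
  structure(list(r = r, d = d, n = n, p = p,
                 min_informative = min_informative),
            class = "pairwise_linkage")
}

#' Estimate the recombination fraction between two markers
#'
#' DH estimator: the fraction of discordant calls among lines
#' non-missing at both markers, with an exact two-sided binomial test of
#' independence (null r = 1/2).
#'
#' @param geno character call matrix.
#' @param marker_i,marker_j marker names.
#' @param min_informative minimum shared non-missing lines; below it the
#'   pair is flagged uninformative.
#' @return a one-row data frame: marker_i, marker_j, r_hat (raw),
#'   n_informative, d_discordant, p_indep, informative (logical).
#' @export
estimate_r <- function(geno, marker_i, marker_j, min_informative = 20) {
  check_geno(geno)
  stopifnot(marker_i %in% colnames(geno), marker_j %in% colnames(geno))
  pw <- pairwise_linkage(geno[, c(marker_i, marker_j), drop = FALSE],
                         min_informative = min_informative)
  data.frame(marker_i = marker_i, marker_j = marker_j,
             r_hat = pw$r[1, 2], n_informative = pw$n[1, 2],
             d_discordant = pw$d[1, 2], p_indep = pw$p[1, 2],
             informative = pw$n[1, 2] >= min_informative,
             stringsAsFactors = FALSE)
}

#' Convert recombination fractions to map distances
#'
#' Haldane (no interference): d = -50 ln(1 - 2r). Kosambi (partial
#' interference): d = 25 ln((1 + 2r) / (1 - 2r)). Both in centiMorgan.
#'
#' @param r recombination fraction(s) in `[0, 0.5)`.
#' @param fn `"kosambi"` (default) or `"haldane"`.
#' @return distance(s) in cM.
#' @export
map_distance <- function(r, fn = c("kosambi", "haldane")) {
  fn <- match.arg(fn)
  if (any(r < 0 | r >= 0.5, na.rm = TRUE))
    stop("map_distance requires 0 <= r < 0.5; clamp first")
  switch(fn,
         haldane = -50 * log(1 - 2 * r),
         kosambi = 25 * log((1 + 2 * r) / (1 - 2 * r)))
}

#' Convert map distances back to recombination fractions
#'
#' Inverse of [map_distance()].
#'
#' @param d distance(s) in cM, non-negative.
#' @param fn mapping function.
#' @return recombination fraction(s) in `[0, 0.5)`.
#' @export
dist_to_r <- function(d, fn = c("kosambi", "haldane")) {
  fn <- match.arg(fn)
  if (any(d < 0, na.rm = TRUE)) stop("distances must be non-negative")
  switch(fn,
         haldane = (1 - exp(-d / 50)) / 2,
         kosambi = tanh(d / 50) / 2)
}

# Recombination fractions clamped just below 1/2 so that mapping
# functions stay finite; the raw estimates are kept in the pairwise
# object. Uninformative (NA) entries are left NA.
clamp_r <- function(r, cap = 0.4999) pmin(r, cap)

#' Cluster markers into linkage groups
#'
#' Builds the graph whose edges join marker pairs with an independence
#' p-value below `p_cutoff` and an estimated distance of at most
#' `max_dist_cM`, and returns its connected components. The defaults
#' (p < 1e-10, 15 cM) are the stringent settings typical of high-density
#' DH maps.
#'
#' @param geno character call matrix (already curated).
#' @param p_cutoff grouping p-value cutoff.
#' @param max_dist_cM maximum pairwise distance for an edge, in cM.
#' @param fn mapping function used for the distance threshold.
#' @param min_informative minimum informative lines per pair.
#' @param pw optional precomputed [pairwise_linkage()] object.
#' @return a list with `groups` (list of character vectors, largest
#'   first) and `unplaced` (markers in singleton components).
#' @export
group_markers <- function(geno, p_cutoff = 1e-10, max_dist_cM = 15.0,
                          fn = c("kosambi", "haldane"),
                          min_informative = 20, pw = NULL) {
  fn <- match.arg(fn)
  if (is.null(pw)) pw <- pairwise_linkage(geno, min_informative)
  d_cm <- map_distance(clamp_r(pw$r), fn)
  adj <- !is.na(pw$p) & pw$p < p_cutoff & !is.na(d_cm) & d_cm <= max_dist_cM
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)
  groups <- split(colnames(pw$r), comp$membership)
  sizes <- lengths(groups)
  unplaced <- unlist(groups[sizes == 1], use.names = FALSE)
  groups <- groups[sizes > 1]
  ord <- order(-lengths(groups),
               vapply(groups, function(g) g[[1]], ""))
  list(groups = unname(groups[ord]), unplaced = sort(unplaced))
}

# Deterministic Prim MST on a dense weight matrix; ties broken by lowest
# vertex index. Returns an edge list (2-column integer matrix).
prim_mst <- function(w) {
  m <- nrow(w)
  in_tree <- logical(m)
  best_w <- rep(Inf, m)
  best_from <- integer(m)
  in_tree[1] <- TRUE
  cand <- w[1, ]
  upd <- cand < best_w
  best_w[upd] <- cand[upd]
  best_from[upd] <- 1L
  edges <- matrix(0L, m - 1, 2)
  for (k in seq_len(m - 1)) {
    best_w[in_tree] <- Inf
    v <- which.min(best_w)          # ties: lowest index
    edges[k, ] <- c(best_from[v], v)
    in_tree[v] <- TRUE
    cand <- w[v, ]
    upd <- !in_tree & cand < best_w
    best_w[upd] <- cand[upd]
    best_from[upd] <- v
  }
  edges
}

# Adjacency list of a tree given as an edge list; neighbours sorted by
# index so traversals are deterministic.
tree_adj <- function(edges, m) {
  adj <- vector("list", m)
  for (k in seq_len(nrow(edges))) {
    i <- edges[k, 1]; j <- edges[k, 2]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  lapply(adj, sort)
}

# Greedy nearest-neighbour path from `start`; ties broken by lowest
# index (which.min).
nn_path <- function(w, start) {
  m <- nrow(w)
  path <- integer(m)
  path[1] <- start
  left <- rep(TRUE, m)
  left[start] <- FALSE
  cur <- start
  for (k in 2:m) {
    cand <- w[cur, ]
    cand[!left] <- Inf
    cur <- which.min(cand)
    path[k] <- cur
    left[cur] <- FALSE
  }
  path
}

# Farthest vertex from `start` in an unweighted tree (BFS); used twice
# to find one endpoint of the tree diameter.
bfs_farthest <- function(adj, start) {
  m <- length(adj)
  dist <- rep(-1L, m)
  dist[start] <- 0L
  queue <- start
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (u in adj[[v]]) if (dist[u] < 0) {
      dist[u] <- dist[v] + 1L
      queue <- c(queue, u)
    }
  }
  which.max(dist)                   # ties: lowest index
}

# Iterative depth-first traversal (preorder) from `start`, neighbours in
# index order.
dfs_order <- function(adj, start) {
  m <- length(adj)
  seen <- logical(m)
  out <- integer(m)
  stack <- start
  k <- 0L
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (seen[v]) next
    seen[v] <- TRUE
    k <- k + 1L
    out[k] <- v
    nb <- adj[[v]][!seen[adj[[v]]]]
    if (length(nb)) stack <- c(stack, rev(nb))   # visit lowest index first
  }
  out
}

#' Sum of adjacent recombination fractions of an order
#'
#' The objective minimized by [order_markers()]: the sum of estimated
#' recombination fractions between consecutive markers of an order.
#' Uninformative pairs contribute the fixed penalty `0.75`.
#'
#' @param order character vector of marker names.
#' @param pw a [pairwise_linkage()] object covering the markers.
#' @return the SARF value.
#' @export
sarf <- function(order, pw) {
  r <- pw$r[order, order]
  r[is.na(r)] <- 0.75
  m <- length(order)
  if (m < 2) return(0)
  sum(r[cbind(seq_len(m - 1), seq(2, m))])
}

#' Order the markers of one linkage group
#'
#' Builds the complete graph of the group weighted by the estimated
#' recombination fractions and computes its minimum spanning tree
#' (deterministic Prim, ties by marker order). The initial path is the
#' MST itself when it is a Hamiltonian path, otherwise a depth-first
#' traversal from one endpoint of the tree diameter; either way the
#' path is then refined by deterministic 2-opt segment reversals and
#' or-opt segment relocations minimizing the sum of adjacent
#' recombination fractions (SARF) until a full cycle yields no
#' improvement. The returned order is canonically oriented so the
#' lexicographically smaller terminal marker comes first.
#'
#' @param geno character call matrix.
#' @param group character vector of marker names (>= 2).
#' @param min_informative minimum informative lines per pair.
#' @param pw optional precomputed [pairwise_linkage()] object.
#' @return character vector: the ordered markers.
#' @export
order_markers <- function(geno, group, min_informative = 20, pw = NULL) {
  if (length(group) < 2) stop("need at least 2 markers to order")
  group <- sort(group)              # identifier order fixes all tie-breaks
  if (is.null(pw))
    pw <- pairwise_linkage(geno[, group, drop = FALSE], min_informative)
  w <- pw$r[group, group]
  w[is.na(w)] <- 0.75               # uninformative: worse than any real r
  m <- length(group)
  if (m == 2) return(canonical_orientation(group))
  edges <- prim_mst(w)
  adj <- tree_adj(edges, m)
  deg <- lengths(adj)
  if (all(deg <= 2)) {
    mst_path <- dfs_order(adj, which(deg == 1)[1])
  } else {
    e1 <- bfs_farthest(adj, 1L)
    e2 <- bfs_farthest(adj, e1)
    mst_path <- dfs_order(adj, min(e1, e2))
  }
  # deterministic multi-start: the MST path plus nearest-neighbour
  # constructions from up to 8 spread-out seed markers, each refined;
  # the lowest-SARF result wins (first found on ties)
  starts <- c(list(mst_path),
              lapply(unique(round(seq(1, m, length.out = min(m, 8)))),
                     function(s) nn_path(w, s)))
  best <- NULL
  best_sarf <- Inf
  for (p in starts) {
    cand <- refine_order_2opt(p, w)
    s <- sum(w[cbind(cand[-m], cand[-1])])
    if (s < best_sarf - 1e-12) {
      best <- cand
      best_sarf <- s
    }
  }
  canonical_orientation(group[best])
}

# Orient an order so the lexicographically smaller terminal marker is
# first; identity when already oriented.
canonical_orientation <- function(order) {
  if (length(order) >= 2 && order[length(order)] < order[1]) rev(order)
  else order
}

#' Assemble a genetic map from an ordered linkage group
#'
#' Positions are cumulative sums of adjacent-pair distances: the
#' recombination fraction of each consecutive pair, clamped below 0.5,
#' passed through the chosen mapping function.
#'
#' @param geno character call matrix.
#' @param order ordered marker names (from [order_markers()]).
#' @param fn mapping function.
#' @param lg_id label for the linkage group.
#' @param min_informative minimum informative lines per adjacent pair;
#'   an uninformative adjacency is an error naming the pair.
#' @param pw optional precomputed [pairwise_linkage()] object.
#' @return a `genetic_map` data frame: lg, marker, position_cM; the map
#'   length (last position) is in attribute `length_cM`, the mapping
#'   function in attribute `fn`.
#' @export
build_map <- function(geno, order, fn = c("kosambi", "haldane"),
                      lg_id = "LG1", min_informative = 20, pw = NULL) {
  fn <- match.arg(fn)
  if (is.null(pw))
    pw <- pairwise_linkage(geno[, order, drop = FALSE], min_informative)
  m <- length(order)
  if (m < 1) stop("empty marker order")
  if (m == 1) {
    pos <- 0
  } else {
    idx <- cbind(order[-m], order[-1])
    r_adj <- pw$r[idx]
    n_adj <- pw$n[idx]
    if (any(n_adj < pw$min_informative)) {
      k <- which(n_adj < pw$min_informative)[1]
      stop("uninformative adjacent pair: ", order[k], " / ", order[k + 1])
    }
    pos <- c(0, cumsum(map_distance(clamp_r(r_adj), fn)))
  }
  map <- data.frame(lg = lg_id, marker = order, position_cM = pos,
                    stringsAsFactors = FALSE)
  class(map) <- c("genetic_map", "data.frame")
  attr(map, "length_cM") <- pos[length(pos)]
  attr(map, "fn") <- fn
  map
}

#' Total length of a genetic map
#'
#' @param map a `genetic_map` data frame (possibly several LGs).
#' @return summed length over linkage groups, in cM.
#' @export
map_length <- function(map) {
  sum(tapply(map$position_cM, map$lg, max))
}

#' Correct double recombinants by the flanking genotype
#'
#' A non-terminal marker call that disagrees with both its nearest
#' non-missing flanking calls, while those flanks agree with each other
#' and lie within `window_cM` on each side, implies two crossovers in a
#' short interval — at high density almost always a scoring error. One
#' pass in map order replaces every such focal call with the flanking
#' genotype; decisions are taken against the original calls, so a
#' correction never cascades within the pass. Terminal markers are never
#' modified and missing calls are never imputed.
#'
#' @param geno character call matrix.
#' @param map a single-LG `genetic_map` giving order and positions.
#' @param window_cM maximum distance to each flanking call.
#' @return the corrected matrix, with attribute `log`: data frame line,
#'   marker, old, new (one row per change).
#' @export
correct_double_recombinants <- function(geno, map, window_cM = 10) {
  check_geno(geno)
  stopifnot(length(unique(map$lg)) == 1)
  ord <- map$marker
  pos <- map$position_cM
  sub <- geno[, ord, drop = FALSE]
  changes <- list()
  for (i in seq_len(nrow(sub))) {
    calls <- sub[i, ]
    nm <- which(calls != "U")
    if (length(nm) < 3) next
    prev <- nm[1:(length(nm) - 2)]
    cur <- nm[2:(length(nm) - 1)]
    nxt <- nm[3:length(nm)]
    hit <- calls[prev] == calls[nxt] & calls[cur] != calls[prev] &
      (pos[cur] - pos[prev]) <= window_cM &
      (pos[nxt] - pos[cur]) <= window_cM
    for (k in which(hit)) {
      changes[[length(changes) + 1]] <-
        data.frame(line = rownames(sub)[i], marker = ord[cur[k]],
                   old = calls[cur[k]], new = calls[prev[k]],
                   stringsAsFactors = FALSE)
    }
  }
  log <- if (length(changes)) do.call(rbind, changes)
         else data.frame(line = character(), marker = character(),
                         old = character(), new = character(),
                         stringsAsFactors = FALSE)
  out <- geno
  if (nrow(log)) out[cbind(log$line, log$marker)] <- log$new
  attr(out, "log") <- log
  out
}
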