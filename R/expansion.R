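#' Map inflation factor
#'
#' IF = ((L_seq - L_sket) / L_sket) * 100: the percentage excess of a
#' sequential map's length over the skeleton map's length. Negative
#' values are reported as-is.
#'
#' @param L_seq sequential-map length (cM).
#' @param L_sket skeleton-map length (cM); must be positive.
#' @return inflation factor in percent.
#' @export
inflation_factor <- function(L_seq, L_sket) {
  if (any(L_sket <= 0))
    stop("inflation factor undefined for non-positive skeleton length")
  (L_seq - L_sket) / L_sket * 100
}

#' Marker-order collinearity between a sequential and the skeleton map
#'
#' Spearman rank correlation of the skeleton markers' positions in the
#' two maps (ties by average rank, as arise when several delegates sit
#' at the same position). Because either map may come out in either
#' orientation, the absolute value is reported.
#'
#' @param map_seq,map_sket `genetic_map` data frames sharing the
#'   skeleton's delegate markers.
#' @return |Spearman rho|; NA with a warning when fewer than 3 markers
#'   are shared.
#' @export
order_collinearity <- function(map_seq, map_sket) {
  shared <- intersect(map_sket$marker, map_seq$marker)
  if (length(shared) < 3) {
    warning("fewer than 3 shared markers; collinearity undefined")
    return(NA_real_)
  }
  p1 <- map_seq$position_cM[match(shared, map_seq$marker)]
  p2 <- map_sket$position_cM[match(shared, map_sket$marker)]
  abs(cor(p1, p2, method = "spearman"))
}

#' Experiment design for the proportion-level resampling study
#'
#' Levels of co-segregating-marker proportion and replicates per level.
#' The full design (10-80% by 10, 50 replicates) applies to linkage
#' groups whose own co-segregation proportion reaches the top level;
#' for less co-segregating LGs the fallback design (10-60%, 20
#' replicates) is used instead.
#'
#' @param levels percent levels, strictly increasing.
#' @param replicates replicates per level (>= 1).
#' @param fallback_levels,fallback_replicates design used when an LG's
#'   co-segregation proportion is below `max(levels)`.
#' @return an `experiment_design` list.
#' @export
experiment_design <- function(levels = seq(10, 80, by = 10),
                              replicates = 50,
                              fallback_levels = seq(10, 60, by = 10),
                              fallback_replicates = 20) {
  stopifnot(all(diff(levels) > 0), all(diff(fallback_levels) > 0),
            replicates >= 1, fallback_replicates >= 1)
  structure(list(levels = levels, replicates = replicates,
                 fallback_levels = fallback_levels,
                 fallback_replicates = fallback_replicates),
            class = "experiment_design")
}

# Round-half-up sample size at proportion level p (percent).
level_sample_size <- function(p, n_coseg) as.integer(floor(p / 100 * n_coseg + 0.5))

# Shared machinery: build one sequential map (delegates + added
# co-segregating markers), returning its record fields.
seq_map_record <- function(geno, added, skeleton, fn, min_informative, pw,
                           lg_id) {
  markers <- c(skeleton$marker, added)
  ord <- order_markers(geno, markers, min_informative, pw = pw)
  map <- build_map(geno, ord, fn, lg_id, min_informative, pw = pw)
  L_seq <- attr(map, "length_cM")
  L_sket <- attr(skeleton, "length_cM")
  list(L_seq = L_seq, L_sket = L_sket,
       IF = inflation_factor(L_seq, L_sket),
       spearman_rho = order_collinearity(map, skeleton))
}

#' Phase I: sequential maps adding one co-segregating marker at a time
#'
#' Draws a seeded random permutation of the LG's co-segregating
#' (non-delegate) markers and, for k = 1 .. n_coseg, fully re-orders and
#' re-maps the delegates plus the first k markers of the permutation.
#' One record per k; exactly as many sequential maps as there are
#' co-segregating markers on the LG.
#'
#' @param geno character call matrix.
#' @param clusters `cluster_set` with delegates selected.
#' @param fn mapping function.
#' @param lg_id linkage-group label.
#' @param seed seed for the permutation.
#' @param min_informative minimum informative lines per pair.
#' @param pw optional precomputed [pairwise_linkage()] covering the LG.
#' @return data frame of `SequentialMapRecord`s: lg, mode, markers_added,
#'   replicate, L_seq, L_sket, IF, spearman_rho.
#' @export
phase1_sequential <- function(geno, clusters, fn = c("kosambi", "haldane"),
                              lg_id = "LG1", seed = 1L,
                              min_informative = 20, pw = NULL) {
  fn <- match.arg(fn)
  stopifnot(inherits(clusters, "cluster_set"),
            !is.null(clusters$is_delegate))
  if (is.null(pw))
    pw <- pairwise_linkage(geno[, clusters$marker, drop = FALSE],
                           min_informative)
  skeleton <- build_skeleton(geno, clusters, fn, lg_id, min_informative,
                             pw = pw)
  coseg <- clusters$marker[!clusters$is_delegate]
  if (length(coseg) == 0 || attr(skeleton, "length_cM") <= 0) {
    if (length(coseg) > 0)
      warning(lg_id, ": zero-length skeleton, sequential maps aborted")
    return(data.frame(lg = character(), mode = character(),
                      markers_added = integer(), replicate = integer(),
                      L_seq = numeric(), L_sket = numeric(), IF = numeric(),
                      spearman_rho = numeric(), stringsAsFactors = FALSE))
  }
  perm <- with_seed(derive_seed(seed, lg_id, "phase1"),
                    sample(coseg, length(coseg)))
  recs <- lapply(seq_along(perm), function(k) {
    r <- seq_map_record(geno, perm[seq_len(k)], skeleton, fn,
                        min_informative, pw, lg_id)
    data.frame(lg = lg_id, mode = "phaseI_sequential", markers_added = k,
               replicate = 1L, L_seq = r$L_seq, L_sket = r$L_sket,
               IF = r$IF, spearman_rho = r$spearman_rho,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, recs)
}

#' Phase II: sequential maps at sampled proportion levels
#'
#' For each feasible proportion level p and replicate, samples
#' round(p/100 * n_coseg) co-segregating markers without replacement,
#' re-orders and re-maps the delegates plus the sample, and records the
#' inflation factor and order collinearity. Levels above the LG's own
#' co-segregation proportion are skipped (with a message), mirroring the
#' fallback design for weakly co-segregating LGs; each record's seed is
#' derived from (master seed, lg, level, replicate) so any single map is
#' reproducible in isolation.
#'
#' @param geno character call matrix.
#' @param clusters `cluster_set` with delegates selected.
#' @param design an [experiment_design()].
#' @param fn mapping function.
#' @param lg_id linkage-group label.
#' @param master_seed master seed of the experiment.
#' @param min_informative minimum informative lines per pair.
#' @param pw optional precomputed [pairwise_linkage()] covering the LG.
#' @return data frame of records: lg, mode, proportion_pct, replicate,
#'   L_seq, L_sket, IF, spearman_rho.
#' @export
phase2_sampled <- function(geno, clusters, design = experiment_design(),
                           fn = c("kosambi", "haldane"), lg_id = "LG1",
                           master_seed = 1L, min_informative = 20,
                           pw = NULL) {
  fn <- match.arg(fn)
  stopifnot(inherits(clusters, "cluster_set"),
            !is.null(clusters$is_delegate),
            inherits(design, "experiment_design"))
  if (is.null(pw))
    pw <- pairwise_linkage(geno[, clusters$marker, drop = FALSE],
                           min_informative)
  skeleton <- build_skeleton(geno, clusters, fn, lg_id, min_informative,
                             pw = pw)
  coseg <- clusters$marker[!clusters$is_delegate]
  n_coseg <- length(coseg)
  if (n_coseg > 0 && attr(skeleton, "length_cM") <= 0) {
    warning(lg_id, ": zero-length skeleton, sequential maps aborted")
    n_coseg <- 0
  }
  avail_pct <- coseg_proportion(max(n_coseg, 0), nrow(clusters),
                                digits = 6)
  if (avail_pct >= max(design$levels)) {
    levels <- design$levels
    reps <- design$replicates
  } else {
    levels <- design$fallback_levels
    reps <- design$fallback_replicates
  }
  feasible <- levels <= avail_pct & level_sample_size(levels, n_coseg) >= 1
  if (any(!feasible))
    message(lg_id, ": skipping infeasible level(s) ",
            paste(levels[!feasible], collapse = ", "),
            " (co-segregation proportion ", round(avail_pct, 1), "%)")
  levels <- levels[feasible]
  recs <- list()
  for (p in levels) {
    k <- level_sample_size(p, n_coseg)
    for (rep in seq_len(reps)) {
      added <- with_seed(derive_seed(master_seed, lg_id, p, rep),
                         sample(coseg, k))
      r <- seq_map_record(geno, added, skeleton, fn, min_informative, pw,
                          lg_id)
      recs[[length(recs) + 1]] <-
        data.frame(lg = lg_id, mode = "phaseII_sampled",
                   proportion_pct = p, replicate = rep, L_seq = r$L_seq,
                   L_sket = r$L_sket, IF = r$IF,
                   spearman_rho = r$spearman_rho, stringsAsFactors = FALSE)
    }
  }
  if (length(recs) == 0)
    return(data.frame(lg = character(), mode = character(),
                      proportion_pct = numeric(), replicate = integer(),
                      L_seq = numeric(), L_sket = numeric(), IF = numeric(),
                      spearman_rho = numeric(), stringsAsFactors = FALSE))
  do.call(rbind, recs)
}

#' Summarize inflation factors by proportion level
#'
#' Mean, sample standard deviation and map count of IF per proportion
#' level, optionally split by further grouping columns (e.g. `lg`).
#'
#' @param records Phase II record data frame.
#' @param by additional grouping column names in `records`.
#' @return data frame: grouping columns, n_maps, mean_IF, sd_IF.
#' @export
summarize_inflation <- function(records, by = character(0)) {
  stopifnot(nrow(records) > 0, "proportion_pct" %in% names(records))
  keys <- c(by, "proportion_pct")
  agg <- aggregate(records$IF, records[keys],
                   function(x) c(n = length(x), mean = mean(x),
                                 sd = sd(x)))
  out <- cbind(agg[keys], n_maps = agg$x[, "n"], mean_IF = agg$x[, "mean"],
               sd_IF = agg$x[, "sd"])
  out[do.call(order, out[keys]), , drop = FALSE]
}
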