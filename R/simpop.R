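#' Simulation configuration for a DH population
#'
#' Bundles and validates the parameters of the doubled haploid genotype
#' simulator. The defaults emulate a durum-wheat-like mapping population:
#' 177 lines, 14 linkage groups, and 85% of markers sitting in
#' zero-recombination clusters.
#'
#' @param n_lines number of DH individuals.
#' @param n_lg number of linkage groups (chromosomes).
#' @param lg_length_cM true genetic length of each LG in centiMorgan;
#'   recycled to `n_lg`.
#' @param n_unique_loci number of distinct marker positions per LG;
#'   recycled to `n_lg`; must be at least 2.
#' @param coseg_proportion target fraction of markers that are extra
#'   copies at already-occupied loci, in `[0, 1)`. The realized marker
#'   count per LG is `round(n_unique_loci / (1 - coseg_proportion))`.
#' @param miscall_rate per-call probability of flipping A and B, in
#'   `[0, 0.5)`.
#' @param missing_rate per-call probability of masking a call to U
#'   (missing), in `[0, 0.1]`.
#' @param seed RNG seed for the simulation.
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_lines = 177, n_lg = 14, lg_length_cM = 150,
                       n_unique_loci = 40, coseg_proportion = 0.85,
                       miscall_rate = 0, missing_rate = 0, seed = 1L) {
  stopifnot(n_lines >= 1, n_lg >= 1)
  lg_length_cM <- rep_len(lg_length_cM, n_lg)
  n_unique_loci <- rep_len(as.integer(n_unique_loci), n_lg)
  if (any(n_unique_loci < 2))
    stop("n_unique_loci must be >= 2 on every linkage group")
  if (coseg_proportion < 0 || coseg_proportion >= 1)
    stop("coseg_proportion must be in [0, 1)")
  if (miscall_rate < 0 || miscall_rate >= 0.5)
    stop("miscall_rate must be in [0, 0.5)")
  if (missing_rate < 0 || missing_rate > 0.1)
    stop("missing_rate must be in [0, 0.1]")
  n_markers <- as.integer(round(n_unique_loci / (1 - coseg_proportion)))
  if (any(n_markers < 3))
    stop("realized marker count per LG is below 3; increase n_unique_loci ",
         "or coseg_proportion")
  structure(list(n_lines = as.integer(n_lines), n_lg = as.integer(n_lg),
                 lg_length_cM = lg_length_cM, n_unique_loci = n_unique_loci,
                 coseg_proportion = coseg_proportion,
                 miscall_rate = miscall_rate, missing_rate = missing_rate,
                 n_markers = n_markers, seed = as.integer(seed)),
            class = "sim_config")
}

# Simulate one DH gamete per line along one chromosome under the
# no-interference (Poisson crossover) model: crossover count per meiosis
# is Poisson(L/100), crossover positions are uniform on [0, L], and the
# allele at position x is the starting allele XOR'd with the parity of
# crossovers to the left of x. Recombination fractions between loci are
# then Haldane-consistent by construction.
sim_gametes <- function(n_lines, positions_cM, lg_length_cM) {
  m <- length(positions_cM)
  alleles <- matrix(0L, n_lines, m)
  start <- rbinom(n_lines, 1, 0.5)
  n_xo <- rpois(n_lines, lg_length_cM / 100)
  for (i in seq_len(n_lines)) {
    if (n_xo[i] == 0L) {
      alleles[i, ] <- start[i]
    } else {
      xo <- runif(n_xo[i], 0, lg_length_cM)
      parity <- vapply(positions_cM, function(p) sum(xo < p) %% 2, 0)
      alleles[i, ] <- (start[i] + parity) %% 2
    }
  }
  alleles
}

#' Simulate genotypes for one linkage group at given true positions
#'
#' Lower-level entry point used by [simulate_dh_population()] and handy
#' for constructing small controlled instances (e.g. a single co-located
#' marker pair). Each marker is assigned to a locus via `locus_of`; all
#' markers at a locus inherit the same parental allele before noise.
#'
#' @param n_lines number of DH lines.
#' @param positions_cM true positions of the distinct loci (cM).
#' @param lg_length_cM chromosome length; defaults to the span of
#'   `positions_cM` (at least 1 cM).
#' @param locus_of integer vector mapping each marker to a locus index;
#'   defaults to one marker per locus.
#' @param miscall_rate,missing_rate per-call noise probabilities.
#' @param marker_names optional marker names.
#' @return a character matrix of A/B/U calls, lines x markers, with
#'   attributes `truth` (data frame marker/true_position_cM/cluster_id),
#'   `error_mask` and `missing_mask` (logical matrices).
#' @export
sim_lg_genotypes <- function(n_lines, positions_cM,
                             lg_length_cM = max(max(positions_cM), 1),
                             locus_of = seq_along(positions_cM),
                             miscall_rate = 0, missing_rate = 0,
                             marker_names = NULL) {
  stopifnot(all(locus_of >= 1), all(locus_of <= length(positions_cM)))
  m <- length(locus_of)
  if (is.null(marker_names)) marker_names <- sprintf("M%03d", seq_len(m))
  alleles <- sim_gametes(n_lines, positions_cM, lg_length_cM)[, locus_of,
                                                             drop = FALSE]
  err <- matrix(runif(n_lines * m) < miscall_rate, n_lines, m)
  alleles <- (alleles + err) %% 2
  geno <- matrix(c("A", "B")[alleles + 1L], n_lines, m)
  miss <- matrix(runif(n_lines * m) < missing_rate, n_lines, m)
  geno[miss] <- "U"
  dimnames(geno) <- list(sprintf("line_%03d", seq_len(n_lines)), marker_names)
  dimnames(err) <- dimnames(miss) <- dimnames(geno)
  attr(geno, "truth") <- data.frame(marker = marker_names,
                                    true_position_cM = positions_cM[locus_of],
                                    cluster_id = locus_of,
                                    stringsAsFactors = FALSE)
  attr(geno, "error_mask") <- err
  attr(geno, "missing_mask") <- miss
  geno
}

#' Simulate a DH genotype matrix with known ground truth
#'
#' Simulates meioses for every line and linkage group under the
#' no-interference Poisson crossover model, places
#' `round(n_unique_loci / (1 - coseg_proportion))` markers per LG by
#' adding extra marker copies at randomly chosen loci, then applies
#' independent symmetric A/B miscalls and missing-call masking. Both
#' parental alleles are equally likely at every chromosome start, so
#' each marker segregates 1:1 in expectation.
#'
#' @param config a [sim_config()] object.
#' @return a list with components
#'   \describe{
#'     \item{geno}{character matrix of calls, lines x markers;}
#'     \item{truth}{data frame marker, lg, true_position_cM, cluster_id;}
#'     \item{error_mask, missing_mask}{logical matrices marking where a
#'       miscall / missing mask was applied;}
#'     \item{config}{the configuration used.}
#'   }
#' @export
simulate_dh_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    genos <- vector("list", config$n_lg)
    truths <- vector("list", config$n_lg)
    for (g in seq_len(config$n_lg)) {
      n_uni <- config$n_unique_loci[g]
      n_mark <- config$n_markers[g]
      len <- config$lg_length_cM[g]
      positions <- sort(runif(n_uni, 0, len))
      # every locus carries one marker; extra copies land on random loci
      extra <- if (n_mark > n_uni)
        sample.int(n_uni, n_mark - n_uni, replace = TRUE) else integer(0)
      locus_of <- sort(c(seq_len(n_uni), extra))
      nm <- sprintf("LG%02d_M%04d", g, seq_len(n_mark))
      gg <- sim_lg_genotypes(config$n_lines, positions,
                             lg_length_cM = len, locus_of = locus_of,
                             miscall_rate = config$miscall_rate,
                             missing_rate = config$missing_rate,
                             marker_names = nm)
      tt <- attr(gg, "truth")
      tt$lg <- sprintf("LG%02d", g)
      tt$cluster_id <- sprintf("LG%02d_C%04d", g, tt$cluster_id)
      truths[[g]] <- tt[, c("marker", "lg", "true_position_cM", "cluster_id")]
      genos[[g]] <- gg
    }
    geno <- do.call(cbind, lapply(genos, function(x) {
      attributes(x)[c("truth", "error_mask", "missing_mask")] <- NULL
      x
    }))
    rownames(geno) <- sprintf("line_%03d", seq_len(config$n_lines))
    list(geno = geno,
         truth = do.call(rbind, truths),
         error_mask = do.call(cbind, lapply(genos, attr, "error_mask")),
         missing_mask = do.call(cbind, lapply(genos, attr, "missing_mask")),
         config = config)
  })
}

#' Filter markers on segregation, missingness and polymorphism
#'
#' Curates a DH genotype matrix the way high-density SNP data are
#' curated before mapping: monomorphic markers are dropped, markers with
#' a missing-call fraction at or above `max_missing` are dropped, and
#' markers whose non-missing calls depart from the expected 1:1 DH
#' segregation ratio by a 1-df chi-square test at `alpha` are dropped.
#'
#' @param geno character call matrix (lines x markers, A/B/U).
#' @param alpha significance level of the 1:1 chi-square test.
#' @param max_missing maximum tolerated missing fraction (exclusive).
#' @return the filtered matrix, with attribute `log`: a data frame with
#'   one row per input marker (marker, n_A, n_B, missing_frac, chisq,
#'   p_value, status), status one of kept / monomorphic /
#'   excess_missing / distorted.
#' @export
segregation_filter <- function(geno, alpha = 0.05, max_missing = 0.10) {
  check_geno(geno)
  n_a <- colSums(geno == "A")
  n_b <- colSums(geno == "B")
  miss <- colMeans(geno == "U")
  n <- n_a + n_b
  chisq <- ifelse(n > 0, (n_a - n_b)^2 / n, NA_real_)
  p <- pchisq(chisq, df = 1, lower.tail = FALSE)
  status <- rep("kept", ncol(geno))
  status[p < alpha] <- "distorted"
  status[miss >= max_missing] <- "excess_missing"
  status[n_a == 0 | n_b == 0] <- "monomorphic"
  log <- data.frame(marker = colnames(geno), n_A = n_a, n_B = n_b,
                    missing_frac = miss, chisq = chisq, p_value = p,
                    status = status, row.names = NULL,
                    stringsAsFactors = FALSE)
  out <- geno[, status == "kept", drop = FALSE]
  if (ncol(out) == 0)
    warning("segregation_filter removed every marker")
  attr(out, "log") <- log
  out
}
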