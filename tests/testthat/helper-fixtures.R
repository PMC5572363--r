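# Shared fixtures and independent oracles for the test suite.

# Build a genotype matrix from per-marker call strings, e.g.
# geno_from_strings(M1 = "AABB", M2 = "ABUB").
geno_from_strings <- function(...) {
  cols <- list(...)
  m <- do.call(cbind, lapply(cols, function(s) strsplit(s, "")[[1]]))
  colnames(m) <- names(cols)
  rownames(m) <- sprintf("line_%03d", seq_len(nrow(m)))
  m
}

# All permutations of 1..m (rows), enumeration oracle for small m.
all_perms <- function(m) {
  if (m == 1) return(matrix(1L, 1, 1))
  p <- all_perms(m - 1)
  do.call(rbind, lapply(1:m, function(k)
    cbind(k, matrix((1:m)[-k][p], nrow(p), m - 1))))
}

# Brute-force minimum SARF over all marker orders; independent of the
# MST + local-search path it is used to check.
brute_force_min_sarf <- function(rmat) {
  m <- nrow(rmat)
  P <- all_perms(m)
  s <- rep(0, nrow(P))
  for (i in 1:(m - 1)) s <- s + rmat[cbind(P[, i], P[, i + 1])]
  min(s)
}

# A 14-LG zero-noise genome with regular-ish locus spacing (gaps 5-9 cM
# stay well inside the 15 cM grouping threshold) and 50% of markers as
# extra copies at existing loci.
make_zero_noise_genome <- function(seed, n_lines = 177, n_lg = 14,
                                   n_loci = 12) {
  set.seed(seed)
  gs <- list()
  truths <- list()
  for (g in seq_len(n_lg)) {
    pos <- cumsum(c(0, runif(n_loci - 1, 5, 9)))
    locus_of <- sort(c(seq_len(n_loci),
                       sample(n_loci, n_loci, replace = TRUE)))
    gg <- sim_lg_genotypes(n_lines, pos, max(pos), locus_of,
                           marker_names = sprintf("LG%02d_M%03d", g,
                                                  seq_along(locus_of)))
    tt <- attr(gg, "truth")
    tt$lg <- sprintf("LG%02d", g)
    truths[[g]] <- tt
    attributes(gg)[c("truth", "error_mask", "missing_mask")] <- NULL
    gs[[g]] <- gg
  }
  list(geno = do.call(cbind, gs), truth = do.call(rbind, truths))
}
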