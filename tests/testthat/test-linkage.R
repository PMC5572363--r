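test_that("estimate_r counts discordant lines and tests independence", {
  g10 <- geno_from_strings(a = "AAAAABBBBB", b = "AAAAABBBBB",
                           c = "BAAAABBBBB", d = "BBBBBAAAAA",
                           e = "ABABABABAA")
  expect_equal(estimate_r(g10, "a", "b", min_informative = 5)$r_hat, 0)
  expect_equal(estimate_r(g10, "a", "c", min_informative = 5)$r_hat, 0.1)
  half <- estimate_r(g10, "a", "e", min_informative = 5)
  expect_equal(half$r_hat, 0.5)
  expect_equal(half$p_indep, 1.0)
  # complete linkage in repulsion is maximally non-independent
  rep_pair <- estimate_r(g10, "a", "d", min_informative = 5)
  expect_equal(rep_pair$r_hat, 1.0)
  expect_equal(rep_pair$p_indep, 2 * 0.5^10)
})

test_that("uninformative pairs are flagged below the informative minimum", {
  g <- geno_from_strings(a = "ABABUUUUUU", b = "UUUUABABAB")
  est <- estimate_r(g, "a", "b")
  expect_false(est$informative)
  expect_true(is.na(est$r_hat))
})

test_that("pairwise statistics are symmetric with zero self-recombination", {
  set.seed(2)
  g <- sim_lg_genotypes(60, sort(runif(6, 0, 50)), miscall_rate = 0.05,
                        missing_rate = 0.05)
  pw <- pairwise_linkage(g, min_informative = 10)
  expect_equal(pw$r, t(pw$r))
  expect_equal(unname(diag(pw$r)), rep(0, 6))
})

test_that("mapping functions match their closed forms and invert exactly", {
  expect_equal(map_distance(0, "haldane"), 0)
  expect_equal(map_distance(0, "kosambi"), 0)
  expect_equal(map_distance(0.1, "haldane"), -50 * log(0.8))
  expect_equal(map_distance(0.1, "kosambi"), 25 * log(1.5))
  r <- seq(0, 0.49, by = 0.01)
  for (fn in c("haldane", "kosambi")) {
    d <- map_distance(r, fn)
    expect_true(all(diff(d) > 0))
    expect_equal(dist_to_r(d, fn), r, tolerance = 1e-9)
  }
  # Kosambi compresses relative to Haldane except at r = 0
  expect_true(all(map_distance(r[-1], "kosambi") <
                    map_distance(r[-1], "haldane")))
  expect_error(map_distance(0.5), "clamp")
})

test_that("independent chromosomes fall into separate linkage groups", {
  set.seed(13)
  g1 <- sim_lg_genotypes(200, cumsum(c(0, runif(24, 1, 2))),
                         marker_names = sprintf("c1_%02d", 1:25))
  g2 <- sim_lg_genotypes(200, cumsum(c(0, runif(24, 1, 2))),
                         marker_names = sprintf("c2_%02d", 1:25))
  gr <- group_markers(cbind(g1, g2))
  expect_length(gr$groups, 2)
  expect_setequal(gr$groups[[1]], colnames(g1))
  expect_setequal(gr$groups[[2]], colnames(g2))
})

test_that("identical columns form one group; sparse markers are unplaced", {
  base <- paste(rep(c("A", "B"), 25), collapse = "")
  g <- geno_from_strings(a = base, b = base, c = base)
  gr <- group_markers(g)
  expect_length(gr$groups, 1)
  # a marker observed in too few lines shares no informative pair
  sparse <- c(rep("U", 45), rep("A", 5))
  g2 <- cbind(g, d = sparse)
  rownames(g2) <- rownames(g)
  gr2 <- group_markers(g2)
  expect_identical(gr2$unplaced, "d")
})

test_that("ordering recovers the true arrangement on clean instances", {
  set.seed(101)
  for (t in 1:5) {
    pos <- cumsum(c(0, runif(19, 5, 8)))
    g <- sim_lg_genotypes(200, pos)
    ord <- order_markers(g, colnames(g))
    expect_true(identical(ord, colnames(g)) ||
                  identical(ord, rev(colnames(g))))
  }
})

test_that("two markers get the canonical orientation", {
  g <- geno_from_strings(b = paste(rep(c("A", "B"), 15), collapse = ""),
                         a = paste(rep(c("A", "B"), 15), collapse = ""))
  expect_identical(order_markers(g, c("b", "a")), c("a", "b"))
})

test_that("local search attains the exhaustive SARF minimum on small instances", {
  set.seed(303)
  for (t in 1:100) {
    m <- sample(4:7, 1)
    g <- sim_lg_genotypes(150, sort(runif(m, 0, 60)), 60,
                          miscall_rate = 0.01)
    pw <- pairwise_linkage(g)
    ord <- order_markers(g, colnames(g), pw = pw)
    expect_equal(sarf(ord, pw), brute_force_min_sarf(pw$r),
                 tolerance = 1e-9)
  }
})

test_that("map positions are cumulative distances along the order", {
  base <- paste(rep(c("A", "B"), 15), collapse = "")
  g <- geno_from_strings(a = base, b = base, c = base, d = base)
  map <- build_map(g, c("a", "b", "c", "d"))
  expect_equal(attr(map, "length_cM"), 0)
  expect_equal(map$position_cM, rep(0, 4))
  # adjacent r = 0.1 twice, Haldane: 2 * 11.157 cM
  flip <- function(x) ifelse(x == "A", "B", "A")
  a <- rep(c("A", "B"), 15)
  b <- a; b[1:3] <- flip(b[1:3])
  cc <- b; cc[28:30] <- flip(cc[28:30])
  g30 <- cbind(a = a, b = b, c = cc)
  rownames(g30) <- sprintf("line_%03d", 1:30)
  pw <- pairwise_linkage(g30)
  expect_equal(unname(pw$r[cbind(c("a", "b"), c("b", "c"))]),
               c(0.1, 0.1), tolerance = 1e-12)
  map2 <- build_map(g30, c("a", "b", "c"), fn = "haldane")
  expect_equal(attr(map2, "length_cM"), -100 * log(0.8), tolerance = 1e-9)
})

test_that("an uninformative adjacency is a named error", {
  g <- geno_from_strings(a = "ABABUUUUUU", b = "UUUUABABAB")
  expect_error(build_map(g, c("a", "b")), "a / b")
})

test_that("map length on clean data recovers the simulated truth", {
  set.seed(17)
  lens <- replicate(20, {
    pos <- c(0, sort(runif(13, 0, 100)), 100)
    g <- sim_lg_genotypes(200, pos)
    pw <- pairwise_linkage(g)
    ord <- order_markers(g, colnames(g), pw = pw)
    attr(build_map(g, ord, "haldane", pw = pw), "length_cM")
  })
  expect_equal(mean(lens), 100, tolerance = 0.06)
})

test_that("double recombinants are replaced by the flanking genotype", {
  # textbook case: A,B,A at 0/1/2 cM becomes A,A,A; A,B,B is a real
  # crossover and stays
  m1 <- rep(c("A", "B"), 15)
  g <- cbind(m1 = m1, m2 = ifelse(m1 == "A", "B", "A"), m3 = m1)
  rownames(g) <- sprintf("line_%03d", 1:30)
  map <- data.frame(lg = "LG1", marker = c("m1", "m2", "m3"),
                    position_cM = c(0, 1, 2))
  out <- correct_double_recombinants(g, map)
  log <- attr(out, "log")
  expect_true(all(out[, "m2"] == out[, "m1"]))
  expect_equal(nrow(log), 30)      # every line had the sandwich pattern
  # single crossover pattern untouched
  g2 <- geno_from_strings(m1 = "AAAA", m2 = "BBBB", m3 = "BBBB")
  out2 <- correct_double_recombinants(g2, map)
  expect_true(all(out2 == g2))
  expect_equal(nrow(attr(out2, "log")), 0)
})

test_that("correction respects the window, terminals and missing calls", {
  g <- geno_from_strings(m1 = "A", m2 = "B", m3 = "A", m4 = "U")
  far <- data.frame(lg = "LG1", marker = c("m1", "m2", "m3", "m4"),
                    position_cM = c(0, 20, 40, 41))
  expect_equal(nrow(attr(correct_double_recombinants(g, far), "log")), 0)
  near <- data.frame(lg = "LG1", marker = c("m1", "m2", "m3", "m4"),
                     position_cM = c(0, 5, 10, 11))
  out <- correct_double_recombinants(g, near)
  expect_identical(unname(out[1, ]), c("A", "A", "A", "U"))
})

test_that("correction shortens an error-inflated map", {
  set.seed(23)
  g <- sim_lg_genotypes(200, sort(runif(25, 0, 80)), 80,
                        miscall_rate = 0.01)
  pw <- pairwise_linkage(g)
  ord <- order_markers(g, colnames(g), pw = pw)
  map <- build_map(g, ord, "haldane", pw = pw)
  gc <- correct_double_recombinants(g, map)
  pw2 <- pairwise_linkage(gc)
  ord2 <- order_markers(gc, colnames(gc), pw = pw2)
  map2 <- build_map(gc, ord2, "haldane", pw = pw2)
  expect_lt(attr(map2, "length_cM"), attr(map, "length_cM"))
})
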