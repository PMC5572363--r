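test_that("inflation factor follows its defining formula", {
  expect_equal(inflation_factor(2052.0, 2052.0), 0)
  # genome-total and single-LG worked examples
  expect_equal(inflation_factor(2421.1, 2052.0),
               (2421.1 - 2052.0) / 2052.0 * 100)
  expect_equal(round(inflation_factor(2421.1, 2052.0), 2), 17.99)
  expect_equal(round(inflation_factor(154.4, 137.3), 2), 12.45)
  # negative inflation is reported as-is
  expect_lt(inflation_factor(95, 100), 0)
  # scale invariance
  expect_equal(inflation_factor(3 * 154.4, 3 * 137.3),
               inflation_factor(154.4, 137.3))
  expect_error(inflation_factor(10, 0), "undefined")
})

test_that("order collinearity is orientation-free with tie-aware ranks", {
  mk <- function(markers, pos) {
    m <- data.frame(lg = "LG1", marker = markers, position_cM = pos)
    class(m) <- c("genetic_map", "data.frame")
    m
  }
  ids <- sprintf("m%02d", 1:10)
  sket <- mk(ids, 0:9)
  expect_equal(order_collinearity(mk(ids, 0:9), sket), 1.0)
  expect_equal(order_collinearity(mk(rev(ids), 0:9), sket), 1.0)
  # one adjacent swap: 1 - 6 * 2 / (10 * 99)
  swapped <- mk(ids[c(1:4, 6, 5, 7:10)], 0:9)
  expect_equal(order_collinearity(swapped, sket), 1 - 12 / 990,
               tolerance = 1e-9)
  expect_warning(r <- order_collinearity(mk(ids[1:2], 0:1), sket),
                 "fewer than 3")
  expect_true(is.na(r))
})

test_that("phase I produces one exact record per co-segregating marker", {
  cfg <- sim_config(n_lines = 150, n_lg = 1, lg_length_cM = 70,
                    n_unique_loci = 10, coseg_proportion = 0.5, seed = 31)
  sim <- simulate_dh_population(cfg)
  pw <- pairwise_linkage(sim$geno)
  cl <- select_delegates(find_clusters(sim$geno, pw = pw), 2)
  rec <- phase1_sequential(sim$geno, cl, "kosambi", "LG01", seed = 9,
                           pw = pw)
  expect_equal(nrow(rec), attr(cl, "n_coseg"))
  expect_equal(rec$markers_added, seq_len(nrow(rec)))
  # zero noise: every sequential map equals the skeleton
  expect_true(all(abs(rec$IF) < 1e-9))
  expect_true(all(abs(rec$spearman_rho - 1) < 1e-9))
})

test_that("phase I on an LG without co-segregation is empty", {
  set.seed(3)
  g <- sim_lg_genotypes(150, cumsum(c(0, runif(7, 5, 9))))
  pw <- pairwise_linkage(g)
  cl <- select_delegates(find_clusters(g, pw = pw), 1)
  expect_equal(attr(cl, "n_coseg"), 0)
  rec <- phase1_sequential(g, cl, "kosambi", "LG01", seed = 1, pw = pw)
  expect_equal(nrow(rec), 0)
})

test_that("phase II bookkeeping: sample sizes, record counts, fallback", {
  cfg <- sim_config(n_lines = 150, n_lg = 1, lg_length_cM = 70,
                    n_unique_loci = 10, coseg_proportion = 0.85,
                    seed = 12)
  sim <- simulate_dh_population(cfg)
  pw <- pairwise_linkage(sim$geno)
  cl <- select_delegates(find_clusters(sim$geno, pw = pw), 2)
  des <- experiment_design(replicates = 2, fallback_replicates = 2)
  rec <- phase2_sampled(sim$geno, cl, des, "kosambi", "LG01",
                        master_seed = 4, pw = pw)
  expect_equal(nrow(rec), 8 * 2)              # 8 levels, 2 replicates
  expect_true(all(abs(rec$IF) < 1e-9))
  # an LG below the top level falls back to the reduced design
  cfg2 <- sim_config(n_lines = 150, n_lg = 1, lg_length_cM = 70,
                     n_unique_loci = 10, coseg_proportion = 0.5,
                     seed = 13)
  sim2 <- simulate_dh_population(cfg2)
  pw2 <- pairwise_linkage(sim2$geno)
  cl2 <- select_delegates(find_clusters(sim2$geno, pw = pw2), 2)
  expect_equal(coseg_proportion(cl2), 50)
  rec2 <- phase2_sampled(sim2$geno, cl2, des, "kosambi", "LG01",
                         master_seed = 4, pw = pw2)
  expect_setequal(unique(rec2$proportion_pct), seq(10, 50, 10))
})

test_that("phase II records are reproducible from their derived seeds", {
  cfg <- sim_config(n_lines = 150, n_lg = 1, lg_length_cM = 70,
                    n_unique_loci = 8, coseg_proportion = 0.6, seed = 21)
  sim <- simulate_dh_population(cfg)
  pw <- pairwise_linkage(sim$geno)
  cl <- select_delegates(find_clusters(sim$geno, pw = pw), 2)
  des <- experiment_design(levels = c(20, 40), replicates = 2,
                           fallback_levels = c(20, 40),
                           fallback_replicates = 2)
  r1 <- phase2_sampled(sim$geno, cl, des, "kosambi", "LG01",
                       master_seed = 7, pw = pw)
  r2 <- phase2_sampled(sim$geno, cl, des, "kosambi", "LG01",
                       master_seed = 7, pw = pw)
  expect_identical(r1, r2)
})

test_that("mean inflation rises with the co-segregation proportion", {
  cfg <- sim_config(n_lines = 150, n_lg = 1, lg_length_cM = 100,
                    n_unique_loci = 25, coseg_proportion = 0.85,
                    miscall_rate = 0.01, seed = 61)
  sim <- simulate_dh_population(cfg)
  cl <- select_delegates(clusters_from_truth(sim$truth, sim$geno), 1)
  pw <- pairwise_linkage(sim$geno)
  des <- experiment_design(replicates = 5)
  rec <- phase2_sampled(sim$geno, cl, des, "haldane", "LG01",
                        master_seed = 19, pw = pw)
  s <- summarize_inflation(rec)
  expect_equal(cor(s$mean_IF, s$proportion_pct, method = "spearman"), 1)
})

test_that("summaries report mean, sample SD and counts per level", {
  rec <- data.frame(lg = "LG01", mode = "phaseII_sampled",
                    proportion_pct = c(10, 10, 20, 20),
                    replicate = c(1, 2, 1, 2),
                    L_seq = 0, L_sket = 0,
                    IF = c(10, 20, 5, 5), spearman_rho = 1)
  s <- summarize_inflation(rec)
  expect_equal(s$n_maps, c(2, 2))
  expect_equal(s$mean_IF, c(15, 5))
  expect_equal(s$sd_IF, c(sd(c(10, 20)), 0))
  expect_equal(round(s$sd_IF[1], 2), 7.07)
})
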