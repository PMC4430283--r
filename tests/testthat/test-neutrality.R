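test_that("Tajima's D matches the constant-by-constant oracle", {
  lc <- locus_alignment(c(a = "AAAA", b = "AAAT", c = "AATT", d = "ATTT"))
  expect_equal(tajimas_d(lc), oracle_tajima_d(unclass(lc)[, ]))
  set.seed(41)
  for (rep in 1:25) {
    mat <- random_alignment(8, 40, n_var = sample(1:6, 1))
    expect_equal(tajimas_d(make_locus(mat)), oracle_tajima_d(mat))
  }
  mono <- locus_alignment(c(a = "AAAA", b = "AAAA"))
  expect_true(is.na(tajimas_d(mono)))
})

test_that("Fu & Li's starred tests flag singleton excess and deficit", {
  # n = 10, S = 5: every mutation a singleton vs none a singleton
  all_single <- matrix("A", 10, 5)
  for (j in 1:5) all_single[j, j] <- "T"
  rownames(all_single) <- paste0("i", 1:10)
  none_single <- matrix("A", 10, 5)
  for (j in 1:5) none_single[1:5, j] <- "T"
  rownames(none_single) <- paste0("i", 1:10)
  r1 <- fu_li_star_tests(make_locus(all_single))
  r2 <- fu_li_star_tests(make_locus(none_single))
  expect_lt(r1$Dstar, 0)
  expect_gt(r2$Dstar, 0)
  expect_lt(r1$Fstar, 0)
  expect_gt(r2$Fstar, 0)
  # matches the formula oracle on random data
  set.seed(43)
  for (rep in 1:25) {
    mat <- random_alignment(10, 40, n_var = sample(2:6, 1))
    got <- fu_li_star_tests(make_locus(mat))
    want <- oracle_fu_li(mat)
    expect_equal(got$Dstar, want$Dstar)
    expect_equal(got$Fstar, want$Fstar)
  }
  # singleton count on a small example
  lc <- locus_alignment(c(a = "AAA", b = "AAT", c = "AAA", d = "AAA"))
  expect_equal(saltmigrate:::sfs_summary(lc)$eta_s, 1)
})

test_that("Fay & Wu's H separates low- and high-frequency derived alleles", {
  # all derived singletons: theta_H small, H > 0
  n <- 10
  mat <- matrix("A", n, 6)
  for (j in 1:5) mat[j, j] <- "T"
  rownames(mat) <- paste0("i", 1:n)
  og <- strrep("A", 6)
  h_low <- fay_wu_h(make_locus(mat), og)
  expect_equal(h_low, oracle_fay_wu_h(rep(1, 5), n))
  expect_gt(h_low, 0)
  # all derived at n-1 copies: strongly negative
  mat2 <- matrix("T", n, 6)
  mat2[, 6] <- "A"
  for (j in 1:5) mat2[1, j] <- "A"
  rownames(mat2) <- paste0("i", 1:n)
  h_high <- fay_wu_h(make_locus(mat2), strrep("A", 6))
  expect_equal(h_high, oracle_fay_wu_h(rep(n - 1, 5), n))
  expect_lt(h_high, 0)
  # monomorphic: undefined
  expect_true(is.na(fay_wu_h(locus_alignment(c(a = "AAA", b = "AAA")), "AAA")))
  # sites where the outgroup carries a third state are excluded
  mat3 <- rbind(a = c("A", "C"), b = c("T", "C"), c = c("A", "A"))
  expect_message(fay_wu_h(make_locus(mat3), "GA"), "excluded")
})

test_that("Ewens allele-count distribution matches exhaustive enumeration", {
  for (theta in c(0.3, 1, 2.5)) {
    expect_equal(ewens_k_distribution(4, theta), oracle_ewens_k4(theta),
                 tolerance = 1e-10)
  }
  expect_equal(sum(ewens_k_distribution(20, 1.7)), 1, tolerance = 1e-12)
})

test_that("Fu's Fs is large and negative when every sequence is distinct", {
  # n = 6, all distinct haplotypes, low pairwise diversity
  mat <- matrix("A", 6, 6)
  for (j in 1:6) mat[j, j] <- "T"
  rownames(mat) <- paste0("i", 1:6)
  fs <- fu_fs(make_locus(mat))
  expect_lt(fs, -2)
  mono <- locus_alignment(c(a = "AAA", b = "AAA"))
  expect_true(is.na(fu_fs(mono)))
})

test_that("fixed-S null simulation conditions exactly on S", {
  sim <- simulate_fixed_s(12, 7, 200, seed = 2)
  expect_equal(dim(sim$counts), c(200L, 7L))
  expect_true(all(sim$counts >= 1 & sim$counts <= 11))
  expect_true(all(sim$K >= 1 & sim$K <= 12))
})

test_that("neutrality statistics have ~zero mean under the neutral null", {
  sim <- simulate_fixed_s(20, 5, 4000, seed = 8)
  nulls <- saltmigrate:::null_statistics(sim, 20)
  # normalized statistics are centred near zero under neutrality
  expect_lt(abs(mean(nulls$D)), 0.1)
  expect_lt(abs(mean(nulls$Dstar)), 0.15)
  expect_lt(abs(mean(nulls$Fstar)), 0.15)
})

test_that("simulation p-values behave like p-values", {
  sim <- simulate_fixed_s(15, 4, 2000, seed = 5)
  nulls <- saltmigrate:::null_statistics(sim, 15)
  p_med <- simulate_null_pvalue("D", 15, 4, median(nulls$D),
                                n_sims = 2000, seed = 5)
  expect_gt(p_med, 0.9)
  # p approximately uniform across null datasets
  set.seed(77)
  sim_obs <- simulate_fixed_s(12, 5, 300)
  obs_stats <- saltmigrate:::null_statistics(sim_obs, 12)$D
  ref <- saltmigrate:::null_statistics(simulate_fixed_s(12, 5, 2000), 12)$D
  pvals <- vapply(obs_stats[1:200], function(o)
    min(1, 2 * min(mean(ref <= o), mean(ref >= o))), numeric(1))
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.001)
})

test_that("the calibrated synthetic data show no departure from neutrality", {
  ds <- generate_study_like_dataset(seed = 6)
  tab <- neutrality_tests(ds, genome = "nuclear", n_sims = 2000, seed = 10)
  polym <- tab[!is.na(tab$D), ]
  expect_gt(nrow(polym), 0)
  expect_true(all(polym$p_D > 0.05))
  expect_true(all(polym$p_Dstar > 0.05))
  expect_true(all(polym$p_Fstar > 0.05))
})
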