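test_that("mismatch histograms count pairwise differences", {
  ds <- generate_toy(list(loc = c("AA", "AT", "TT")))
  h <- mismatch_distribution(ds, genome = NULL)
  expect_equal(h$count[h$differences == 1], 2L)
  expect_equal(h$count[h$differences == 2], 1L)
  expect_equal(sum(h$count), 3L)

  same <- generate_toy(list(loc = rep("ACGT", 5)))
  h0 <- mismatch_distribution(same, genome = NULL)
  expect_equal(h0$count, 10L)
  expect_equal(h0$differences, 0L)
})

test_that("expected mismatch frequencies are a proper distribution", {
  for (pars in list(c(3, 0.5, 50), c(0.5, 0.1, 5), c(10, 2, 200))) {
    f <- expected_mismatch(0:400, pars[1], pars[2], pars[3])
    expect_true(all(f >= 0))
    expect_equal(sum(f), 1, tolerance = 1e-6)
  }
  # tau = 0 collapses to the stationary distribution at theta0
  expect_equal(expected_mismatch(0:50, 0, 2, 99),
               2^(0:50) / 3^(1:51), tolerance = 1e-12)
  # enormous tau approaches the stationary distribution at theta1
  expect_equal(expected_mismatch(0:30, 500, 1, 3),
               3^(0:30) / 4^(1:31), tolerance = 1e-6)
})

test_that("the closed form is recovered from its own histogram", {
  truth <- c(tau = 3, theta0 = 0.5, theta1 = 50)
  f <- expected_mismatch(0:60, truth[1], truth[2], truth[3])
  h <- tibble::tibble(differences = 0:60, count = f * 1e9)
  fit <- fit_sudden_expansion(h, extra_classes = 0)
  expect_lt(fit$ssd, 1e-8)
  expect_lt(abs(fit$tau / truth["tau"] - 1), 1e-3)
  expect_lt(abs(fit$theta1 / truth["theta1"] - 1), 0.05)
  expect_lt(fit$theta0, 0.6)
})

test_that("a histogram with all mass at zero degenerates cleanly", {
  h <- tibble::tibble(differences = 0L, count = 10L)
  fit <- fit_sudden_expansion(h)
  expect_equal(fit$tau, 0)
  expect_equal(fit$theta0, 0)
  expect_equal(fit$ssd, 0)
})

test_that("raggedness matches the direct sums", {
  uni <- tibble::tibble(differences = 0:4, count = rep(2L, 5))
  expect_equal(raggedness(uni), 0.08)
  spike <- tibble::tibble(differences = 0L, count = 7L)
  expect_equal(raggedness(spike), 2)
  smooth <- tibble::tibble(differences = 0:6,
                           count = c(1, 4, 8, 10, 8, 4, 1))
  two_spike <- tibble::tibble(differences = 0:6,
                              count = c(18, 0, 0, 0, 0, 0, 18))
  expect_lt(raggedness(smooth), raggedness(two_spike))
  set.seed(3)
  for (rep in 1:20) {
    cnt <- rpois(8, 4) + 1
    h <- tibble::tibble(differences = 0:7, count = cnt)
    expect_equal(raggedness(h), oracle_raggedness(cnt))
  }
})

test_that("expansion data fit the sudden-expansion model better than constant-size data", {
  set.seed(14)
  wins <- replicate(40, {
    h_exp <- saltmigrate:::simulate_expansion_mismatch(30, 4, 0.5, 60)
    scn <- demographic_scenario(c(A = 4))
    g <- simulate_genealogies(scn, c(A = 30), n_loci = 1)
    m <- add_mutations(g, tibble::tibble(locus = "x", length = 1e9, mu = 0.5))
    der <- m[[1]]$derived
    d <- matrix(0L, 30, 30)
    for (j in seq_len(ncol(der))) d <- d + outer(der[, j], der[, j], "!=")
    diffs <- d[upper.tri(d)]
    h_const <- tibble::tibble(differences = 0:max(diffs, 0),
                              count = tabulate(diffs + 1L, max(diffs, 0) + 1L))
    fit_sudden_expansion(h_exp)$ssd < fit_sudden_expansion(h_const)$ssd
  })
  expect_gt(mean(wins), 0.6)
})

test_that("parameter recovery under the expansion model is adequate", {
  set.seed(15)
  rel_err <- replicate(50, {
    h <- saltmigrate:::simulate_expansion_mismatch(60, 2, 0.4, 40)
    fit <- fit_sudden_expansion(h)
    abs(fit$tau - 2) / 2
  })
  expect_lt(median(rel_err), 0.30)
})

test_that("bootstrap SSD p-values behave sensibly", {
  set.seed(16)
  h <- saltmigrate:::simulate_expansion_mismatch(30, 3, 0.5, 50)
  fit <- fit_sudden_expansion(h)
  pv <- ssd_pvalue(fit, 30, n_boot = 80, seed = 17)
  expect_true(pv$p_ssd >= 0 && pv$p_ssd <= 1)
  # SSD == 0 cannot be exceeded downward: p = 1 up to boot noise
  h0 <- tibble::tibble(differences = 0L, count = 10L)
  fit0 <- fit_sudden_expansion(h0)
  pv0 <- ssd_pvalue(fit0, 5, n_boot = 40, seed = 18)
  expect_gt(pv0$p_ssd, 0.9)
})

test_that("the northern-China-like group does not reject sudden expansion", {
  ds <- generate_study_like_dataset(seed = 5)
  hB <- mismatch_distribution(ds, group = "B")
  fitB <- fit_sudden_expansion(hB)
  pv <- ssd_pvalue(fitB, sum(ds$pop_map$group == "B"), n_boot = 100,
                   seed = 19)
  expect_gt(pv$p_ssd, 0.05)
})
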