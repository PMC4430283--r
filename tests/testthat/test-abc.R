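test_that("the four scenario templates validate and differ as intended", {
  scns <- define_scenarios()
  expect_length(scns, 4)
  for (s in scns) expect_true(validate_scenario(s))
  # fast event matrices agree with the reference builder
  p <- list(N_A = 5e3, N_B = 2e4, N_C = 1e3, N_anc = 800, N_B0 = 200,
            T1 = 2e4, T2 = 9e3, T_exp = 4e3, r = 0.3)
  for (sid in 1:4) {
    ref <- saltmigrate:::scenario_matrix(migration_scenario(sid, p))
    fast <- saltmigrate:::fast_event_matrix(as.character(sid), p$N_B0,
                                            p$N_anc, p$T1, p$T2, p$T_exp, p$r)
    dimnames(ref) <- dimnames(fast) <- NULL
    expect_equal(ref, fast)
  }
})

test_that("summary vectors follow their definitions on toy data", {
  ds <- generate_toy(list(loc = rep("ACGTACGT", 6)),
                     populations = rep(c("p1", "p2"), each = 3),
                     groups = c(p1 = "G1", p2 = "G2"))
  s <- compute_summaries(ds, genome = NULL)
  expect_equal(unname(s[c("Nh_G1", "S_G1", "pi_G1")]), c(1, 0, 0))
  expect_equal(unname(s["B_G1_G2"]), 0)

  # two groups fixed for haplotypes 5 differences apart
  ds2 <- generate_toy(list(loc = rep(c("AAAAAAAA", "TTTTTAAA"), each = 3)),
                      populations = rep(c("p1", "p2"), each = 3),
                      groups = c(p1 = "G1", p2 = "G2"))
  s2 <- compute_summaries(ds2, genome = NULL)
  expect_equal(unname(s2["B_G1_G2"]), 5)
  expect_equal(unname(s2["W_G1_G2"]), 0)
  # ordering is stable
  expect_identical(names(s2), names(compute_summaries(ds2, genome = NULL)))
})

test_that("weighted lineage summaries equal individual-level summaries", {
  # simulated lineages copied within populations must give the same
  # summary vector as one weighted lineage per population
  ds <- generate_study_like_dataset(seed = 21)
  obs <- compute_summaries(ds)
  # reconstruct lineage-level data: first individual of each population
  pm <- ds$pop_map
  firsts <- pm[!duplicated(pm$population), ]
  sizes <- table(pm$population)[firsts$population]
  nuc <- ds$loci[ds$genome == "nuclear"]
  d <- 0
  concat <- do.call(cbind, purrr::map(nuc, unclass))[firsts$individual, ]
  groups <- sort(unique(pm$group))
  w <- as.numeric(sizes)
  grp <- match(firsts$group, groups)
  ng <- tapply(w, grp, sum)
  # S per group from weighted counts equals the individual-level S
  for (g in seq_along(groups)) {
    idx <- which(grp == g)
    sub <- concat[idx, , drop = FALSE]
    S_w <- sum(apply(sub, 2, function(col) {
      cw <- tapply(rep(w[idx], 1), col, FUN = sum)
      length(cw) > 1
    }))
    expect_equal(unname(obs[paste0("S_", groups[g])]), S_w)
  }
})

test_that("abc output is deterministic given a seed and probabilities sum to 1", {
  ds <- generate_study_like_dataset(seed = 2)
  des <- abc_design(ds)
  obs <- compute_summaries(ds)
  r1 <- run_abc(obs, des, n_sims = 1500, seed = 99)
  r2 <- run_abc(obs, des, n_sims = 1500, seed = 99)
  expect_equal(r1$model_probs, r2$model_probs)
  sums <- r1$model_probs %>%
    dplyr::group_by(method) %>%
    dplyr::summarise(s = sum(probability))
  expect_equal(sums$s, rep(1, 2), tolerance = 1e-6)
  expect_true(all(r1$model_probs$lower >= 0 & r1$model_probs$upper <= 1))
})

test_that("parameter adjustment is the identity at zero discrepancy", {
  set.seed(7)
  params <- tibble::tibble(N_A = exp(runif(150, 5, 10)),
                           T1 = runif(150, 1e3, 1e5))
  obs <- c(s1 = 0.5, s2 = -0.2, s3 = 1)
  summ <- matrix(rep(obs, each = 150), 150, 3,
                 dimnames = list(NULL, names(obs)))
  adj <- adjust_parameters(params, summ, obs, distances = rep(0.5, 150))
  expect_equal(adj$N_A, params$N_A, tolerance = 1e-8)
  expect_equal(adj$T1, params$T1, tolerance = 1e-8)
})

test_that("adjustment shrinks posterior spread on average", {
  set.seed(8)
  shrunk <- replicate(20, {
    n <- 300
    theta <- runif(n, 0, 10)
    s <- theta + rnorm(n, 0, 1)      # informative summary
    obs <- 5
    d <- abs(s - obs)
    keep <- order(d)[1:150]
    adj <- adjust_parameters(tibble::tibble(r = theta[keep]),
                             matrix(s[keep], ncol = 1,
                                    dimnames = list(NULL, "s")),
                             c(s = obs), d[keep])
    var(adj$r) <= var(theta[keep])
  })
  expect_gt(mean(shrunk), 0.8)
})

test_that("scenarios are recovered above chance by the full loop", {
  # datasets simulated under scenarios 1 and 3 with distinct histories are
  # classified back to their generating scenario
  correct <- 0
  for (i in 1:6) {
    sid <- c(1, 3)[(i %% 2) + 1]
    p <- list(N_A = 12000, N_B = 60000, N_C = 3000, N_anc = 1500,
              N_B0 = 300, T1 = 23000, T2 = 11000, T_exp = 8000)
    ds <- generate_study_like_dataset(seed = 300 + i, params = p,
                                      scenario_id = sid)
    res <- run_abc(compute_summaries(ds), abc_design(ds), n_sims = 4000,
                   seed = 400 + i)
    lg <- res$model_probs[res$model_probs$method == "logistic", ]
    if (lg$scenario[which.max(lg$probability)] == sid) correct <- correct + 1
  }
  expect_gt(correct, 3)
})

test_that("model checking places self-consistent data inside the envelope", {
  ds <- generate_study_like_dataset(seed = 23)
  des <- abc_design(ds)
  res <- run_abc(compute_summaries(ds), des, n_sims = 3000, seed = 24)
  chk <- model_check_pca(res, des, n_post = 200, seed = 25)
  expect_false(chk$outside)
  expect_true(all(c("PC1", "PC2", "what") %in% names(chk$coords)))
  # training-mean projection is the origin
  ctr <- colMeans(chk$coords[chk$coords$what == "prior-predictive",
                             c("PC1", "PC2")])
  expect_equal(unname(as.numeric(ctr)), c(0, 0), tolerance = 1e-8)
})
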