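test_that("pairwise coalescence times match E[T2] = 2 Ne", {
  scn <- demographic_scenario(c(A = 1000))
  td <- tidy(simulate_genealogies(scn, c(A = 2), n_loci = 8000, seed = 1))
  se <- sd(td$tmrca) / sqrt(nrow(td))
  expect_lt(abs(mean(td$tmrca) - 2000), 4 * se)
})

test_that("total branch length matches 4 Ne a_(n-1)", {
  scn <- demographic_scenario(c(A = 500))
  td <- tidy(simulate_genealogies(scn, c(A = 20), n_loci = 6000, seed = 2))
  expected <- 4 * 500 * sum(1 / (1:19))
  se <- sd(td$tlen) / sqrt(nrow(td))
  expect_lt(abs(mean(td$tlen) - expected), 4 * se)
})

test_that("lineages split at time T never coalesce more recently", {
  scn <- demographic_scenario(c(A = 100, B = 100)) |>
    ev_split(500, "B", into = "A")
  td <- tidy(simulate_genealogies(scn, c(A = 1, B = 1), n_loci = 2000,
                                  seed = 3))
  expect_true(all(td$tmrca >= 500))
  expect_lt(abs(mean(td$tmrca) - 700), 25)  # T + 2 Ne
})

test_that("mutation overlay reproduces Watterson's expectation", {
  scn <- demographic_scenario(c(A = 1000))
  g <- simulate_genealogies(scn, c(A = 10), n_loci = 6000, seed = 4)
  lm <- tibble::tibble(locus = paste0("l", 1:6000), length = 1000, mu = 1e-3)
  m <- add_mutations(g, lm, seed = 5)
  S <- vapply(m, function(x) ncol(x$derived), numeric(1))
  theta <- 4 * 1000 * 1e-3
  expected <- theta * sum(1 / (1:9))
  se <- sd(S) / sqrt(length(S))
  expect_lt(abs(mean(S) - expected), 4 * se)
  # mu = 0 leaves every sequence identical
  m0 <- add_mutations(g[1:5], lm[1:5, ] |> dplyr::mutate(mu = 0))
  expect_true(all(vapply(m0, function(x) ncol(x$derived), numeric(1)) == 0))
})

test_that("pairwise differences estimate theta = 4 Ne mu L", {
  scn <- demographic_scenario(c(A = 800))
  g <- simulate_genealogies(scn, c(A = 2), n_loci = 8000, seed = 6)
  m <- add_mutations(g, tibble::tibble(locus = paste0("l", 1:8000),
                                       length = 500, mu = 2e-6 * 500),
                     seed = 7)
  diffs <- vapply(m, function(x) ncol(x$derived), numeric(1))
  theta <- 4 * 800 * 2e-6 * 500
  se <- sd(diffs) / sqrt(length(diffs))
  expect_lt(abs(mean(diffs) - theta), 4 * se)
})

test_that("the site frequency spectrum is proportional to 1/i", {
  # E[S_i] = theta / i; per-locus counts share a genealogy, so compare
  # class means against theory with empirical standard errors
  scn <- demographic_scenario(c(A = 1000))
  n_loci <- 4000
  g <- simulate_genealogies(scn, c(A = 10), n_loci = n_loci, seed = 8)
  m <- add_mutations(g, tibble::tibble(locus = paste0("l", seq_len(n_loci)),
                                       length = 5000, mu = 1e-3), seed = 9)
  per <- t(vapply(m, function(x) tabulate(colSums(x$derived), 9),
                  numeric(9)))
  theta <- 4 * 1000 * 1e-3
  z <- (colMeans(per) - theta / (1:9)) /
    (apply(per, 2, sd) / sqrt(n_loci))
  expect_true(all(abs(z) < 4))
})

test_that("a strong instantaneous expansion makes genealogies star-like", {
  scn <- demographic_scenario(c(A = 50000)) |>
    ev_resize(1000, "A", 500)
  g <- simulate_genealogies(scn, c(A = 20), n_loci = 400, seed = 9)
  lm <- tibble::tibble(locus = paste0("l", 1:400), length = 2000,
                       mu = 1e-6 * 2000)
  m <- add_mutations(g, lm, seed = 10)
  Ds <- vapply(m, function(x) {
    if (ncol(x$derived) < 2) return(NA_real_)
    cnts <- colSums(x$derived)
    n <- nrow(x$derived)
    pi_abs <- sum(cnts * (n - cnts)) / choose(n, 2)
    saltmigrate:::tajima_d_from(n, ncol(x$derived), pi_abs)
  }, numeric(1))
  expect_lt(mean(Ds, na.rm = TRUE), -0.5)
})

test_that("stranded lineages are caught by scenario validation", {
  scn <- demographic_scenario(c(A = 100, B = 100))  # never joined
  expect_error(simulate_genealogies(scn, c(A = 2, B = 2)), "stranded")
  scn2 <- demographic_scenario(c(A = 100, B = 100, C = 100)) |>
    ev_split(100, "B", into = "A")
  expect_error(validate_scenario(scn2), "stranded")
  # events touching a closed deme are rejected
  scn3 <- demographic_scenario(c(A = 100, B = 100)) |>
    ev_split(100, "B", into = "A") |>
    ev_resize(200, "B", 50)
  expect_error(validate_scenario(scn3), "closed deme")
})

test_that("summary means agree with the stored msprime benchmarks", {
  fx <- jsonlite::read_json(test_path("fixtures", "msprime_benchmarks.json"),
                            simplifyVector = TRUE)
  tol <- 0.04  # Monte-Carlo error at 2e4 oracle + 6e3 package replicates

  scn <- demographic_scenario(c(A = 1000))
  g <- simulate_genealogies(scn, c(A = 10), n_loci = 6000, seed = 11)
  m <- add_mutations(g, tibble::tibble(locus = paste0("l", 1:6000),
                                       length = 1000, mu = 1e-3), seed = 12)
  S <- vapply(m, function(x) ncol(x$derived), numeric(1))
  expect_lt(abs(mean(S) / fx$constant$mean_S - 1), tol)
  expect_lt(abs(mean(tidy(g)$tmrca) / fx$constant$mean_tmrca - 1), tol)

  scn2 <- demographic_scenario(c(A = 500, B = 500, anc = 500)) |>
    ev_split(2000, "A", into = "anc") |>
    ev_split(2000, "B", into = "anc")
  g2 <- simulate_genealogies(scn2, c(A = 5, B = 5, anc = 0), n_loci = 6000,
                             seed = 13)
  m2 <- add_mutations(g2, tibble::tibble(locus = paste0("l", 1:6000),
                                         length = 1000, mu = 1e-3), seed = 14)
  S2 <- vapply(m2, function(x) ncol(x$derived), numeric(1))
  expect_lt(abs(mean(S2) / fx$split$mean_S - 1), tol)
  expect_lt(abs(mean(tidy(g2)$tmrca) / fx$split$mean_tmrca - 1), tol)

  scn3 <- demographic_scenario(c(A = 10000)) |>
    ev_resize(1000, "A", 100)
  g3 <- simulate_genealogies(scn3, c(A = 20), n_loci = 6000, seed = 15)
  m3 <- add_mutations(g3, tibble::tibble(locus = paste0("l", 1:6000),
                                         length = 1000, mu = 1e-3), seed = 16)
  S3 <- vapply(m3, function(x) ncol(x$derived), numeric(1))
  expect_lt(abs(mean(S3) / fx$expansion$mean_S - 1), tol)
  expect_lt(abs(mean(tidy(g3)$tmrca) / fx$expansion$mean_tmrca - 1), tol)
})

test_that("admixture routes lineages in the stated proportions", {
  # B founded entirely from A: coalescence with A-like times
  scn_a <- demographic_scenario(c(A = 200, B = 200, C = 200)) |>
    ev_admixture(10, "B", into = "A", source2 = "C", proportion = 1) |>
    ev_split(1e6, "C", into = "A")
  td <- tidy(simulate_genealogies(scn_a, c(A = 1, B = 1, C = 0),
                                  n_loci = 1500, seed = 17))
  expect_lt(mean(td$tmrca), 3000)  # ~ 10 + 2*200
  # B founded entirely from C: must wait for the deep C/A split
  scn_c <- demographic_scenario(c(A = 200, B = 200, C = 200)) |>
    ev_admixture(10, "B", into = "A", source2 = "C", proportion = 0) |>
    ev_split(5e4, "C", into = "A")
  td2 <- tidy(simulate_genealogies(scn_c, c(A = 1, B = 1, C = 0),
                                   n_loci = 300, seed = 18))
  expect_true(all(td2$tmrca >= 5e4))
})
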