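#' Default prior specification for the migration scenarios
#'
#' Log-uniform effective sizes and uniform event times; divergence-time
#' ordering (`T1 > T2 > Texp`) is enforced by conditional sampling.
#'
#' @return Tibble with columns `parameter`, `dist`, `min`, `max`.
#' @export
abc_priors <- function() {
  tibble(parameter = c("N_A", "N_B", "N_C", "N_anc", "N_B0",
                       "T1", "T2", "T_exp", "r"),
         dist = c(rep("logunif", 5), rep("unif", 4)),
         min = c(rep(1e2, 5), 1e3, 5e2, 1e2, 0.05),
         max = c(rep(1e6, 5), 1e5, NA, NA, 0.95))
}

scenario_parameters <- function(scenario_id) {
  base <- c("N_A", "N_B", "N_C", "N_B0", "T1", "T2", "T_exp")
  switch(scenario_id,
         `1` = c(base, "N_anc"),
         `2` = c(base, "N_anc"),
         `3` = c(base, "N_anc"),
         `4` = c(base, "r"),
         stop("scenario_id must be 1..4"))
}

draw_parameters <- function(scenario_id, n, priors = abc_priors()) {
  pr <- function(p) priors[priors$parameter == p, ]
  draw1 <- function(p, lo = NULL, hi = NULL) {
    row <- pr(p)
    lo <- if (is.null(lo)) row$min else pmax(lo, row$min)
    hi <- if (is.null(hi)) row$max else hi
    if (row$dist == "logunif") exp(runif(n, log(lo), log(hi)))
    else runif(n, lo, hi)
  }
  d <- tibble(N_A = draw1("N_A"), N_B = draw1("N_B"), N_C = draw1("N_C"),
              N_B0 = draw1("N_B0"),
              T1 = draw1("T1"))
  d$T2 <- runif(n, pr("T2")$min, d$T1)
  d$T_exp <- runif(n, pr("T_exp")$min, d$T2)
  if ("N_anc" %in% scenario_parameters(as.character(scenario_id)))
    d$N_anc <- draw1("N_anc")
  if ("r" %in% scenario_parameters(as.character(scenario_id)))
    d$r <- runif(n, pr("r")$min, pr("r")$max)
  d
}

#' The four divergence-with-expansion migration scenarios
#'
#' Three sampled groups A (central Asia), B (northern China + Buriatia)
#' and C (North America + Russia); all scenarios include a recent
#' expansion of B (size `N_B0` before `T_exp`). Looking forwards in time:
#' * scenario 1 — A is the source: the ancestor of (B, C) splits from A at
#'   `T1`; B and C split at `T2`.
#' * scenario 2 — B is the source: the ancestor of (A, C) splits from B at
#'   `T1`; A and C split at `T2`.
#' * scenario 3 — C is the source: the ancestor of (A, B) splits from C at
#'   `T1`; A and B split at `T2`.
#' * scenario 4 — admixture origin: A and C split at `T1`; B is founded at
#'   `T2` by admixture of A (proportion `r`) and C.
#'
#' @param params Named list/row with entries `N_A`, `N_B`, `N_C`, `N_B0`,
#'   `T1`, `T2`, `T_exp` plus `N_anc` (scenarios 1-3) or `r` (scenario 4).
#' @param scenario_id Integer 1..4 (for `migration_scenario`).
#' @return A [demographic_scenario()] (or list of all four for
#'   [define_scenarios()]).
#' @export
migration_scenario <- function(scenario_id, params) {
  p <- as.list(params)
  demes <- c(A = p$N_A, B = p$N_B, C = p$N_C)
  scn <- demographic_scenario(demes, label = paste0("scenario", scenario_id))
  scn <- ev_resize(scn, p$T_exp, "B", p$N_B0)
  if (scenario_id == 1) {
    scn <- ev_split(scn, p$T2, "C", into = "B")
    scn <- ev_resize(scn, p$T2, "B", p$N_anc)
    scn <- ev_split(scn, p$T1, "B", into = "A")
  } else if (scenario_id == 2) {
    scn <- ev_split(scn, p$T2, "C", into = "A")
    scn <- ev_resize(scn, p$T2, "A", p$N_anc)
    scn <- ev_split(scn, p$T1, "A", into = "B")
  } else if (scenario_id == 3) {
    scn <- ev_split(scn, p$T2, "B", into = "A")
    scn <- ev_resize(scn, p$T2, "A", p$N_anc)
    scn <- ev_split(scn, p$T1, "A", into = "C")
  } else if (scenario_id == 4) {
    scn <- ev_admixture(scn, p$T2, "B", into = "A", source2 = "C",
                        proportion = p$r)
    scn <- ev_split(scn, p$T1, "C", into = "A")
  } else stop("scenario_id must be 1..4")
  scn
}

#' @rdname migration_scenario
#' @param example_params Parameter values used to instantiate the returned
#'   templates (defaults to mid-prior values).
#' @export
define_scenarios <- function(example_params = NULL) {
  if (is.null(example_params))
    example_params <- list(N_A = 1e4, N_B = 1e5, N_C = 1e4, N_anc = 1e3,
                           N_B0 = 5e2, T1 = 2.3e4, T2 = 1.1e4, T_exp = 8e3,
                           r = 0.5)
  purrr::map(1:4, migration_scenario, params = example_params)
}

#' Sampling design for ABC simulation
#'
#' Describes how simulated lineages map to groups: one lineage per
#' sampling unit with a weight (its number of copied individuals). The
#' default mirrors a design where within-population variation is absent,
#' so one lineage is simulated per population and weighted by the
#' population sample size.
#'
#' @param dataset A [multilocus_dataset()]; lineages are populations when
#'   `by_population = TRUE` (default), individuals otherwise.
#' @param by_population Simulate one lineage per population, weighted by
#'   its number of individuals.
#' @param genome Which loci define the locus lengths (default nuclear).
#' @param mu_site Mutation rate per site per year.
#' @return List of class `abc_design` with `sample_deme`, `weights`,
#'   `group`, `groups`, `locus_len`, `mu_site`.
#' @export
abc_design <- function(dataset, by_population = TRUE, genome = "nuclear",
                       mu_site = 9.3e-9) {
  pm <- dataset$pop_map
  groups <- sort(unique(pm$group))
  if (by_population) {
    units <- pm %>% count(.data$population, .data$group)
    grp <- match(units$group, groups) - 1L
    w <- units$n
  } else {
    grp <- match(pm$group, groups) - 1L
    w <- rep(1, nrow(pm))
  }
  loci <- dataset$loci
  if (!is.null(genome)) loci <- loci[dataset$genome[names(loci)] == genome]
  structure(list(sample_deme = as.integer(grp), weights = as.numeric(w),
                 group = as.integer(grp), groups = groups,
                 locus_len = vapply(loci, ncol, numeric(1)),
                 mu_site = mu_site),
            class = "abc_design")
}

summary_names <- function(groups) {
  one <- purrr::map(groups, ~ paste0(c("Nh_", "S_", "pi_"), .x))
  pairs <- combn(groups, 2)
  two <- purrr::map(seq_len(ncol(pairs)), function(j)
    paste0(c("W_", "B_"), pairs[1, j], "_", pairs[2, j]))
  c(unlist(one), unlist(two))
}

#' One- and two-sample summary statistics of a dataset
#'
#' Per group: number of distinct haplotypes (concatenated loci), number of
#' segregating sites, and mean pairwise differences; per group pair: mean
#' within-sample pairwise differences (W) and mean between-sample pairwise
#' differences (B). The ordering is fixed (groups sorted, then pairs in
#' lexicographic order), so vectors are directly comparable across runs.
#'
#' @param dataset A [multilocus_dataset()].
#' @param genome Restrict to `"nuclear"` (default) loci.
#' @return Named numeric vector (class `summary_vector`).
#' @export
compute_summaries <- function(dataset, genome = "nuclear") {
  pm <- dataset$pop_map
  groups <- sort(unique(pm$group))
  loci <- dataset$loci
  if (!is.null(genome)) loci <- loci[dataset$genome[names(loci)] == genome]
  concat <- do.call(cbind, purrr::map(loci, unclass))[pm$individual, ,
                                                      drop = FALSE]
  cols <- analyzable_columns(concat)
  sub <- concat[, cols, drop = FALSE]
  idx_of <- purrr::map(groups, ~ which(pm$group == .x))
  for (g in seq_along(groups))
    if (length(idx_of[[g]]) < 2) stop("group '", groups[g],
                                      "' has fewer than 2 individuals")
  n <- nrow(sub)
  d <- matrix(0, n, n)
  for (j in seq_len(ncol(sub)))
    if (dplyr::n_distinct(sub[, j]) > 1L)
      d <- d + outer(sub[, j], sub[, j], "!=")
  out <- numeric(0)
  for (g in seq_along(groups)) {
    idx <- idx_of[[g]]
    m <- sub[idx, , drop = FALSE]
    Nh <- dplyr::n_distinct(apply(m, 1, paste, collapse = ""))
    S <- sum(apply(m, 2, dplyr::n_distinct) > 1L)
    pi_g <- mean(d[idx, idx][upper.tri(d[idx, idx])])
    out <- c(out, Nh, S, pi_g)
  }
  pairs <- combn(seq_along(groups), 2)
  for (j in seq_len(ncol(pairs))) {
    i1 <- idx_of[[pairs[1, j]]]; i2 <- idx_of[[pairs[2, j]]]
    within <- c(d[i1, i1][upper.tri(d[i1, i1])], d[i2, i2][upper.tri(d[i2, i2])])
    out <- c(out, mean(within), mean(d[i1, i2]))
  }
  structure(setNames(out, summary_names(groups)), class = "summary_vector")
}

# fast numeric event-matrix builder equivalent to
# scenario_matrix(migration_scenario(id, params)); demes A=1, B=2, C=3
fast_event_matrix <- function(scenario_id, NB0, Nanc, T1, T2, Texp, r) {
  resB <- c(Texp, 2, 2, 0, 0, NB0)
  switch(scenario_id,
    `1` = rbind(resB, c(T2, 1, 3, 2, 0, 0), c(T2, 2, 2, 0, 0, Nanc),
                c(T1, 1, 2, 1, 0, 0), deparse.level = 0),
    `2` = rbind(resB, c(T2, 1, 3, 1, 0, 0), c(T2, 2, 1, 0, 0, Nanc),
                c(T1, 1, 1, 2, 0, 0), deparse.level = 0),
    `3` = rbind(resB, c(T2, 1, 2, 1, 0, 0), c(T2, 2, 1, 0, 0, Nanc),
                c(T1, 1, 1, 3, 0, 0), deparse.level = 0),
    `4` = rbind(resB, c(T2, 3, 2, 1, 3, r), c(T1, 1, 3, 1, 0, 0),
                deparse.level = 0),
    stop("scenario_id must be 1..4"))
}

#' Simulate summary statistics under a migration scenario
#'
#' @param scenario_id Integer 1..4.
#' @param params Tibble of parameter draws (one row per simulation), e.g.
#'   from the scenario priors.
#' @param design An [abc_design()].
#' @return Matrix (draws x summaries).
#' @export
simulate_summaries <- function(scenario_id, params, design) {
  sid <- as.character(scenario_id)
  NA_ <- params$N_A; NB <- params$N_B; NC <- params$N_C
  NB0 <- params$N_B0; T1 <- params$T1; T2 <- params$T2; Te <- params$T_exp
  Nanc <- if ("N_anc" %in% names(params)) params$N_anc else rep(0, nrow(params))
  r <- if ("r" %in% names(params)) params$r else rep(0, nrow(params))
  scen_list <- lapply(seq_len(nrow(params)), function(i) {
    list(events = fast_event_matrix(sid, NB0[i], Nanc[i], T1[i], T2[i],
                                    Te[i], r[i]),
         N0 = c(NA_[i], NB[i], NC[i]))
  })
  m <- abc_sim_batch_cpp(scen_list, design$sample_deme, design$group,
                         design$weights, unname(design$locus_len),
                         design$mu_site)
  colnames(m) <- summary_names(design$groups)
  m
}

epanechnikov <- function(d, h) ifelse(d < h, 1 - (d / h)^2, 0)

#' Local-linear regression adjustment of accepted parameter draws
#'
#' Beaumont-style ABC posterior adjustment: each parameter (log scale for
#' sizes/times, identity for proportions) is regressed on the discrepancy
#' between accepted and observed summaries with Epanechnikov weights, and
#' draws are corrected to the observed point. Falls back to a ridge
#' regression when the design is rank-deficient.
#'
#' @param params Tibble of accepted parameter draws.
#' @param summaries Matrix of their (standardized) summary statistics.
#' @param observed Standardized observed summary vector.
#' @param distances Distances of the accepted draws to the observed point.
#' @return Tibble of adjusted draws with attribute `quantiles` (median and
#'   95% interval per parameter) and `ridge` flag.
#' @export
adjust_parameters <- function(params, summaries, observed, distances) {
  if (nrow(params) < 100) stop("need at least 100 accepted draws")
  X <- sweep(summaries, 2, observed)
  w <- epanechnikov(distances, max(distances) * (1 + 1e-9))
  ridge <- FALSE
  adj <- purrr::map(names(params), function(p) {
    y <- params[[p]]
    loged <- !p %in% "r"
    yt <- if (loged) log(y) else y
    fit <- lm(yt ~ X, weights = w)
    b <- stats::coef(fit)[-1]
    if (anyNA(b)) {
      ridge <<- TRUE
      XtWX <- crossprod(X * sqrt(w))
      lambda <- 1e-6 * mean(diag(XtWX))
      if (!is.finite(lambda) || lambda <= 0) lambda <- 1e-8
      b <- solve(XtWX + diag(lambda, ncol(X)),
                 crossprod(X * w, yt - stats::weighted.mean(yt, w)))[, 1]
    }
    star <- yt - as.vector(X %*% b)
    if (loged) exp(star) else star
  })
  out <- as_tibble(setNames(adj, names(params)))
  qs <- purrr::map(out, quantile, probs = c(0.025, 0.5, 0.975))
  attr(out, "quantiles") <- bind_rows(purrr::imap(qs, ~ tibble(
    parameter = .y, lower = .x[1], median = .x[2], upper = .x[3])))
  attr(out, "ridge") <- ridge
  out
}

#' ABC model choice over the four migration scenarios
#'
#' Simulates summary statistics under each scenario, standardizes all
#' summaries by their simulation-table standard deviation, and estimates
#' per-scenario posterior probabilities two ways: the direct approach
#' (scenario composition among the `n_direct` closest simulations, with a
#' binomial confidence interval) and multinomial logistic regression over
#' the `tolerance` fraction of closest simulations evaluated at the
#' observed point (delta-method confidence interval). Parameters of the
#' best-supported scenario are adjusted by local-linear regression.
#'
#' @param observed Observed summary vector ([compute_summaries()]).
#' @param design An [abc_design()].
#' @param scenarios Integer vector of scenario ids (default 1:4).
#' @param priors Prior table ([abc_priors()]).
#' @param n_sims Simulations per scenario.
#' @param tolerance Fraction of closest simulations for the logistic
#'   regression and parameter adjustment (default 0.01).
#' @param n_direct Number of closest simulations for the direct estimate.
#' @param seed Optional seed.
#' @return Object of class `abc_result`: `model_probs` tibble (scenario,
#'   method, probability, CI), `posterior` (adjusted draws for the winning
#'   scenario), `winner`, plus the simulation reference table needed for
#'   model checking.
#' @export
run_abc <- function(observed, design, scenarios = 1:4, priors = abc_priors(),
                    n_sims = 20000, tolerance = 0.01, n_direct = 400,
                    seed = NULL) {
  with_seed(seed, {
    draws <- purrr::map(scenarios, ~ draw_parameters(.x, n_sims, priors))
    sims <- purrr::map2(scenarios, draws,
                        ~ simulate_summaries(.x, .y, design))
    tab <- do.call(rbind, sims)
    scen_id <- rep(scenarios, each = n_sims)

    sds <- apply(tab, 2, sd)
    keep <- sds > 0
    if (any(!keep))
      warning("summary statistic(s) with zero variance dropped: ",
              paste(colnames(tab)[!keep], collapse = ", "))
    Z <- sweep(tab[, keep, drop = FALSE], 2, sds[keep], "/")
    zobs <- observed[colnames(tab)][keep] / sds[keep]
    dist <- sqrt(rowSums(sweep(Z, 2, zobs)^2))

    # direct approach
    ord <- order(dist)
    top <- ord[seq_len(min(n_direct, length(ord)))]
    p_direct <- vapply(scenarios, function(s) mean(scen_id[top] == s),
                       numeric(1))
    se <- sqrt(p_direct * (1 - p_direct) / length(top))
    direct <- tibble(scenario = scenarios, method = "direct",
                     probability = p_direct,
                     lower = pmax(0, p_direct - 1.96 * se),
                     upper = pmin(1, p_direct + 1.96 * se))

    # logistic regression on the tolerance fraction of closest simulations
    n_tol <- min(length(dist),
                 max(ceiling(tolerance * length(dist)), 10 * length(scenarios)))
    sel <- ord[seq_len(n_tol)]
    logistic <- tryCatch({
      df <- as.data.frame(Z[sel, , drop = FALSE])
      df$scenario <- factor(scen_id[sel], levels = scenarios)
      wts <- epanechnikov(dist[sel], max(dist[sel]) * (1 + 1e-9))
      fit <- nnet::multinom(scenario ~ ., data = df, weights = wts,
                            trace = FALSE, maxit = 500)
      nd <- as.data.frame(t(zobs))
      pr <- as.numeric(stats::predict(fit, nd, type = "probs"))
      if (length(pr) == 1) pr <- c(1 - pr, pr)
      ci <- multinom_ci(fit, nd, levels = scenarios)
      tibble(scenario = scenarios, method = "logistic", probability = pr,
             lower = ci$lower, upper = ci$upper)
    }, error = function(e) {
      warning("logistic regression failed (", conditionMessage(e),
              "); falling back to the direct estimate")
      mutate(direct, method = "logistic")
    })

    probs <- bind_rows(direct, logistic)
    # the logistic estimate is the sharper of the two at moderate
    # simulation counts; fall back to the direct composition if it failed
    winner <- scenarios[which.max(logistic$probability)]

    # parameter adjustment for the winning scenario
    win_rows <- which(scen_id == winner)
    win_sel <- win_rows[order(dist[win_rows])][
      seq_len(max(100, ceiling(tolerance * length(win_rows))))]
    posterior <- adjust_parameters(draws[[match(winner, scenarios)]][
      win_sel - (match(winner, scenarios) - 1) * n_sims, ],
      Z[win_sel, , drop = FALSE], zobs, dist[win_sel])

    structure(list(model_probs = probs, winner = winner,
                   posterior = posterior,
                   quantiles = attr(posterior, "quantiles"),
                   summaries = tab, scenario_id = scen_id,
                   standardization = sds, observed = observed,
                   n_sims = n_sims, tolerance = tolerance,
                   n_direct = n_direct),
              class = "abc_result")
  })
}

# delta-method CI for multinomial-logit probabilities at one point
multinom_ci <- function(fit, newdata, levels) {
  X <- stats::model.matrix(~ ., data = newdata)
  B <- stats::coef(fit)
  if (is.null(dim(B))) B <- matrix(B, nrow = 1)
  eta <- c(0, as.vector(B %*% t(X)))
  p <- exp(eta) / sum(exp(eta))
  V <- tryCatch(stats::vcov(fit), error = function(e) NULL)
  if (is.null(V)) return(tibble(lower = rep(NA_real_, length(levels)),
                                upper = rep(NA_real_, length(levels))))
  K <- length(eta)
  # gradient of p_k wrt the stacked coefficients (rowwise per outcome)
  grad <- matrix(0, K, length(as.vector(t(B))))
  nb <- ncol(X)
  for (k in seq_len(K)) {
    for (j in 2:K) {
      dpk_detaj <- p[k] * ((k == j) - p[j])
      grad[k, ((j - 2) * nb + 1):((j - 1) * nb)] <- dpk_detaj * as.vector(X)
    }
  }
  se <- sqrt(pmax(0, diag(grad %*% V %*% t(grad))))
  tibble(lower = pmax(0, p - 1.96 * se), upper = pmin(1, p + 1.96 * se))
}

#' @export
print.abc_result <- function(x, ...) {
  cat("<abc_result> winner: scenario ", x$winner, "\n", sep = "")
  print(as.data.frame(x$model_probs), row.names = FALSE)
  invisible(x)
}

#' @export
tidy.abc_result <- function(x, ...) x$model_probs

#' @export
glance.abc_result <- function(x, ...) {
  tibble(winner = x$winner, n_sims = x$n_sims, tolerance = x$tolerance,
         n_direct = x$n_direct)
}

#' PCA model checking for a fitted scenario
#'
#' Fits a PCA on the prior-predictive simulated summaries, projects the
#' observed vector and a set of posterior-predictive summaries, and flags
#' the fit when the observed point falls outside the 95% ellipse of the
#' posterior-predictive cloud on the first two components.
#'
#' @param result An [run_abc()] result.
#' @param design The [abc_design()] used for the run.
#' @param n_post Number of posterior-predictive simulations.
#' @param seed Optional seed.
#' @return List: `coords` tibble (PC1/PC2 for sims, posterior-predictive
#'   points and the observed vector), `outside` flag, `mahalanobis`
#'   distance of the observed point.
#' @export
model_check_pca <- function(result, design, n_post = 500, seed = NULL) {
  tab <- result$summaries
  sds <- apply(tab, 2, sd)
  if (all(sds == 0)) stop("all summaries constant; PCA undefined")
  keep <- sds > 0
  pc <- prcomp(tab[, keep, drop = FALSE], center = TRUE, scale. = TRUE)
  post <- result$posterior
  idx <- with_seed(seed, sample.int(nrow(post), n_post, replace = TRUE))
  pp <- simulate_summaries(result$winner, post[idx, , drop = FALSE], design)
  proj <- function(m) stats::predict(pc, m[, keep, drop = FALSE])[, 1:2,
                                                                  drop = FALSE]
  sims2 <- proj(tab)
  pp2 <- proj(pp)
  obs2 <- proj(matrix(result$observed[colnames(tab)], 1,
                      dimnames = list(NULL, colnames(tab))))
  mu <- colMeans(pp2)
  S <- cov(pp2)
  md <- mahalanobis(obs2, mu, S)
  coords <- bind_rows(
    as_tibble(sims2) %>% mutate(what = "prior-predictive"),
    as_tibble(pp2) %>% mutate(what = "posterior-predictive"),
    as_tibble(obs2) %>% mutate(what = "observed"))
  list(coords = coords, outside = md > stats::qchisq(0.95, 2),
       mahalanobis = unname(md))
}
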