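#' Individual-by-locus haplotype-allele matrix
#'
#' Collapses each locus to haplotypes and codes every individual by its
#' haplotype id — the form in which sequence data enter model-based
#' clustering (one "allele" per locus per haploid individual).
#'
#' @param dataset A [multilocus_dataset()].
#' @param genome Restrict to `"nuclear"` or `"chloroplast"` loci.
#' @return Integer matrix (individuals x loci) with haplotype ids 1..J_l.
#' @export
haplotype_allele_matrix <- function(dataset, genome = NULL) {
  loci <- dataset$loci
  if (!is.null(genome)) loci <- loci[dataset$genome[names(loci)] == genome]
  inds <- dataset$pop_map$individual
  X <- vapply(loci, function(lc) {
    asg <- attr(collapse_haplotypes(lc), "assignment")
    as.integer(sub("^H", "", asg[inds]))
  }, integer(length(inds)))
  rownames(X) <- inds
  X
}

rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), alpha)
  if (sum(g) == 0) g[sample.int(length(g), 1)] <- 1
  g / sum(g)
}

#' Bayesian admixture clustering by Gibbs sampling
#'
#' Fits the standard admixture model for haploid multilocus data: each
#' individual has ancestry proportions `Q[i, ]` (Dirichlet(alpha) prior,
#' alpha updated by a Metropolis step with uniform prior on (0, 10]); each
#' cluster has per-locus allele frequencies with a symmetric
#' Dirichlet(lambda) prior. Returns posterior means and the model
#' log-likelihood estimate used for choosing K.
#'
#' @param X Integer matrix (individuals x loci) of haplotype/allele ids,
#'   e.g. from [haplotype_allele_matrix()].
#' @param K Number of clusters.
#' @param burnin,iters MCMC sweeps to discard / retain. Defaults are
#'   test-scale; increase (e.g. 1e5 / 1e6) for production runs.
#' @param lambda Dirichlet parameter of the allele-frequency prior.
#' @param alpha Initial ancestry concentration parameter.
#' @param update_alpha Update alpha by Metropolis (default TRUE).
#' @param seed Optional seed.
#' @return Object of class `admixture_fit`: `Q` (posterior-mean ancestry),
#'   `P` (list per locus of posterior-mean allele frequencies), `K`,
#'   `lnPD` (mean log-likelihood minus half its variance, the usual model
#'   evidence proxy), `loglik_mean`, `loglik_var`, `alpha`, `seed`.
#' @export
admixture_mcmc <- function(X, K, burnin = 5000, iters = 20000, lambda = 1,
                           alpha = 1, update_alpha = TRUE, seed = NULL) {
  N <- nrow(X)
  Lc <- ncol(X)
  if (K < 1) stop("K must be >= 1")
  if (K > N) stop("K larger than the number of individuals")
  J <- apply(X, 2, max)
  poly <- J > 1
  if (K > 1 && !any(poly)) {
    warning("all loci monomorphic; ancestry is unidentifiable (uniform Q)")
    Q <- matrix(1 / K, N, K, dimnames = list(rownames(X), NULL))
    P <- purrr::map(seq_len(Lc), ~ matrix(1, K, 1))
    ll <- 0
    return(structure(list(Q = Q, P = P, K = K, lnPD = ll, loglik_mean = ll,
                          loglik_var = 0, alpha = alpha, seed = seed),
                     class = "admixture_fit"))
  }
  if (K == 1) {
    # exact: Q is a column of ones; lnPD is the multinomial log-likelihood
    # at the maximum-likelihood allele frequencies
    P <- purrr::map(seq_len(Lc), function(l) {
      t(as.matrix(tabulate(X[, l], J[l]) / N))
    })
    ll <- sum(vapply(seq_len(Lc), function(l)
      sum(log(P[[l]][1, X[, l]])), numeric(1)))
    Q <- matrix(1, N, 1, dimnames = list(rownames(X), NULL))
    return(structure(list(Q = Q, P = P, K = 1L, lnPD = ll, loglik_mean = ll,
                          loglik_var = 0, alpha = alpha, seed = seed),
                     class = "admixture_fit"))
  }

  run <- function() {
    Z <- matrix(sample.int(K, N * Lc, replace = TRUE), N, Lc)
    Q <- matrix(1 / K, N, K)
    P <- purrr::map(seq_len(Lc), ~ matrix(1 / J[.x], K, J[.x]))
    a <- alpha
    Qsum <- matrix(0, N, K)
    Psum <- purrr::map(seq_len(Lc), ~ matrix(0, K, J[.x]))
    lls <- numeric(iters)
    kept <- 0
    total <- burnin + iters
    for (sweep in seq_len(total)) {
      # allele frequencies
      for (l in seq_len(Lc)) {
        cnt <- matrix(tabulate((X[, l] - 1L) * K + Z[, l], K * J[l]), K, J[l])
        P[[l]] <- t(apply(lambda + cnt, 1, rdirichlet1))
        if (J[l] == 1) P[[l]] <- matrix(1, K, 1)
      }
      # ancestry proportions
      nik <- vapply(seq_len(K), function(k) rowSums(Z == k), numeric(N))
      Q <- t(apply(a + nik, 1, rdirichlet1))
      # latent origins
      for (l in seq_len(Lc)) {
        W <- Q * t(P[[l]])[X[, l], , drop = FALSE]
        cs <- W
        for (k in 2:K) cs[, k] <- cs[, k - 1] + W[, k]
        u <- runif(N) * cs[, K]
        znew <- rep(1L, N)
        for (k in 1:(K - 1)) znew <- znew + (u > cs[, k])
        Z[, l] <- znew
      }
      # alpha Metropolis step
      if (update_alpha) {
        ap <- a + rnorm(1, 0, 0.05)
        if (ap > 0 && ap <= 10) {
          lp <- function(al) N * (lgamma(K * al) - K * lgamma(al)) +
            (al - 1) * sum(log(pmax(Q, 1e-300)))
          if (log(runif(1)) < lp(ap) - lp(a)) a <- ap
        }
      }
      if (sweep > burnin) {
        kept <- kept + 1
        Qsum <- Qsum + Q
        for (l in seq_len(Lc)) Psum[[l]] <- Psum[[l]] + P[[l]]
        lls[kept] <- sum(vapply(seq_len(Lc), function(l)
          sum(log(rowSums(Q * t(P[[l]])[X[, l], , drop = FALSE]))),
          numeric(1)))
      }
    }
    Qm <- Qsum / kept
    rownames(Qm) <- rownames(X)
    list(Q = Qm, P = purrr::map(Psum, ~ .x / kept), a = a,
         llm = mean(lls), llv = var(lls))
  }
  r <- with_seed(seed, run())
  structure(list(Q = r$Q, P = r$P, K = as.integer(K),
                 lnPD = r$llm - r$llv / 2, loglik_mean = r$llm,
                 loglik_var = r$llv, alpha = r$a, seed = seed),
            class = "admixture_fit")
}

#' @export
print.admixture_fit <- function(x, ...) {
  cat("<admixture_fit> K = ", x$K, ", ln P(D) ~ ", round(x$lnPD, 2),
      "\n", sep = "")
  invisible(x)
}

#' @export
tidy.admixture_fit <- function(x, ...) {
  as_tibble(x$Q, .name_repair = ~ paste0("Q", seq_len(x$K))) %>%
    mutate(individual = rownames(x$Q), .before = 1)
}

#' @export
glance.admixture_fit <- function(x, ...) {
  tibble(K = x$K, lnPD = x$lnPD, loglik_mean = x$loglik_mean,
         loglik_var = x$loglik_var, alpha = x$alpha)
}

# greedy column matching of Q to a reference (CLUMPP-style)
align_q <- function(Q, ref) {
  K <- ncol(Q)
  perm <- integer(K)
  used <- logical(K)
  for (k in seq_len(K)) {
    costs <- vapply(seq_len(K), function(j)
      if (used[j]) Inf else sum(abs(ref[, k] - Q[, j])), numeric(1))
    perm[k] <- which.min(costs)
    used[perm[k]] <- TRUE
  }
  Q[, perm, drop = FALSE]
}

#' Replicated clustering over a range of K
#'
#' @param X Haplotype-allele matrix.
#' @param k_range Integer vector of K values.
#' @param n_reps Replicate runs per K.
#' @param seed Seed (replicate seeds are derived from it).
#' @param ... Passed to [admixture_mcmc()].
#' @return List of `admixture_fit` objects (class `admixture_runs`).
#' @export
cluster_k_profile <- function(X, k_range = 1:5, n_reps = 3, seed = 1, ...) {
  runs <- purrr::flatten(purrr::map(k_range, function(K)
    purrr::map(seq_len(n_reps), function(r)
      admixture_mcmc(X, K, seed = seed + 1000L * K + r, ...))))
  structure(runs, class = "admixture_runs")
}

#' Evanno delta-K table
#'
#' Per-K mean and standard deviation of the log-likelihood estimate over
#' replicate runs, and the Evanno second-difference statistic
#' `deltaK = |L(K+1) - 2 L(K) + L(K-1)| / sd(L(K))` (undefined at the
#' endpoints of the K range; infinite when sd is zero).
#'
#' @param runs A list of [admixture_mcmc()] fits covering >= 3 consecutive
#'   K values with >= 2 replicates each (e.g. [cluster_k_profile()]).
#' @return Tibble with columns `K`, `mean_lnPD`, `sd_lnPD`, `delta_K`.
#' @export
evanno_delta_k <- function(runs) {
  tb <- bind_rows(purrr::map(runs, glance)) %>%
    group_by(.data$K) %>%
    summarise(mean_lnPD = mean(.data$lnPD), sd_lnPD = sd(.data$lnPD),
              n_reps = dplyr::n()) %>%
    arrange(.data$K)
  if (nrow(tb) < 3) stop("need at least 3 consecutive K values")
  if (any(diff(tb$K) != 1)) stop("K values must be consecutive")
  m <- tb$mean_lnPD
  dk <- rep(NA_real_, nrow(tb))
  for (i in 2:(nrow(tb) - 1)) {
    num <- abs(m[i + 1] - 2 * m[i] + m[i - 1])
    dk[i] <- if (tb$sd_lnPD[i] == 0 || is.na(tb$sd_lnPD[i])) Inf
             else num / tb$sd_lnPD[i]
  }
  mutate(tb, delta_K = dk)
}
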