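#' Mismatch distribution
#'
#' Histogram of the number of pairwise nucleotide differences between all
#' sequence pairs (concatenated loci), optionally restricted to the
#' populations of one group.
#'
#' @param dataset A [multilocus_dataset()].
#' @param group Optional group id (or vector of population ids via
#'   `populations`) to subset individuals.
#' @param populations Optional character vector of population ids.
#' @param genome Restrict to `"nuclear"` (default) or `"chloroplast"` loci.
#' @return Tibble with columns `differences` (0..max) and `count`; class
#'   `mismatch_histogram`. The counts sum to n(n-1)/2.
#' @export
mismatch_distribution <- function(dataset, group = NULL, populations = NULL,
                                  genome = "nuclear") {
  pm <- dataset$pop_map
  keep <- pm$individual
  if (!is.null(group)) keep <- pm$individual[pm$group %in% group]
  if (!is.null(populations)) keep <- pm$individual[pm$population %in% populations]
  if (length(keep) < 2) stop("need at least 2 individuals")
  loci <- dataset$loci
  if (!is.null(genome)) loci <- loci[dataset$genome[names(loci)] == genome]
  n <- length(keep)
  d <- matrix(0, n, n)
  for (lc in loci) {
    mat <- unclass(lc)[keep, , drop = FALSE]
    cols <- analyzable_columns(unclass(lc))
    for (j in cols) {
      if (dplyr::n_distinct(mat[, j]) > 1L) d <- d + outer(mat[, j], mat[, j], "!=")
    }
  }
  diffs <- d[upper.tri(d)]
  tb <- tibble(differences = 0:max(diffs),
               count = as.integer(tabulate(diffs + 1L, max(diffs) + 1L)))
  class(tb) <- c("mismatch_histogram", class(tb))
  tb
}

#' Expected mismatch frequencies under sudden demographic expansion
#'
#' Closed-form distribution of pairwise differences for a population that
#' grew instantaneously from scaled size `theta0` to `theta1` at scaled
#' time `tau` (units of 1/(2u)) before present:
#' \deqn{F_j = \hat F_j(\theta_1) P(\Gamma_{j+1} \le \beta\tau) +
#'   e^{-\beta\tau} \sum_{i=0}^j \frac{\tau^i}{i!} \hat F_{j-i}(\theta_0)}
#' with \eqn{\hat F_j(\theta) = \theta^j/(\theta+1)^{j+1}} the stationary
#' geometric and \eqn{\beta = (\theta_1+1)/\theta_1}.
#'
#' @param j Integer vector of difference classes.
#' @param tau Scaled expansion time.
#' @param theta0,theta1 Pre- and post-expansion scaled sizes.
#' @return Probabilities for each class in `j`.
#' @export
expected_mismatch <- function(j, tau, theta0, theta1) {
  stopifnot(tau >= 0, theta0 >= 0, theta1 > 0)
  beta <- (theta1 + 1) / theta1
  geom <- function(jj, th) if (th == 0) as.numeric(jj == 0)
                           else exp(jj * log(th) - (jj + 1) * log(th + 1))
  vapply(j, function(jj) {
    recent <- geom(jj, theta1) * pgamma(beta * tau, jj + 1)
    if (tau == 0) return(recent + exp(-beta * tau) * geom(jj, theta0))
    i <- 0:jj
    # Poisson-style weights in log space to avoid overflow at large tau
    lw <- -beta * tau + i * log(tau) - lgamma(i + 1)
    recent + sum(exp(lw) * geom(jj - i, theta0))
  }, numeric(1))
}

#' Fit the sudden-expansion model to a mismatch distribution
#'
#' Least-squares fit of the expected mismatch frequencies to the observed
#' relative frequencies, minimizing the sum of squared deviations (SSD)
#' with bounded Nelder-Mead over multiple starts. `theta1` is capped at
#' 99999; fits at the cap are flagged.
#'
#' @param histogram A [mismatch_distribution()] result (or tibble with
#'   `differences`, `count`).
#' @param extra_classes Fit range extends this many classes past the
#'   largest observed difference (default 5).
#' @return Object of class `mismatch_fit`: `tau`, `theta0`, `theta1`,
#'   `ssd`, `at_cap`, the observed histogram and fitted frequencies.
#' @export
fit_sudden_expansion <- function(histogram, extra_classes = 5) {
  if (!nrow(histogram)) stop("empty histogram")
  n_pairs <- sum(histogram$count)
  jmax <- max(histogram$differences) + extra_classes
  obs <- numeric(jmax + 1)
  obs[histogram$differences + 1] <- histogram$count / n_pairs
  if (all(histogram$count[histogram$differences > 0] == 0)) {
    fit <- list(tau = 0, theta0 = 0, theta1 = 1e-6, ssd = 0, at_cap = FALSE)
    return(structure(c(fit, list(observed = histogram,
                                 expected = expected_mismatch(0:jmax, 0, 0, 1e-6),
                                 n_pairs = n_pairs)),
                     class = "mismatch_fit"))
  }
  cap <- 99999
  ssd_of <- function(par) {
    tau <- exp(par[1]); th0 <- exp(par[2]); th1 <- exp(par[3])
    if (th1 > cap) th1 <- cap
    sum((expected_mismatch(0:jmax, tau, th0, th1) - obs)^2)
  }
  mean_d <- sum((0:jmax) * obs)
  starts <- list(c(log(max(mean_d, .5)), log(.1), log(max(10 * mean_d, 5))),
                 c(log(max(mean_d / 2, .2)), log(.01), log(cap / 10)),
                 c(log(max(2 * mean_d, 1)), log(1), log(max(mean_d, 2))),
                 c(log(.5), log(.5), log(50)))
  best <- NULL
  for (s in starts) {
    o <- tryCatch(optim(s, ssd_of, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-12)),
                  error = function(e) NULL)
    if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
  }
  if (is.null(best)) stop("sudden-expansion fit failed to converge from any start")
  tau <- exp(best$par[1]); th0 <- exp(best$par[2])
  th1 <- min(exp(best$par[3]), cap)
  structure(list(tau = tau, theta0 = th0, theta1 = th1, ssd = best$value,
                 at_cap = th1 >= cap * 0.999, observed = histogram,
                 expected = expected_mismatch(0:jmax, tau, th0, th1),
                 n_pairs = n_pairs),
            class = "mismatch_fit")
}

#' @export
print.mismatch_fit <- function(x, ...) {
  cat("<mismatch_fit> tau = ", signif(x$tau, 4), ", theta0 = ",
      signif(x$theta0, 4), ", theta1 = ", signif(x$theta1, 5),
      if (x$at_cap) " (at cap)", ", SSD = ", signif(x$ssd, 4), "\n", sep = "")
  invisible(x)
}

#' @export
glance.mismatch_fit <- function(x, ...) {
  tibble(tau = x$tau, theta0 = x$theta0, theta1 = x$theta1, ssd = x$ssd,
         at_cap = x$at_cap)
}

#' Harpending's raggedness index
#'
#' \eqn{r = \sum_{i=1}^{d+1} (x_i - x_{i-1})^2} over relative frequencies
#' with the convention \eqn{x_{d+1} = 0}.
#'
#' @param histogram A [mismatch_distribution()] result.
#' @return The raggedness index.
#' @export
raggedness <- function(histogram) {
  x <- histogram$count / sum(histogram$count)
  sum(diff(c(0, x, 0))^2)
}

# simulate a mismatch histogram of n sequences under the fitted expansion
# model (single locus, scale-free: u = 1/2 so theta = N and tau = t)
simulate_expansion_mismatch <- function(n, tau, theta0, theta1) {
  scn <- demographic_scenario(c(A = max(theta1, 1e-8) / 2))
  if (tau > 0) scn <- ev_resize(scn, tau, "A", max(theta0, 1e-8) / 2)
  g <- simulate_genealogies(scn, c(A = n), n_loci = 1)
  m <- add_mutations(g, tibble(locus = "sim", length = 1e9, mu = 0.5))
  der <- m[[1]]$derived
  d <- matrix(0L, n, n)
  for (j in seq_len(ncol(der))) d <- d + outer(der[, j], der[, j], "!=")
  diffs <- d[upper.tri(d)]
  tibble(differences = 0:max(diffs, 0),
         count = as.integer(tabulate(diffs + 1L, max(diffs, 0) + 1L)))
}

#' Parametric-bootstrap p-values for the expansion fit
#'
#' Simulates samples under the fitted sudden-expansion model, refits each,
#' and reports the proportion of bootstrap replicates with a larger SSD
#' than observed (and likewise for the raggedness index).
#'
#' @param fit A [fit_sudden_expansion()] result.
#' @param n Number of sequences behind the observed histogram.
#' @param n_boot Bootstrap replicates.
#' @param seed Optional seed.
#' @return Tibble with `p_ssd`, `p_rag` and the replicate statistics as
#'   attributes.
#' @export
ssd_pvalue <- function(fit, n, n_boot = 1000, seed = NULL) {
  obs_rag <- raggedness(fit$observed)
  res <- with_seed(seed, {
    ssd_b <- rag_b <- rep(NA_real_, n_boot)
    fails <- 0
    for (b in seq_len(n_boot)) {
      h <- simulate_expansion_mismatch(n, fit$tau, fit$theta0, fit$theta1)
      fb <- tryCatch(fit_sudden_expansion(h), error = function(e) NULL)
      if (is.null(fb)) { fails <- fails + 1; next }
      ssd_b[b] <- fb$ssd
      rag_b[b] <- raggedness(h)
    }
    if (fails > 0.1 * n_boot) stop("more than 10% of bootstrap refits failed")
    list(ssd_b = ssd_b, rag_b = rag_b)
  })
  out <- tibble(p_ssd = mean(res$ssd_b >= fit$ssd, na.rm = TRUE),
                p_rag = mean(res$rag_b >= obs_rag, na.rm = TRUE),
                n_boot = n_boot)
  attr(out, "ssd_boot") <- res$ssd_b
  attr(out, "rag_boot") <- res$rag_b
  out
}

#' Mismatch-expansion table for the standard group partitions
#'
#' Runs the mismatch analysis for a list of group subsets (by default: all
#' populations; each group; and the complement of the largest group) and
#' reports the fitted parameters with bootstrap p-values.
#'
#' @param dataset A [multilocus_dataset()].
#' @param subsets Named list of population-id vectors; default uses all
#'   populations plus each group in the population map.
#' @param n_boot Bootstrap replicates per subset.
#' @param seed Optional seed.
#' @return Tibble shaped like a demographic-expansion table: one row per
#'   subset with `theta0`, `theta1`, `ssd`, `p_ssd`, `rag`, `p_rag`.
#' @export
mismatch_expansion_table <- function(dataset, subsets = NULL, n_boot = 200,
                                     seed = NULL) {
  pm <- dataset$pop_map
  if (is.null(subsets)) {
    subsets <- c(list(all = unique(pm$population)),
                 purrr::map(split(pm$population, pm$group), unique))
  }
  with_seed(seed, bind_rows(purrr::imap(subsets, function(popv, nm) {
    inds <- pm$individual[pm$population %in% popv]
    if (length(inds) < 3)
      return(tibble(subset = nm, n = length(inds), theta0 = NA, theta1 = NA,
                    tau = NA, ssd = NA, p_ssd = NA, rag = NA, p_rag = NA))
    h <- mismatch_distribution(dataset, populations = popv)
    if (max(h$differences[h$count > 0]) == 0)
      return(tibble(subset = nm, n = length(inds), theta0 = NA, theta1 = NA,
                    tau = NA, ssd = NA, p_ssd = NA, rag = NA, p_rag = NA))
    fit <- fit_sudden_expansion(h)
    pv <- ssd_pvalue(fit, length(inds), n_boot = n_boot)
    tibble(subset = nm, n = length(inds), theta0 = fit$theta0,
           theta1 = fit$theta1, tau = fit$tau, ssd = fit$ssd,
           p_ssd = pv$p_ssd, rag = raggedness(h), p_rag = pv$p_rag)
  })))
}
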