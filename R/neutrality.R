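ln_harmonic <- function(n, p = 1) sum(1 / seq_len(n - 1)^p)

# sample-configuration summaries shared by the neutrality statistics
sfs_summary <- function(locus) {
  mat <- unclass(locus)
  n <- nrow(mat)
  cols <- analyzable_columns(mat)
  seg <- cols[apply(mat[, cols, drop = FALSE], 2, dplyr::n_distinct) > 1L]
  minor <- vapply(seg, function(j) {
    cnt <- sort(table(mat[, j]), decreasing = TRUE)
    sum(cnt[-1])  # non-major allele count (folded)
  }, numeric(1))
  singletons <- sum(vapply(seg, function(j) {
    any(table(mat[, j]) == 1L)
  }, logical(1)))
  list(n = n, S = length(seg), seg = seg,
       pi_abs = mean_pairwise_differences(mat, cols),
       eta_s = singletons,
       K = nrow(collapse_haplotypes(locus_like(mat))))
}

tajima_constants <- function(n) {
  a1 <- ln_harmonic(n)
  a2 <- ln_harmonic(n, 2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

tajima_d_from <- function(n, S, pi_abs) {
  if (S < 1) return(NA_real_)
  k <- tajima_constants(n)
  (pi_abs - S / k$a1) / sqrt(k$e1 * S + k$e2 * S * (S - 1))
}

fu_li_constants <- function(n) {
  a <- ln_harmonic(n)
  b <- ln_harmonic(n, 2)
  an1 <- a + 1 / n
  cn <- 2 * (n * a - 2 * (n - 1)) / ((n - 1) * (n - 2))
  dn <- cn + (n - 2) / (n - 1)^2 +
    2 / (n - 1) * (1.5 - (2 * an1 - 3) / (n - 2) - 1 / n)
  vD <- ((n / (n - 1))^2 * b + a^2 * dn -
           2 * (n * a * (a + 1)) / (n - 1)^2) / (a^2 + b)
  uD <- n / (n - 1) * (a - n / (n - 1)) - vD
  vF <- ((2 * n^3 + 110 * n^2 - 255 * n + 153) / (9 * n^2 * (n - 1)) +
           2 * (n - 1) * a / n^2 - 8 * b / n) / (a^2 + b)
  uF <- ((4 * n^2 + 19 * n + 3 - 12 * (n + 1) * an1) /
           (3 * n * (n - 1))) / a - vF
  list(a = a, b = b, uD = uD, vD = vD, uF = uF, vF = vF)
}

fu_li_from <- function(n, S, pi_abs, eta_s) {
  if (S < 1) return(list(Dstar = NA_real_, Fstar = NA_real_))
  k <- fu_li_constants(n)
  Dstar <- (n / (n - 1) * S - k$a * eta_s) / sqrt(k$uD * S + k$vD * S^2)
  Fstar <- (pi_abs - (n - 1) / n * eta_s) / sqrt(k$uF * S + k$vF * S^2)
  list(Dstar = Dstar, Fstar = Fstar)
}

fay_wu_from <- function(n, derived_counts, pi_abs) {
  if (!length(derived_counts)) return(NA_real_)
  theta_H <- sum(2 * derived_counts^2) / (n * (n - 1))
  pi_abs - theta_H
}

#' Tajima's D
#'
#' \eqn{D = (\pi - S/a_1) / \sqrt{e_1 S + e_2 S(S-1)}} with the 1989
#' constants; `NA` when there is no polymorphism.
#'
#' @param locus A [locus_alignment()].
#' @return The statistic (dimensionless), `NA` when S = 0.
#' @export
tajimas_d <- function(locus) {
  s <- sfs_summary(locus)
  tajima_d_from(s$n, s$S, s$pi_abs)
}

#' Fu and Li's D* and F* (no-outgroup tests)
#'
#' Contrast the number of singleton mutations with the total number of
#' segregating sites (D*) or with nucleotide diversity (F*), using the
#' corrected variance constants in common use.
#'
#' @param locus A [locus_alignment()].
#' @return Named list with `Dstar` and `Fstar` (`NA` when S = 0).
#' @export
fu_li_star_tests <- function(locus) {
  s <- sfs_summary(locus)
  fu_li_from(s$n, s$S, s$pi_abs, s$eta_s)
}

#' Fay and Wu's H
#'
#' \eqn{H = \pi - \theta_H} with
#' \eqn{\theta_H = \sum_i 2 S_i i^2 / (n(n-1))} over derived-allele counts,
#' polarized against a designated outgroup sequence. Sites where the
#' outgroup carries a gap, `N`, or a third state are excluded.
#'
#' @param locus A [locus_alignment()].
#' @param outgroup Outgroup sequence: a single aligned string, or the name
#'   of a row of `locus` to treat as outgroup (that row is then dropped
#'   from the ingroup).
#' @return The statistic (`NA` when no polarizable polymorphic site).
#' @export
fay_wu_h <- function(locus, outgroup) {
  mat <- unclass(locus)
  if (length(outgroup) == 1L && outgroup %in% rownames(mat)) {
    og <- mat[outgroup, ]
    mat <- mat[setdiff(rownames(mat), outgroup), , drop = FALSE]
  } else {
    og <- strsplit(toupper(outgroup), "")[[1]]
    if (length(og) != ncol(mat)) stop("outgroup is not alignable (length mismatch)")
  }
  n <- nrow(mat)
  cols <- analyzable_columns(mat)
  seg <- cols[apply(mat[, cols, drop = FALSE], 2, dplyr::n_distinct) > 1L]
  usable <- logical(length(seg))
  derived <- numeric(length(seg))
  for (i in seq_along(seg)) {
    j <- seg[i]
    alleles <- unique(mat[, j])
    if (og[j] %in% alleles) {
      usable[i] <- TRUE
      derived[i] <- sum(mat[, j] != og[j])
    }
  }
  if (any(!usable))
    message(sum(!usable), " segregating site(s) excluded: outgroup gap, ",
            "ambiguity or third state")
  keep <- seg[usable]
  if (!length(keep)) return(NA_real_)
  pi_abs <- mean_pairwise_differences(mat, keep)
  fay_wu_from(n, derived[usable], pi_abs)
}

# log unsigned Stirling numbers of the first kind, row n (k = 1..n)
log_stirling_row <- function(n) {
  row <- 0  # row 1: |s(1,1)| = 1
  if (n == 1) return(row)
  for (m in 1:(n - 1)) {
    # row for m+1 from row for m: |s(m+1,k)| = m*|s(m,k)| + |s(m,k-1)|
    new <- numeric(m + 1)
    prev <- c(row, -Inf)
    shifted <- c(-Inf, row)
    for (k in seq_len(m + 1)) {
      x <- log(m) + prev[k]
      y <- shifted[k]
      new[k] <- if (is.infinite(x)) y else if (is.infinite(y)) x
                else max(x, y) + log1p(exp(-abs(x - y)))
    }
    row <- new
  }
  row
}

#' Ewens distribution of the number of alleles
#'
#' `P(K = k)` for a sample of `n` under the Ewens sampling formula with
#' scaled mutation rate `theta`.
#'
#' @param n Sample size.
#' @param theta Scaled mutation rate (mean pairwise differences).
#' @return Numeric vector of probabilities for k = 1..n.
#' @export
ewens_k_distribution <- function(n, theta) {
  ls <- log_stirling_row(n)
  lp <- ls + seq_len(n) * log(theta) - sum(log(theta + 0:(n - 1)))
  exp(lp)
}

#' Fu's Fs
#'
#' \eqn{F_s = \ln(S' / (1 - S'))} with
#' \eqn{S' = P(K \ge k_{obs} \mid \theta = \hat\pi)} from the Ewens
#' sampling distribution; large negative values indicate an excess of
#' haplotypes, as produced by recent demographic expansion.
#'
#' @param locus A [locus_alignment()].
#' @return The statistic (`NA` when there is no polymorphism or a single
#'   haplotype).
#' @export
fu_fs <- function(locus) {
  s <- sfs_summary(locus)
  fu_fs_from(s$n, s$K, s$pi_abs)
}

fu_fs_from <- function(n, K, pi_abs) {
  if (pi_abs <= 0 || K <= 1) return(NA_real_)
  p <- ewens_k_distribution(n, pi_abs)
  Sp <- sum(p[K:n])
  Sp <- min(max(Sp, .Machine$double.xmin), 1 - 1e-15)
  log(Sp / (1 - Sp))
}

#' Fixed-S coalescent null distributions
#'
#' Simulates constant-size coalescent samples conditioned on exactly
#' `S` segregating sites (mutations placed multinomially by branch length)
#' and returns the derived-allele count of every site plus the haplotype
#' count per replicate.
#'
#' @param n Sample size.
#' @param S Number of segregating sites to condition on.
#' @param n_sims Number of replicates.
#' @param seed Optional seed.
#' @return List with `counts` (`n_sims` x `S` derived-allele counts) and
#'   `K` (haplotype count per replicate).
#' @export
simulate_fixed_s <- function(n, S, n_sims, seed = NULL) {
  stopifnot(n >= 2, S >= 1, n_sims >= 1)
  with_seed(seed, fixed_s_batch_cpp(as.integer(n), as.integer(S),
                                    as.integer(n_sims)))
}

null_statistics <- function(sim, n) {
  counts <- sim$counts
  S <- ncol(counts)
  pi_abs <- rowSums(counts * (n - counts)) / (n * (n - 1) / 2)
  eta_s <- rowSums(counts == 1L | counts == n - 1L)
  thetaH <- rowSums(2 * counts^2) / (n * (n - 1))
  kD <- tajima_constants(n)
  kF <- fu_li_constants(n)
  fs <- vapply(seq_len(nrow(counts)), function(r)
    fu_fs_from(n, sim$K[r], pi_abs[r]), numeric(1))
  tibble(
    D = (pi_abs - S / kD$a1) / sqrt(kD$e1 * S + kD$e2 * S * (S - 1)),
    Dstar = (n / (n - 1) * S - kF$a * eta_s) /
      sqrt(kF$uD * S + kF$vD * S^2),
    Fstar = (pi_abs - (n - 1) / n * eta_s) /
      sqrt(kF$uF * S + kF$vF * S^2),
    H = pi_abs - thetaH,
    Fs = fs)
}

#' Coalescent-simulation p-value for a neutrality statistic
#'
#' Compares an observed statistic with its null distribution from
#' constant-size coalescent samples conditioned on the observed number of
#' segregating sites. Two-tailed for D, D*, F*; lower-tailed for H and Fs.
#'
#' @param statistic One of `"D"`, `"Dstar"`, `"Fstar"`, `"H"`, `"Fs"`, or a
#'   function of (`derived_counts`, `n`, `K`) returning a scalar.
#' @param n Sample size.
#' @param S_obs Observed segregating sites to condition on.
#' @param observed Observed statistic value.
#' @param n_sims Number of null replicates (>= 100).
#' @param seed Optional seed.
#' @return The simulation p-value.
#' @export
simulate_null_pvalue <- function(statistic, n, S_obs, observed,
                                 n_sims = 10000, seed = NULL) {
  stopifnot(n_sims >= 100)
  sim <- simulate_fixed_s(n, S_obs, n_sims, seed)
  if (is.function(statistic)) {
    vals <- vapply(seq_len(n_sims), function(r)
      statistic(sim$counts[r, ], n, sim$K[r]), numeric(1))
    tail <- "two"
  } else {
    statistic <- match.arg(statistic, c("D", "Dstar", "Fstar", "H", "Fs"))
    vals <- null_statistics(sim, n)[[statistic]]
    tail <- if (statistic %in% c("H", "Fs")) "lower" else "two"
  }
  ok <- is.finite(vals)
  if (mean(ok) < 0.5) stop("statistic undefined in more than half of the null replicates")
  vals <- vals[ok]
  if (tail == "lower") return(mean(vals <= observed))
  min(1, 2 * min(mean(vals <= observed), mean(vals >= observed)))
}

#' Neutrality-test table for a multilocus dataset
#'
#' Computes Tajima's D, Fu and Li's D* and F*, Fu's Fs (and Fay and Wu's H
#' when an outgroup is supplied) per locus with fixed-S coalescent
#' p-values.
#'
#' @param dataset A [multilocus_dataset()].
#' @param genome Restrict to `"nuclear"` or `"chloroplast"` loci.
#' @param outgroup Optional named character vector of outgroup sequences
#'   per locus (for H).
#' @param n_sims Null replicates per locus.
#' @param seed Optional seed.
#' @return Tibble with one row per polymorphic locus: statistics and
#'   p-values; monomorphic loci are reported with `NA` statistics.
#' @export
neutrality_tests <- function(dataset, genome = NULL, outgroup = NULL,
                             n_sims = 10000, seed = NULL) {
  loci <- dataset$loci
  if (!is.null(genome)) loci <- loci[dataset$genome[names(loci)] == genome]
  with_seed(seed, bind_rows(purrr::map(loci, function(lc) {
    s <- sfs_summary(lc)
    if (s$S == 0)
      return(tibble(locus = locus_name(lc), n = s$n, S = 0L,
                    D = NA, Dstar = NA, Fstar = NA, Fs = NA,
                    p_D = NA, p_Dstar = NA, p_Fstar = NA, p_Fs = NA))
    fl <- fu_li_from(s$n, s$S, s$pi_abs, s$eta_s)
    D <- tajima_d_from(s$n, s$S, s$pi_abs)
    Fs <- fu_fs_from(s$n, s$K, s$pi_abs)
    sim <- simulate_fixed_s(s$n, s$S, n_sims)
    nulls <- null_statistics(sim, s$n)
    p2 <- function(v, obs) min(1, 2 * min(mean(v <= obs, na.rm = TRUE),
                                          mean(v >= obs, na.rm = TRUE)))
    tibble(locus = locus_name(lc), n = s$n, S = s$S,
           D = D, Dstar = fl$Dstar, Fstar = fl$Fstar, Fs = Fs,
           p_D = p2(nulls$D, D), p_Dstar = p2(nulls$Dstar, fl$Dstar),
           p_Fstar = p2(nulls$Fstar, fl$Fstar),
           p_Fs = if (is.na(Fs)) NA_real_
                  else mean(nulls$Fs <= Fs, na.rm = TRUE))
  })))
}
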