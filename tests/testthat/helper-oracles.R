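# Brute-force oracle implementations, coded straight from the defining
# formulas and independent of the package internals.

random_alignment <- function(n, L, n_var = 6, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  base <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  mat <- matrix(rep(base, each = n), n, L)
  var_cols <- sample.int(L, min(n_var, L))
  for (j in var_cols) {
    alt <- sample(setdiff(c("A", "C", "G", "T"), base[j]), 1)
    carriers <- sample.int(n, sample.int(n - 1, 1))
    mat[carriers, j] <- alt
  }
  rownames(mat) <- paste0("ind", seq_len(n))
  mat
}

oracle_S <- function(mat) {
  sum(apply(mat, 2, function(col) {
    col <- col[!(col %in% c("-", "N"))]
    length(unique(col)) > 1
  }) & !apply(mat, 2, function(col) any(col %in% c("-", "N"))))
}

oracle_pi <- function(mat) {
  keep <- !apply(mat, 2, function(col) any(col %in% c("-", "N")))
  sub <- mat[, keep, drop = FALSE]
  n <- nrow(sub)
  tot <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    tot <- tot + mean(sub[i, ] != sub[j, ])
  tot / (n * (n - 1) / 2)
}

oracle_pairdiff <- function(mat) {
  keep <- !apply(mat, 2, function(col) any(col %in% c("-", "N")))
  sub <- mat[, keep, drop = FALSE]
  n <- nrow(sub)
  tot <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    tot <- tot + sum(sub[i, ] != sub[j, ])
  tot / (n * (n - 1) / 2)
}

oracle_theta_w <- function(S, n, L) S / (sum(1 / (1:(n - 1))) * L)

oracle_hd <- function(counts) {
  n <- sum(counts)
  n / (n - 1) * (1 - sum((counts / n)^2))
}

# Rm by exhaustive search over subsets of incompatible (closed) intervals
oracle_rm <- function(mat) {
  keep <- !apply(mat, 2, function(col) any(col %in% c("-", "N")))
  cols <- which(keep)
  cols <- cols[vapply(cols, function(j) length(unique(mat[, j])) == 2,
                      logical(1))]
  iv <- list()
  if (length(cols) >= 2)
    for (a in 1:(length(cols) - 1)) for (b in (a + 1):length(cols))
      if (length(unique(paste(mat[, cols[a]], mat[, cols[b]]))) == 4)
        iv[[length(iv) + 1]] <- c(cols[a], cols[b])
  if (!length(iv)) return(0L)
  best <- 0L
  for (mask in 0:(2^length(iv) - 1)) {
    sel <- which(bitwAnd(mask, 2^(seq_along(iv) - 1)) > 0)
    if (length(sel) <= best) next
    ok <- TRUE
    if (length(sel) > 1)
      for (i in 1:(length(sel) - 1)) for (j in (i + 1):length(sel)) {
        x <- iv[[sel[i]]]; y <- iv[[sel[j]]]
        if (max(x[1], y[1]) <= min(x[2], y[2])) ok <- FALSE  # share a site
      }
    if (ok) best <- length(sel)
  }
  best
}

oracle_tajima_d <- function(mat) {
  n <- nrow(mat)
  S <- oracle_S(mat)
  if (S == 0) return(NA_real_)
  pi_abs <- oracle_pairdiff(mat)
  a1 <- sum(1 / (1:(n - 1)))
  a2 <- sum(1 / (1:(n - 1))^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (pi_abs - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

oracle_singletons <- function(mat) {
  keep <- !apply(mat, 2, function(col) any(col %in% c("-", "N")))
  sum(vapply(which(keep), function(j) {
    tb <- table(mat[, j])
    length(tb) > 1 && any(tb == 1)
  }, logical(1)))
}

oracle_fu_li <- function(mat) {
  n <- nrow(mat)
  S <- oracle_S(mat)
  if (S == 0) return(list(Dstar = NA, Fstar = NA))
  eta_s <- oracle_singletons(mat)
  pi_abs <- oracle_pairdiff(mat)
  a <- sum(1 / (1:(n - 1)))
  b <- sum(1 / (1:(n - 1))^2)
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
  list(Dstar = (n / (n - 1) * S - a * eta_s) / sqrt(uD * S + vD * S^2),
       Fstar = (pi_abs - (n - 1) / n * eta_s) / sqrt(uF * S + vF * S^2))
}

oracle_fay_wu_h <- function(derived_counts, n) {
  pi_abs <- sum(derived_counts * (n - derived_counts)) / choose(n, 2)
  pi_abs - sum(2 * derived_counts^2) / (n * (n - 1))
}

oracle_raggedness <- function(counts) {
  x <- counts / sum(counts)
  xs <- c(0, x, 0)
  sum((xs[-1] - xs[-length(xs)])^2)
}

# AMOVA sums of squares via centroid embedding (Huygens' theorem): encode
# each sequence one-hot scaled by 1/sqrt(2) so squared Euclidean distance
# equals the number of differing sites, then take squared deviations from
# centroids.
oracle_amova <- function(mat, pops, groups_of_pop) {
  n <- nrow(mat)
  emb <- NULL
  for (j in seq_len(ncol(mat))) {
    lev <- unique(mat[, j])
    if (length(lev) == 1) next
    oh <- outer(mat[, j], lev, "==") * 1 / sqrt(2)
    emb <- cbind(emb, oh)
  }
  if (is.null(emb)) emb <- matrix(0, n, 1)
  grp <- groups_of_pop[pops]
  ssd <- function(rows) {
    if (length(rows) < 2) return(0)
    sweep(emb[rows, , drop = FALSE], 2,
          colMeans(emb[rows, , drop = FALSE]))^2 |> sum()
  }
  ss_total <- ssd(seq_len(n))
  ss_wp <- sum(vapply(unique(pops), function(p) ssd(which(pops == p)),
                      numeric(1)))
  ss_wg <- sum(vapply(unique(grp), function(g) ssd(which(grp == g)),
                      numeric(1)))
  P <- length(unique(pops)); G <- length(unique(grp))
  n_p <- table(pops)[unique(pops)]
  n_g <- table(grp)[unique(grp)]
  g_of_p <- groups_of_pop[unique(pops)]
  sum_np2_by_g <- vapply(unique(grp), function(g)
    sum(n_p[g_of_p == g]^2) / n_g[[g]], numeric(1))
  n_c <- (n - sum(sum_np2_by_g)) / (P - G)
  n_b <- (sum(sum_np2_by_g) - sum(n_p^2) / n) / (G - 1)
  n_a <- (n - sum(n_g^2) / n) / (G - 1)
  msAG <- (ss_total - ss_wg) / (G - 1)
  msAP <- (ss_wg - ss_wp) / (P - G)
  msWP <- ss_wp / (n - P)
  sc <- msWP
  sb <- (msAP - sc) / n_c
  sa <- (msAG - sc - n_b * sb) / n_a
  c(a = unname(sa), b = unname(sb), c = unname(sc))
}

# Ewens sampling probabilities for small n by exhaustive enumeration of
# seatings under the Chinese-restaurant construction
oracle_ewens_k <- function(n, theta) {
  probs <- numeric(n)
  rec <- function(tables, i, p) {
    if (i > n) {
      k <- length(tables)
      probs[k] <<- probs[k] + p
      return(invisible())
    }
    denom <- theta + i - 1
    for (t in seq_along(tables)) rec(`[<-`(tables, t, tables[t] + 1), i + 1,
                                     p * tables[t] / denom)
    rec(c(tables, 1), i + 1, p * theta / denom)
  }
  rec(c(1), 2, 1)
  probs
}

oracle_ewens_k4 <- function(theta) oracle_ewens_k(4, theta)

oracle_fu_fs <- function(n, K, pi_abs) {
  p <- oracle_ewens_k(n, pi_abs)
  Sp <- sum(p[K:n])
  log(Sp / (1 - Sp))
}

make_locus <- function(mat, name = "toy") locus_alignment(mat, name = name)
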