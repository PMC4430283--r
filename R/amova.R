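#' Pairwise difference matrix over concatenated loci
#'
#' Number of differing mutational characters between every pair of
#' individuals (substitution columns plus recoded indel/inversion
#' characters), summed across loci.
#'
#' @param dataset A [multilocus_dataset()].
#' @param genome Restrict to `"nuclear"` or `"chloroplast"` loci.
#' @return Symmetric numeric matrix (individuals x individuals).
#' @export
pairwise_difference_matrix <- function(dataset, genome = NULL) {
  loci <- dataset$loci
  if (!is.null(genome)) loci <- loci[dataset$genome[names(loci)] == genome]
  inds <- dataset$pop_map$individual
  d <- matrix(0, length(inds), length(inds), dimnames = list(inds, inds))
  for (lc in loci) {
    rec <- recode_characters(lc, "recode")[inds, , drop = FALSE]
    for (j in seq_len(ncol(rec))) {
      diffm <- outer(rec[, j], rec[, j], "!=")
      d <- d + diffm
    }
  }
  d
}

amova_ss <- function(d2, pops, groups_of_pop) {
  # sums of squares from squared distances (Excoffier et al. 1992):
  # SS over a set = sum_{i<j in set} d2_ij / set size
  ss_of <- function(idx) {
    if (length(idx) < 2) return(0)
    sum(d2[idx, idx][upper.tri(d2[idx, idx])]) / length(idx)
  }
  N <- nrow(d2)
  pop_ids <- unique(pops)
  grp_ids <- unique(groups_of_pop[pop_ids])
  ss_total <- ss_of(seq_len(N))
  ss_wp <- sum(vapply(pop_ids, function(p) ss_of(which(pops == p)), numeric(1)))
  grp_of_ind <- groups_of_pop[pops]
  ss_wg <- sum(vapply(grp_ids, function(g)
    ss_of(which(grp_of_ind == g)), numeric(1)))
  list(AG = ss_total - ss_wg, APWG = ss_wg - ss_wp, WP = ss_wp,
       total = ss_total,
       df = c(AG = length(grp_ids) - 1,
              APWG = length(pop_ids) - length(grp_ids),
              WP = N - length(pop_ids)))
}

amova_components <- function(d2, pops, groups_of_pop) {
  ss <- amova_ss(d2, pops, groups_of_pop)
  N <- nrow(d2)
  pop_ids <- unique(pops)
  grp_of_ind <- groups_of_pop[pops]
  grp_ids <- unique(grp_of_ind)
  n_p <- vapply(pop_ids, function(p) sum(pops == p), numeric(1))
  g_of_p <- groups_of_pop[pop_ids]
  n_g <- vapply(grp_ids, function(g) sum(grp_of_ind == g), numeric(1))
  P <- length(pop_ids)
  G <- length(grp_ids)
  # expected-mean-square coefficients for unequal sizes
  sum_np2_by_g <- vapply(grp_ids, function(g)
    sum(n_p[g_of_p == g]^2) / n_g[names(n_g) == g], numeric(1))
  n_c <- (N - sum(sum_np2_by_g)) / (P - G)
  n_b <- (sum(sum_np2_by_g) - sum(n_p^2) / N) / (G - 1)
  n_a <- (N - sum(n_g^2) / N) / (G - 1)
  ms <- c(AG = unname(ss$AG / ss$df["AG"]),
          APWG = unname(ss$APWG / ss$df["APWG"]),
          WP = unname(ss$WP / ss$df["WP"]))
  sigma_c <- unname(ms["WP"])
  sigma_b <- unname((ms["APWG"] - sigma_c) / n_c)
  sigma_a <- unname((ms["AG"] - sigma_c - n_b * sigma_b) / n_a)
  total <- sigma_a + sigma_b + sigma_c
  list(sigma = c(a = sigma_a, b = sigma_b, c = sigma_c), ss = ss,
       phi = c(CT = sigma_a / total,
               SC = sigma_b / (sigma_b + sigma_c),
               ST = (sigma_a + sigma_b) / total))
}

#' Three-level analysis of molecular variance
#'
#' Partitions squared pairwise distances among groups, among populations
#' within groups, and within populations, with permutation tests for the
#' Phi statistics: individuals permuted among populations (Phi_ST),
#' individuals among populations within their group (Phi_SC), and whole
#' populations among groups (Phi_CT). Negative variance components are
#' reported as-is with a warning, the standard behaviour.
#'
#' @param dataset A [multilocus_dataset()], or a precomputed squared
#'   distance matrix (then `pop_map` must be supplied).
#' @param genome Restrict to `"nuclear"` or `"chloroplast"` loci.
#' @param n_perms Number of permutations (0 to skip testing).
#' @param seed Optional seed.
#' @param pop_map Population map when `dataset` is a distance matrix.
#' @return Object of class `amova_fit` with a tidy components table,
#'   Phi statistics and permutation p-values.
#' @export
amova_three_level <- function(dataset, genome = NULL, n_perms = 1000,
                              seed = NULL, pop_map = NULL) {
  if (inherits(dataset, "multilocus_dataset")) {
    d2 <- pairwise_difference_matrix(dataset, genome)
    pop_map <- dataset$pop_map
  } else d2 <- dataset
  pops <- setNames(pop_map$population, pop_map$individual)[rownames(d2)]
  gop <- pop_map %>% dplyr::distinct(.data$population, .data$group)
  groups_of_pop <- setNames(gop$group, gop$population)
  if (dplyr::n_distinct(groups_of_pop) < 2) stop("need at least 2 groups")
  if (min(table(pops)) < 1) stop("empty population")

  obs <- amova_components(d2, pops, groups_of_pop)
  if (any(obs$sigma < 0))
    warning("negative variance component; reported as-is")
  if (all(d2 == 0)) {
    phi <- c(CT = NA_real_, SC = NA_real_, ST = NA_real_)
    obs$phi <- phi
  }

  pvals <- c(CT = NA_real_, SC = NA_real_, ST = NA_real_)
  if (n_perms > 0 && !all(d2 == 0)) {
    pvals <- with_seed(seed, {
      N <- length(pops)
      hits <- c(CT = 0, SC = 0, ST = 0)
      ge <- function(a, b) is.finite(a) && is.finite(b) && a >= b - 1e-12
      for (b in seq_len(n_perms)) {
        # Phi_ST: individuals among populations (and groups)
        perm <- sample(N)
        st <- amova_components(d2, setNames(pops[perm], names(pops)),
                               groups_of_pop)
        if (ge(st$phi["ST"], obs$phi["ST"])) hits["ST"] <- hits["ST"] + 1
        # Phi_SC: individuals among populations within groups
        grp_of_ind <- groups_of_pop[pops]
        pops_sc <- pops
        for (g in unique(grp_of_ind)) {
          idx <- which(grp_of_ind == g)
          pops_sc[idx] <- pops[idx][sample(length(idx))]
        }
        sc <- amova_components(d2, pops_sc, groups_of_pop)
        if (ge(sc$phi["SC"], obs$phi["SC"])) hits["SC"] <- hits["SC"] + 1
        # Phi_CT: whole populations among groups
        ct <- amova_components(d2, pops, setNames(sample(groups_of_pop),
                                                  names(groups_of_pop)))
        if (ge(ct$phi["CT"], obs$phi["CT"])) hits["CT"] <- hits["CT"] + 1
      }
      p <- (hits + 1) / (n_perms + 1)
      p[!is.finite(obs$phi)] <- NA_real_
      p
    })
  }

  total <- sum(obs$sigma)
  tab <- tibble(
    source = c("Among groups", "Among populations within groups",
               "Within populations"),
    df = as.numeric(obs$ss$df),
    sum_sq = c(obs$ss$AG, obs$ss$APWG, obs$ss$WP),
    sigma2 = as.numeric(obs$sigma),
    percent = if (total > 0) 100 * as.numeric(obs$sigma) / total
              else rep(NA_real_, 3))
  structure(list(components = tab, phi = obs$phi, p_values = pvals,
                 n_perms = n_perms),
            class = "amova_fit")
}

#' @export
print.amova_fit <- function(x, ...) {
  cat("<amova_fit>\n")
  print(as.data.frame(x$components), row.names = FALSE)
  cat("Phi_CT =", round(x$phi["CT"], 4), " Phi_SC =", round(x$phi["SC"], 4),
      " Phi_ST =", round(x$phi["ST"], 4), "\n")
  invisible(x)
}

#' @export
tidy.amova_fit <- function(x, ...) x$components

#' @export
glance.amova_fit <- function(x, ...) {
  tibble(phi_CT = unname(x$phi["CT"]), phi_SC = unname(x$phi["SC"]),
         phi_ST = unname(x$phi["ST"]), p_CT = unname(x$p_values["CT"]),
         p_SC = unname(x$p_values["SC"]), p_ST = unname(x$p_values["ST"]),
         n_perms = x$n_perms)
}
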