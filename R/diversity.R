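#' Analyzable columns of an alignment
#'
#' Per-site statistics use complete deletion: columns containing `N` or a
#' gap in any sequence are excluded, so only substitutions contribute.
#' @noRd
analyzable_columns <- function(mat) {
  which(!apply(mat == "N" | mat == "-", 2, any))
}

#' Count segregating sites
#'
#' A segregating site is an alignment column with at least two distinct
#' bases among the sampled sequences; sites with more than two alleles
#' count once. Columns containing gaps or `N` are excluded (substitutions
#' only).
#'
#' @param locus A [locus_alignment()] or plain character matrix.
#' @param columns Optional column subset (defaults to all analyzable ones).
#' @return Integer count.
#' @export
segregating_sites <- function(locus, columns = NULL) {
  mat <- unclass(locus)
  if (nrow(mat) == 0L || ncol(mat) == 0L) stop("empty alignment")
  cols <- if (is.null(columns)) analyzable_columns(mat) else columns
  if (!length(cols)) return(0L)
  sum(apply(mat[, cols, drop = FALSE], 2,
            function(col) dplyr::n_distinct(col)) > 1L)
}

#' Watterson's theta per site
#'
#' \eqn{\theta_W = S / (a_1 L)} with \eqn{a_1 = \sum_{i=1}^{n-1} 1/i}.
#'
#' @param S Number of segregating sites.
#' @param n Sample size (number of sequences).
#' @param L Analyzable length in base pairs.
#' @return Per-site estimate.
#' @export
watterson_theta <- function(S, n, L) {
  if (n < 2) stop("Watterson's estimator requires n >= 2")
  if (L < 1) stop("analyzable length must be >= 1")
  S / (sum(1 / seq_len(n - 1)) * L)
}

#' Nucleotide diversity (pi) per site
#'
#' Mean proportion of differing analyzable sites over all n(n-1)/2 sequence
#' pairs.
#'
#' @inheritParams segregating_sites
#' @return Per-site estimate.
#' @export
nucleotide_diversity_pi <- function(locus, columns = NULL) {
  mat <- unclass(locus)
  n <- nrow(mat)
  if (n < 2) stop("nucleotide diversity requires n >= 2")
  cols <- if (is.null(columns)) analyzable_columns(mat) else columns
  if (!length(cols)) return(0)
  sub <- mat[, cols, drop = FALSE]
  total <- 0
  for (j in seq_len(ncol(sub))) {
    cnt <- table(sub[, j])
    # differing pairs at this column: n^2 - sum(counts^2), halved
    total <- total + (n^2 - sum(cnt^2)) / 2
  }
  total / (n * (n - 1) / 2) / length(cols)
}

# mean number of pairwise differences (not per site)
mean_pairwise_differences <- function(mat, columns = NULL) {
  cols <- if (is.null(columns)) analyzable_columns(mat) else columns
  if (!length(cols)) return(0)
  nucleotide_diversity_pi(locus_like(mat), cols) * length(cols)
}

locus_like <- function(mat) structure(mat, class = c("locus_alignment", "matrix"),
                                      locus = "tmp")

#' Nei's haplotype diversity
#'
#' Unbiased gene diversity \eqn{H_d = \frac{n}{n-1}(1 - \sum p_i^2)} over
#' haplotype relative frequencies.
#'
#' @param table A [collapse_haplotypes()] result, or an integer vector of
#'   haplotype counts.
#' @return Diversity in `[0, 1]`.
#' @export
haplotype_diversity <- function(table) {
  counts <- if (is.numeric(table)) table else table$count
  n <- sum(counts)
  if (n < 2) stop("haplotype diversity requires n >= 2")
  p <- counts / n
  n / (n - 1) * (1 - sum(p^2))
}

#' Minimum number of recombination events (Hudson-Kaplan Rm)
#'
#' Applies the four-gamete test to every pair of biallelic segregating
#' sites and returns the size of a maximal set of non-conflicting
#' incompatible intervals; intervals sharing an endpoint conflict.
#'
#' @inheritParams segregating_sites
#' @return Integer lower bound on the number of recombination events.
#' @export
minimum_recombination_rm <- function(locus) {
  mat <- unclass(locus)
  cols <- analyzable_columns(mat)
  seg <- cols[apply(mat[, cols, drop = FALSE], 2, dplyr::n_distinct) == 2L]
  if (length(seg) < 2) return(0L)
  incompatible <- list()
  for (a in seq_along(seg)[-length(seg)]) {
    for (b in (a + 1):length(seg)) {
      gametes <- unique(paste(mat[, seg[a]], mat[, seg[b]]))
      if (length(gametes) == 4L)
        incompatible[[length(incompatible) + 1L]] <- c(seg[a], seg[b])
    }
  }
  if (!length(incompatible)) return(0L)
  iv <- do.call(rbind, incompatible)
  iv <- iv[order(iv[, 2], iv[, 1]), , drop = FALSE]
  rm_count <- 0L
  last_end <- -Inf
  for (r in seq_len(nrow(iv))) {
    if (iv[r, 1] > last_end) {  # closed intervals: shared endpoints conflict
      rm_count <- rm_count + 1L
      last_end <- iv[r, 2]
    }
  }
  rm_count
}

# split polymorphic coding columns into synonymous/nonsynonymous changes
change_class <- function(mat, classification) {
  sites <- classification$sites
  cols <- analyzable_columns(mat)
  out <- rep("silent", ncol(mat))
  coding <- which(sites$class %in% c("synonymous-eligible",
                                     "nonsynonymous-eligible"))
  gc <- Biostrings::GENETIC_CODE
  for (j in intersect(coding, cols)) {
    alleles <- unique(mat[, j])
    if (length(alleles) < 2) next
    # evaluate each observed variant in the reference codon context
    ref <- sites$reference
    out[j] <- "nonsynonymous"
    cod_cols <- codon_columns(classification, j)
    if (is.null(cod_cols)) next
    ref_cod <- paste(ref[cod_cols], collapse = "")
    aa <- gc[[ref_cod]]
    syn <- TRUE
    for (b in setdiff(alleles, ref[j])) {
      mut <- ref_cod
      substr(mut, which(cod_cols == j), which(cod_cols == j)) <- b
      if (gc[[mut]] != aa) syn <- FALSE
    }
    out[j] <- if (syn) "synonymous" else "nonsynonymous"
  }
  out
}

# columns of the codon containing site j (NULL when not in a codon)
codon_columns <- function(classification, j) {
  cod <- attr(classification, "codon_map")
  if (is.null(cod)) return(NULL)
  hit <- cod[vapply(cod, function(cc) j %in% cc, logical(1))]
  if (length(hit)) hit[[1]] else NULL
}

#' Per-locus diversity statistics table
#'
#' Computes, for every locus and for the concatenated ("Aligned") data, the
#' summary columns of a standard multilocus diversity table: sample size N,
#' length L, segregating sites S, Watterson's theta and nucleotide
#' diversity pi (total, nonsynonymous `_a`, and silent `_sil` when coding
#' annotation is available), number of haplotypes Nh, haplotype diversity
#' Hd, and the minimum number of recombination events Rm.
#'
#' @param dataset A [multilocus_dataset()].
#' @param genome Restrict to `"nuclear"` or `"chloroplast"` loci
#'   (default: all).
#' @return A tibble with one row per locus plus `Average` and `Aligned`
#'   rows.
#' @export
diversity_stats <- function(dataset, genome = NULL) {
  loci <- dataset$loci
  if (!is.null(genome)) loci <- loci[dataset$genome[names(loci)] == genome]
  rows <- purrr::map(loci, function(lc) {
    mat <- unclass(lc)
    n <- nrow(mat)
    cols <- analyzable_columns(mat)
    S <- segregating_sites(lc)
    hap <- collapse_haplotypes(lc)
    cl <- if (!is.null(dataset$cds) &&
              locus_name(lc) %in% dataset$cds$locus)
      classify_sites(lc, dataset$cds) else classify_sites(lc, NULL)
    chg <- change_class(mat, cl)
    w_ns <- cl$sites$nonsyn_frac
    w_sil <- ifelse(cl$sites$class == "silent", 1, cl$sites$syn_frac)
    ns_cols <- intersect(cols, which(chg == "nonsynonymous" | w_ns > 0))
    sil_cols <- intersect(cols, which(chg %in% c("silent", "synonymous") |
                                        w_sil > 0))
    # restrict segregating columns to their change class
    ns_seg <- intersect(cols[apply(mat[, cols, drop = FALSE], 2,
                                   dplyr::n_distinct) > 1L],
                        which(chg == "nonsynonymous"))
    sil_seg <- intersect(cols[apply(mat[, cols, drop = FALSE], 2,
                                    dplyr::n_distinct) > 1L],
                         which(chg %in% c("silent", "synonymous")))
    L_ns <- sum(w_ns[cols])
    L_sil <- sum(ifelse(cl$sites$class[cols] == "silent", 1,
                        cl$sites$syn_frac[cols]))
    a1 <- sum(1 / seq_len(n - 1))
    pi_at <- function(seg_cols, Lw) {
      if (Lw <= 0) return(0)
      tot <- 0
      for (j in seg_cols) {
        cnt <- table(mat[, j])
        tot <- tot + (n^2 - sum(cnt^2)) / 2 / (n * (n - 1) / 2)
      }
      tot / Lw
    }
    tibble(locus = locus_name(lc), N = n, L = ncol(mat), S = S,
           theta_t = watterson_theta(S, n, length(cols)),
           pi_t = nucleotide_diversity_pi(lc),
           theta_a = if (L_ns > 0) length(ns_seg) / (a1 * L_ns) else 0,
           pi_a = pi_at(ns_seg, L_ns),
           theta_sil = if (L_sil > 0) length(sil_seg) / (a1 * L_sil) else 0,
           pi_sil = pi_at(sil_seg, L_sil),
           Nh = nrow(hap), Hd = haplotype_diversity(hap),
           Rm = minimum_recombination_rm(lc))
  })
  tab <- bind_rows(rows)
  n <- tab$N[1]
  concat <- do.call(cbind, purrr::map(loci, unclass))
  concat_locus <- locus_like(concat)
  S_tot <- sum(tab$S)
  cols <- analyzable_columns(concat)
  aligned <- tibble(locus = "Aligned", N = n, L = sum(tab$L), S = S_tot,
                    theta_t = watterson_theta(segregating_sites(concat_locus),
                                              n, length(cols)),
                    pi_t = nucleotide_diversity_pi(concat_locus),
                    theta_a = NA, pi_a = NA, theta_sil = NA, pi_sil = NA,
                    Nh = nrow(collapse_haplotypes(concat_locus)),
                    Hd = haplotype_diversity(collapse_haplotypes(concat_locus)),
                    Rm = minimum_recombination_rm(concat_locus))
  average <- tab %>%
    summarise(across(c("N", "L", "S", "theta_t", "pi_t", "theta_a", "pi_a",
                       "theta_sil", "pi_sil", "Nh", "Hd", "Rm"), mean)) %>%
    mutate(locus = "Average", .before = 1)
  bind_rows(tab, average, aligned)
}
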