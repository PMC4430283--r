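#' Jukes-Cantor distance correction
#'
#' \eqn{K = -\frac{3}{4}\ln(1 - \frac{4}{3}p)} for a proportion of
#' differing sites `p`.
#'
#' @param p Proportion of differing sites (< 0.75).
#' @return Corrected substitutions per site.
#' @export
jukes_cantor <- function(p) {
  if (any(p >= 0.75)) stop("proportion too large for Jukes-Cantor correction")
  -3 / 4 * log(1 - 4 * p / 3)
}

# Nei-Gojobori counts for one codon pair: fractional syn/nonsyn sites of a
# codon, and pathway-averaged syn/nonsyn differences between two codons
ng86_codon_sites <- function(codon) {
  fr <- codon_syn_fraction()[[codon]]
  if (is.null(fr)) return(c(syn = NA_real_, nonsyn = NA_real_))
  c(syn = sum(fr), nonsyn = 3 - sum(fr))
}

ng86_codon_diffs <- function(c1, c2) {
  gc <- Biostrings::GENETIC_CODE
  aa <- function(cod) gc[[cod]]
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (!length(pos)) return(c(syn = 0, nonsyn = 0))
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    purrr::flatten(purrr::map(seq_along(v), function(i)
      purrr::map(perms(v[-i]), ~ c(v[i], .x))))
  }
  paths <- perms(pos)
  s1 <- strsplit(c1, "")[[1]]
  s2 <- strsplit(c2, "")[[1]]
  tot <- c(syn = 0, nonsyn = 0)
  for (pth in paths) {
    cur <- s1
    for (p in pth) {
      nxt <- cur
      nxt[p] <- s2[p]
      if (aa(paste(cur, collapse = "")) == aa(paste(nxt, collapse = "")))
        tot["syn"] <- tot["syn"] + 1 / length(paths)
      else tot["nonsyn"] <- tot["nonsyn"] + 1 / length(paths)
      cur <- nxt
    }
  }
  tot
}

#' Pairwise K_Total and K_S between two aligned sequences
#'
#' `K_Total` is the Jukes-Cantor-corrected proportion of differing sites
#' over all analyzable positions; `K_S` is the corrected synonymous
#' distance from Nei-Gojobori (1986) counting over the annotated coding
#' region (fractional site counts averaged between the two sequences,
#' pathway-averaged difference counts).
#'
#' @param seq1,seq2 Aligned sequences (strings or character vectors) of
#'   equal length; `seq1` is typically the ingroup consensus, `seq2` the
#'   outgroup.
#' @param cds_start,cds_end 1-based inclusive coding interval (in frame).
#' @return Tibble with `K_total`, `K_s`, `ratio` (NA when `K_s` = 0), and
#'   the underlying counts.
#' @export
pairwise_k_total_ks <- function(seq1, seq2, cds_start = NULL, cds_end = NULL) {
  s1 <- if (length(seq1) == 1) strsplit(toupper(seq1), "")[[1]] else toupper(seq1)
  s2 <- if (length(seq2) == 1) strsplit(toupper(seq2), "")[[1]] else toupper(seq2)
  if (length(s1) != length(s2)) stop("sequences must be aligned (equal length)")
  ok <- !(s1 %in% c("-", "N")) & !(s2 %in% c("-", "N"))
  p_total <- sum(s1[ok] != s2[ok]) / sum(ok)
  K_total <- jukes_cantor(p_total)
  K_s <- NA_real_
  syn_sites <- syn_diffs <- NA_real_
  if (!is.null(cds_start)) {
    cols <- cds_start:cds_end
    cols <- cols[ok[cols]]
    if (length(cols) %% 3 != 0) stop("coding interval not in frame after gap removal")
    cod_idx <- matrix(cols, nrow = 3)
    ss <- 0; sd <- 0
    for (j in seq_len(ncol(cod_idx))) {
      c1 <- paste(s1[cod_idx[, j]], collapse = "")
      c2 <- paste(s2[cod_idx[, j]], collapse = "")
      st1 <- ng86_codon_sites(c1)
      st2 <- ng86_codon_sites(c2)
      if (anyNA(c(st1, st2))) next
      ss <- ss + (st1["syn"] + st2["syn"]) / 2
      sd <- sd + ng86_codon_diffs(c1, c2)["syn"]
    }
    syn_sites <- unname(ss)
    syn_diffs <- unname(sd)
    K_s <- if (syn_sites > 0) jukes_cantor(syn_diffs / syn_sites) else NA_real_
  }
  tibble(K_total = K_total, K_s = K_s,
         ratio = ifelse(is.na(K_s) | K_s == 0, NA_real_, K_total / K_s),
         p_total = p_total, syn_sites = syn_sites, syn_diffs = syn_diffs)
}

#' Per-locus mutation rate from the synonymous-rate calibration
#'
#' \eqn{\mu = \mu_{CHS} \times K_{Total}/K_S \times L}: the synonymous
#' substitution rate of the Brassicaceae CHS gene
#' (1.5e-8 substitutions/site/year) scaled by the locus's total-to-
#' synonymous divergence ratio and its length, giving substitutions per
#' locus per year.
#'
#' @param k_ratio `K_Total / K_S` for the locus.
#' @param L Locus length (bp).
#' @param mu_chs Synonymous calibration rate (per site per year).
#' @return Mutation rate per locus per year.
#' @export
locus_mutation_rate <- function(k_ratio, L, mu_chs = 1.5e-8) {
  if (any(c(k_ratio, L, mu_chs) <= 0)) stop("all inputs must be positive")
  mu_chs * k_ratio * L
}

#' Divergence time from ITS substitutions
#'
#' \eqn{T = k / (2 \mu L)}: substitutions accumulate on both lineages
#' after a split.
#'
#' @param k Number of substitutions between the two taxa.
#' @param L Alignment length (bp).
#' @param mu_site Mutation rate per site per year.
#' @return Divergence time in years (0 when `k` = 0).
#' @export
its_divergence_time <- function(k, L, mu_site) {
  stopifnot(k >= 0, L > 0, mu_site > 0)
  k / (2 * mu_site * L)
}
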