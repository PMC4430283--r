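#' The emulated sampling design
#'
#' 24 populations (99 individuals, 3-6 per population) in three groups —
#' A: central Asia (populations 17-18), B: northern China plus Buriatia
#' (1-16, 20), C: North America plus Russia (19, 21-24) — with 10 nuclear
#' loci totalling 6510 bp and 9 chloroplast fragments totalling 4379 bp,
#' of which only the 405-bp psbA-trnH spacer is polymorphic.
#'
#' @return List with tibbles `populations` (population, n, group),
#'   `nuclear_loci` (locus, length) and `cp_fragments` (locus, length,
#'   polymorphic).
#' @export
study_design <- function() {
  pop_n <- c(rep(4L, 21), rep(5L, 3))
  pop <- sprintf("P%02d", 1:24)
  group <- dplyr::case_when(pop %in% sprintf("P%02d", 17:18) ~ "A",
                            pop %in% sprintf("P%02d", c(1:16, 20)) ~ "B",
                            TRUE ~ "C")
  list(
    populations = tibble(population = pop, n = pop_n, group = group),
    nuclear_loci = tibble(
      locus = c("COP", "DET", "FAH", "CHS", "F3H", "PGIC", "RPS1", "RPS3",
                "HKT", "SOS1"),
      length = c(517, 545, 462, 931, 496, 800, 953, 468, 711, 627)),
    cp_fragments = tibble(
      locus = c("psbA-trnH", "trnL-trnF", "trnS-trnG", "rpl32-trnL", "matK",
                "rbcL", "ndhF", "petB-petD", "atpB-rbcL"),
      length = c(405, 520, 560, 540, 515, 499, 480, 450, 410),
      polymorphic = c(TRUE, rep(FALSE, 8))))
}

#' Default generator parameters (scenario 1 point estimates)
#'
#' The divergence-with-expansion history used as ground truth for
#' synthetic data: the central-Asian group is the source (T1 = 23,000
#' years), the northern-China and North-America groups split at T2 =
#' 11,000 years, and the northern-China group expanded within the
#' Holocene (T_exp = 8,000 years) from a small founder size. Effective
#' sizes are chosen so the emulated nuclear data carry about 11
#' segregating sites over 6510 bp, the observed level of polymorphism.
#'
#' @return Named list of parameters for [migration_scenario()].
#' @export
default_study_params <- function() {
  list(N_A = 12000, N_B = 60000, N_C = 3000, N_anc = 1500, N_B0 = 300,
       T1 = 23000, T2 = 11000, T_exp = 8000)
}

#' Generate a study-like synthetic dataset
#'
#' Simulates the full sampling design under a migration scenario
#' (scenario 1 by default, at the point-estimate parameters of
#' [default_study_params()]), with one lineage per population copied to
#' every individual of that population — mirroring the observed absence
#' of within-population variation. Calibration targets are enforced by
#' redrawing with logged attempts: total nuclear segregating sites between
#' 6 and 18 (around the observed 11) and 5-8 chloroplast haplotypes with
#' polymorphism confined to psbA-trnH.
#'
#' @param seed Integer seed; the dataset is a deterministic function of it.
#' @param params True demographic parameters.
#' @param scenario_id Scenario template (default 1).
#' @param mu_site Nuclear mutation rate per site per year.
#' @param mu_cp Chloroplast (psbA-trnH) rate per site per year; the
#'   spacer is hypervariable relative to the conserved fragments.
#' @param max_attempts Redraw limit for the calibration targets.
#' @return A [multilocus_dataset()] with nuclear and chloroplast loci;
#'   attribute `attempts` records the number of redraws.
#' @export
generate_study_like_dataset <- function(seed, params = default_study_params(),
                                        scenario_id = 1, mu_site = 9.3e-9,
                                        mu_cp = 6e-8, max_attempts = 50) {
  des <- study_design()
  scn <- migration_scenario(scenario_id, params)
  pops <- des$populations
  groups <- sort(unique(pops$group))
  samples <- setNames(as.integer(table(factor(pops$group, groups))), groups)
  # lineages are ordered by group (A block, then B, then C)
  pop_order <- pops$population[order(match(pops$group, groups))]

  with_seed(seed, {
    achieved <- NULL
    for (attempt in seq_len(max_attempts)) {
      gn <- simulate_genealogies(scn, samples, n_loci = nrow(des$nuclear_loci))
      lmod <- mutate(des$nuclear_loci, mu = mu_site * .data$length)
      mn <- add_mutations(gn, lmod)
      S_total <- sum(vapply(mn, function(m) ncol(m$derived), numeric(1)))
      gc_ <- simulate_genealogies(scn, samples, n_loci = 1)
      cp_len <- des$cp_fragments$length[des$cp_fragments$polymorphic]
      mc <- add_mutations(gc_, tibble(locus = "psbA-trnH", length = cp_len,
                                      mu = mu_cp * cp_len))
      cp_nh <- nrow(unique(mc[[1]]$derived))
      achieved <- c(S_nuclear = S_total, cp_haplotypes = cp_nh)
      if (S_total >= 6 && S_total <= 18 && cp_nh >= 5 && cp_nh <= 8) break
      if (attempt == max_attempts)
        stop("calibration unmet after ", max_attempts,
             " attempts; last draw had ", S_total,
             " nuclear segregating sites and ", cp_nh, " cp haplotypes")
    }

    pm <- pops %>%
      arrange(match(.data$group, groups)) %>%
      tidyr::uncount(.data$n, .id = "rep") %>%
      mutate(individual = paste0(.data$population, "_", .data$rep)) %>%
      select("individual", "population", "group")
    lineage_of <- match(pm$population, pop_order)

    nuc <- mutations_to_dataset(mn, pm, lineage_of = lineage_of)
    cp_poly <- mutations_to_dataset(mc, pm, lineage_of = lineage_of)
    # monomorphic chloroplast fragments: constant random references
    mono <- des$cp_fragments[!des$cp_fragments$polymorphic, ]
    mono_loci <- purrr::map2(mono$locus, mono$length, function(nm, L) {
      ref <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                   collapse = "")
      locus_alignment(setNames(rep(ref, nrow(pm)), pm$individual), name = nm)
    })
    loci <- c(nuc$loci, cp_poly$loci, mono_loci)
    genome <- setNames(c(rep("nuclear", length(nuc$loci)),
                         rep("chloroplast", 1 + length(mono_loci))),
                       c(names(nuc$loci), names(cp_poly$loci),
                         vapply(mono_loci, locus_name, character(1))))
    ds <- multilocus_dataset(loci, pm, genome = genome)
    attr(ds, "attempts") <- attempt
    attr(ds, "achieved") <- achieved
    ds
  })
}

#' Build a small deterministic dataset from explicit haplotype strings
#'
#' @param haplotypes Character vector of aligned sequences (one per
#'   individual) or a named list of such vectors (one element per locus).
#' @param populations Character vector of population ids per individual.
#' @param groups Optional named map population -> group (defaults to one
#'   group per population).
#' @param locus Locus name(s) when `haplotypes` is a plain vector.
#' @return A [multilocus_dataset()].
#' @export
generate_toy <- function(haplotypes, populations = NULL, groups = NULL,
                         locus = "toy") {
  if (!is.list(haplotypes)) haplotypes <- setNames(list(haplotypes), locus)
  n <- length(haplotypes[[1]])
  if (is.null(populations)) populations <- rep("pop1", n)
  inds <- paste0("ind", seq_len(n))
  if (is.null(groups)) {
    upops <- unique(populations)
    groups <- setNames(upops, upops)
  }
  pm <- tibble(individual = inds, population = populations,
               group = unname(groups[populations]))
  loci <- purrr::imap(haplotypes, function(seqs, nm)
    locus_alignment(setNames(seqs, inds), name = nm))
  multilocus_dataset(loci, pm)
}
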