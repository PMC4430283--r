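#' Simulate coalescent genealogies under a demographic scenario
#'
#' Draws independent genealogies (one per locus) for samples placed in the
#' scenario's demes. Time is measured in years with one generation per year;
#' deme sizes are haploid effective sizes.
#'
#' @param scn A [demographic_scenario()].
#' @param samples Named integer vector: number of sampled lineages per deme.
#' @param n_loci Number of independent genealogies to draw.
#' @param seed Optional integer seed.
#' @return An object of class `genealogy_set`: a list of genealogies, each
#'   with `parent` (1-based, root = 0), `time` (node times in years),
#'   `n_leaves`, `tmrca` and `tlen`; leaves are ordered by deme as given in
#'   `samples`. The sample layout is kept in attributes.
#' @export
simulate_genealogies <- function(scn, samples, n_loci = 1, seed = NULL) {
  validate_scenario(scn, sampled = names(samples)[samples > 0])
  idx <- setNames(seq_along(scn$demes), names(scn$demes))
  sample_deme <- rep(unname(idx[names(samples)]), samples) - 1L
  gl <- with_seed(seed,
    coalsim_genealogies_cpp(scenario_matrix(scn), unname(scn$demes),
                            as.integer(sample_deme), as.integer(n_loci)))
  structure(gl, class = "genealogy_set",
            deme = rep(names(samples), samples), scenario = scn$label)
}

#' @export
print.genealogy_set <- function(x, ...) {
  cat("<genealogy_set> ", length(x), " genealogies, ",
      x[[1]]$n_leaves, " leaves each\n", sep = "")
  invisible(x)
}

#' Summary statistics of simulated genealogies
#'
#' @param x A `genealogy_set`.
#' @param ... Unused.
#' @return Tibble with one row per genealogy: `tmrca` and total branch
#'   length `tlen` (years).
#' @export
tidy.genealogy_set <- function(x, ...) {
  tibble(locus = seq_along(x),
         tmrca = vapply(x, `[[`, numeric(1), "tmrca"),
         tlen = vapply(x, `[[`, numeric(1), "tlen"))
}

# branch lengths indexed by child node (root excluded)
branch_lengths <- function(g) {
  v <- seq_len(length(g$parent) - 1L)
  g$time[g$parent[v]] - g$time[v]
}

# 0/1 leaf membership for the subtree under each node
descendant_matrix <- function(g) {
  m <- length(g$parent)
  n <- g$n_leaves
  D <- matrix(0L, n, m)
  D[cbind(seq_len(n), seq_len(n))] <- 1L
  for (v in seq_len(m - 1L)) D[, g$parent[v]] <- D[, g$parent[v]] + D[, v]
  D
}

#' Overlay mutations on simulated genealogies
#'
#' Places Poisson-distributed mutations on branches (infinite-sites model:
#' each mutation hits a previously unmutated alignment position) or, when
#' `fixed_S` is given, exactly that many mutations multinomially by branch
#' length (the fixed-S conditioning used for neutrality-test null
#' distributions).
#'
#' @param genealogies A [simulate_genealogies()] result.
#' @param locus_model Tibble with one row per genealogy: columns `locus`
#'   (name), `length` (bp) and `mu` (mutation rate per locus per year).
#' @param fixed_S Optional integer vector (or single value) of segregating
#'   sites per locus overriding the Poisson draw.
#' @param seed Optional integer seed.
#' @return List (one element per locus) with `derived` (leaves x mutations
#'   0/1 matrix), `positions` (1-based alignment positions) and the locus
#'   name; class `mutation_set`.
#' @export
add_mutations <- function(genealogies, locus_model, fixed_S = NULL,
                          seed = NULL) {
  stopifnot(length(genealogies) == nrow(locus_model))
  if (!is.null(fixed_S)) fixed_S <- rep_len(fixed_S, length(genealogies))
  out <- with_seed(seed, purrr::map(seq_along(genealogies), function(l) {
    g <- genealogies[[l]]
    len <- branch_lengths(g)
    L <- locus_model$length[l]
    M <- if (!is.null(fixed_S)) fixed_S[l] else rpois(1, locus_model$mu[l] * sum(len))
    guard <- 0
    while (M > L) {  # finite-length guard for the infinite-sites overlay
      warning("locus '", locus_model$locus[l], "': ", M,
              " mutations exceed length ", L, "; redrawing")
      M <- rpois(1, locus_model$mu[l] * sum(len))
      if ((guard <- guard + 1) > 100) stop("mutation count repeatedly exceeds locus length")
    }
    D <- descendant_matrix(g)
    branches <- if (M > 0) sample.int(length(len), M, replace = TRUE, prob = len)
                else integer(0)
    derived <- D[, branches, drop = FALSE]
    positions <- sort(sample.int(L, M))
    list(derived = derived, positions = positions,
         locus = locus_model$locus[l], length = L)
  }))
  structure(out, class = "mutation_set", deme = attr(genealogies, "deme"))
}

#' Turn simulated mutations into sequence alignments
#'
#' Builds a [multilocus_dataset()] from a `mutation_set`: a random reference
#' sequence per locus, with each mutation substituting a distinct base at
#' its position for the carriers.
#'
#' @param mutations An [add_mutations()] result.
#' @param pop_map Population map tibble; its `individual` column (in order)
#'   names the leaves. When individuals outnumber leaves, `lineage_of` maps
#'   each individual to a leaf (used to copy population-level lineages).
#' @param lineage_of Optional integer vector: leaf index per individual.
#' @param genome Optional genome tags per locus (see [multilocus_dataset()]).
#' @param seed Optional integer seed for reference-sequence generation.
#' @return A [multilocus_dataset()].
#' @export
mutations_to_dataset <- function(mutations, pop_map, lineage_of = NULL,
                                 genome = NULL, seed = NULL) {
  n_leaves <- nrow(mutations[[1]]$derived)
  if (is.null(lineage_of)) lineage_of <- seq_len(nrow(pop_map))
  stopifnot(length(lineage_of) == nrow(pop_map), all(lineage_of <= n_leaves))
  bases <- c("A", "C", "G", "T")
  loci <- with_seed(seed, purrr::map(mutations, function(m) {
    ref <- sample(bases, m$length, replace = TRUE)
    seqs <- matrix(rep(ref, each = n_leaves), n_leaves, m$length)
    for (j in seq_along(m$positions)) {
      alt <- sample(setdiff(bases, ref[m$positions[j]]), 1)
      seqs[m$derived[, j] == 1, m$positions[j]] <- alt
    }
    mat <- seqs[lineage_of, , drop = FALSE]
    rownames(mat) <- pop_map$individual
    locus_alignment(mat, name = m$locus)
  }))
  multilocus_dataset(loci, pop_map, genome = genome)
}
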