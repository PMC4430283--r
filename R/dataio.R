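#' Construct a single-locus alignment
#'
#' A locus alignment holds one aligned haploid sequence per sampled
#' individual. Sequences are stored upper-cased as a character matrix
#' (individuals x alignment columns) restricted to the alphabet
#' `A, C, G, T, -, N`.
#'
#' @param seqs Named character vector of aligned sequences (one per
#'   individual, equal lengths) or a character matrix with row names.
#' @param name Locus name.
#' @param inversions Optional tibble/data.frame with columns `start`, `end`
#'   (1-based inclusive alignment coordinates) marking annotated inversion
#'   blocks that should be treated as single mutational characters.
#' @return An object of class `locus_alignment`.
#' @export
locus_alignment <- function(seqs, name = "locus", inversions = NULL) {
  if (is.matrix(seqs)) {
    mat <- seqs
    mat[] <- toupper(mat)
  } else {
    seqs <- toupper(seqs)
    if (is.null(names(seqs))) names(seqs) <- paste0("ind", seq_along(seqs))
    lens <- nchar(seqs)
    if (length(unique(lens)) != 1L) {
      bad <- names(seqs)[which(lens != lens[1])[1]]
      stop("ragged alignment at locus '", name, "': record '", bad,
           "' has length ", nchar(seqs[bad]), ", expected ", lens[1])
    }
    mat <- do.call(rbind, strsplit(seqs, ""))
    rownames(mat) <- names(seqs)
  }
  if (ncol(mat) == 0L) stop("empty alignment for locus '", name, "'")
  if (anyDuplicated(rownames(mat)))
    stop("duplicate individual ids in locus '", name, "'")
  bad <- setdiff(unique(as.vector(mat)), c("A", "C", "G", "T", "-", "N"))
  if (length(bad))
    stop("locus '", name, "' contains characters outside {A,C,G,T,-,N}: ",
         paste(bad, collapse = ", "))
  structure(mat, class = c("locus_alignment", "matrix"),
            locus = name, inversions = inversions)
}

#' @export
print.locus_alignment <- function(x, ...) {
  cat("<locus_alignment> ", attr(x, "locus"), ": ", nrow(x),
      " sequences x ", ncol(x), " bp\n", sep = "")
  invisible(x)
}

locus_name <- function(locus) attr(locus, "locus")

#' Assemble a multilocus dataset
#'
#' The universal input object: a list of per-locus alignments keyed to a
#' population map (individual -> population -> group).
#'
#' @param loci List of [locus_alignment()] objects (possibly a subset of
#'   individuals per locus, but every individual must appear in `pop_map`).
#' @param pop_map Tibble/data.frame with columns `individual`, `population`,
#'   `group`.
#' @param cds Optional coding annotation: tibble with columns `locus`,
#'   `start`, `end`, `frame` (1-based inclusive alignment coordinates).
#' @param genome Optional named character vector tagging each locus
#'   `"nuclear"` or `"chloroplast"` (defaults to nuclear).
#' @return An object of class `multilocus_dataset`.
#' @export
multilocus_dataset <- function(loci, pop_map, cds = NULL, genome = NULL) {
  pop_map <- as_tibble(pop_map)
  stopifnot(all(c("individual", "population", "group") %in% names(pop_map)))
  pop_map$population <- as.character(pop_map$population)
  pop_map$group <- as.character(pop_map$group)
  names(loci) <- vapply(loci, locus_name, character(1))
  for (lc in loci) {
    unknown <- setdiff(rownames(lc), pop_map$individual)
    if (length(unknown))
      stop("individuals in locus '", locus_name(lc),
           "' missing from population map: ",
           paste(head(unknown, 5), collapse = ", "))
  }
  if (is.null(genome)) genome <- setNames(rep("nuclear", length(loci)), names(loci))
  if (!is.null(cds)) cds <- as_tibble(cds)
  structure(list(loci = loci, pop_map = pop_map, cds = cds, genome = genome),
            class = "multilocus_dataset")
}

#' @export
print.multilocus_dataset <- function(x, ...) {
  cat("<multilocus_dataset> ", length(x$loci), " loci, ",
      nrow(x$pop_map), " individuals, ",
      dplyr::n_distinct(x$pop_map$population), " populations, ",
      dplyr::n_distinct(x$pop_map$group), " groups\n", sep = "")
  invisible(x)
}

n_individuals <- function(dataset) nrow(dataset$pop_map)

#' Read per-locus FASTA alignments plus a population map
#'
#' One FASTA file per locus (pre-aligned, one record per individual); the
#' population map is a TSV with header `individual<TAB>population<TAB>group`.
#'
#' @param paths Character vector of FASTA file paths; locus names are taken
#'   from the file names (without extension).
#' @param pop_map_path Path to the population-map TSV.
#' @param cds_path Optional coding-annotation TSV
#'   (`locus<TAB>start<TAB>end<TAB>frame`, 1-based inclusive).
#' @return A [multilocus_dataset()].
#' @export
read_multilocus_fasta <- function(paths, pop_map_path, cds_path = NULL) {
  pop_map <- utils::read.delim(pop_map_path, colClasses = "character")
  loci <- lapply(paths, function(p) {
    nm <- sub("\\.[^.]*$", "", basename(p))
    ss <- Biostrings::readBStringSet(p)
    locus_alignment(setNames(as.character(ss), names(ss)), name = nm)
  })
  cds <- if (!is.null(cds_path)) utils::read.delim(cds_path) else NULL
  multilocus_dataset(loci, pop_map, cds = cds)
}

#' Write a multilocus dataset as FASTA files plus a population map
#'
#' @param dataset A [multilocus_dataset()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written (loci FASTAs then popmap TSV).
#' @export
write_multilocus_fasta <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(dataset$loci, function(lc) {
    p <- file.path(dir, paste0(locus_name(lc), ".fasta"))
    seqs <- apply(unclass(lc), 1, paste, collapse = "")
    Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), p)
    p
  }, character(1))
  pm <- file.path(dir, "popmap.tsv")
  utils::write.table(dataset$pop_map, pm, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(paths, pm))
}

# maximal runs of TRUE in a logical vector -> list of index ranges
runs_of <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  purrr::map2(starts[r$values], ends[r$values], ~ .x:.y)
}

# Recode an alignment into mutational characters: substitution columns stay
# single characters; each contiguous gap-containing run and each annotated
# inversion block collapses to one character whose state is the block string.
recode_characters <- function(locus, indel_mode = c("recode", "exclude")) {
  indel_mode <- match.arg(indel_mode)
  mat <- unclass(locus)
  inv <- attr(locus, "inversions")
  inv_cols <- integer(0)
  inv_blocks <- list()
  if (!is.null(inv) && nrow(inv)) {
    inv_blocks <- purrr::map2(inv$start, inv$end, ~ .x:.y)
    inv_cols <- unlist(inv_blocks)
  }
  gap_col <- apply(mat == "-", 2, any)
  gap_col[inv_cols] <- FALSE
  gap_runs <- runs_of(gap_col)
  plain <- setdiff(which(!gap_col), inv_cols)

  blocks <- c(as.list(plain),
              if (indel_mode == "recode") gap_runs,
              inv_blocks)
  out <- matrix("", nrow(mat), length(blocks),
                dimnames = list(rownames(mat), NULL))
  for (j in seq_along(blocks)) {
    cols <- blocks[[j]]
    out[, j] <- if (length(cols) == 1L) mat[, cols]
                else apply(mat[, cols, drop = FALSE], 1, paste, collapse = "")
  }
  attr(out, "block_cols") <- blocks
  out
}

#' Collapse aligned sequences into haplotypes
#'
#' Identical sequences share a haplotype, numbered `H1..Hk` in order of first
#' occurrence. With `indel_mode = "recode"` each contiguous gap run and each
#' annotated inversion block counts as a single mutational character (the
#' convention used for haplotype networks); with `"exclude"` gap-containing
#' columns are dropped before comparison.
#'
#' @param locus A [locus_alignment()].
#' @param indel_mode `"recode"` (default) or `"exclude"`.
#' @param pop_map Optional population map tibble; when given, per-population
#'   haplotype counts are attached.
#' @return A tibble with columns `haplotype`, `count` (class
#'   `haplotype_table`), with attributes `assignment` (named haplotype id per
#'   individual), `char_matrix` (recoded character states per haplotype) and,
#'   if `pop_map` is supplied, `pop_counts` (haplotype x population matrix).
#' @export
collapse_haplotypes <- function(locus, indel_mode = c("recode", "exclude"),
                                pop_map = NULL) {
  indel_mode <- match.arg(indel_mode)
  mat <- unclass(locus)
  informative <- apply(mat, 1, function(s) any(!(s %in% c("N", "-"))))
  if (any(!informative))
    stop("degenerate input: sequence(s) ",
         paste(rownames(mat)[!informative], collapse = ", "),
         " contain only gaps/ambiguities")
  rec <- recode_characters(locus, indel_mode)
  keys <- apply(rec, 1, paste, collapse = "\r")
  first <- !duplicated(keys)
  idx <- match(keys, unique(keys))  # haplotype index by first occurrence
  ids <- setNames(paste0("H", idx), rownames(mat))
  tab <- tibble(haplotype = paste0("H", seq_along(unique(keys))),
                count = as.integer(tabulate(idx)))
  attr(tab, "assignment") <- ids
  cm <- rec[first, , drop = FALSE]
  rownames(cm) <- paste0("H", seq_len(sum(first)))
  attr(tab, "char_matrix") <- cm
  attr(tab, "locus") <- locus_name(locus)
  if (!is.null(pop_map)) {
    pops <- pop_map$population[match(rownames(mat), pop_map$individual)]
    attr(tab, "pop_counts") <- unclass(table(ids, pops))[tab$haplotype, ,
                                                         drop = FALSE]
  }
  class(tab) <- c("haplotype_table", class(tab))
  tab
}

codon_syn_fraction <- local({
  code <- NULL
  function() {
    if (is.null(code)) {
      gc <- Biostrings::GENETIC_CODE
      bases <- c("A", "C", "G", "T")
      res <- list()
      for (cod in names(gc)) {
        cod_t <- chartr("U", "T", cod)
        aa <- gc[[cod]]
        fr <- numeric(3)
        for (p in 1:3) {
          alt <- bases[bases != substr(cod_t, p, p)]
          syn <- 0
          for (b in alt) {
            mut <- cod_t
            substr(mut, p, p) <- b
            # changes producing stops count as nonsynonymous so fractional
            # site counts sum to 3 per codon
            if (gc[[mut]] == aa && aa != "*") syn <- syn + 1
          }
          fr[p] <- syn / 3
        }
        res[[cod_t]] <- fr
      }
      code <<- res
    }
    code
  }
})

consensus_sequence <- function(mat) {
  apply(mat, 2, function(col) {
    col <- col[!(col %in% c("-", "N"))]
    if (!length(col)) return("N")
    names(sort(table(col), decreasing = TRUE))[1]
  })
}

#' Classify alignment columns for synonymous/silent partitioning
#'
#' Computes Nei-Gojobori fractional synonymous and nonsynonymous site counts
#' on the consensus sequence over the annotated coding intervals. Noncoding
#' columns are silent; columns containing gaps or `N` are excluded.
#'
#' @param locus A [locus_alignment()].
#' @param cds Tibble with columns `locus`, `start`, `end`, `frame` (1-based
#'   inclusive; `frame` = offset 0..2 of the first complete codon).
#' @return A list of class `site_classification`: `sites` (tibble with
#'   per-column `class`, `syn_frac`, `nonsyn_frac`), `n_syn`, `n_nonsyn`,
#'   `n_silent_sites` (silent = noncoding analyzable + fractional synonymous).
#' @export
classify_sites <- function(locus, cds = NULL) {
  mat <- unclass(locus)
  L <- ncol(mat)
  excluded <- apply(mat == "-" | mat == "N", 2, any)
  cls <- ifelse(excluded, "excluded", "silent")
  syn <- nonsyn <- numeric(L)
  ref <- consensus_sequence(mat)
  codon_map <- list()
  if (!is.null(cds)) {
    cds <- cds[cds$locus == locus_name(locus), , drop = FALSE]
    frtab <- codon_syn_fraction()
    for (r in seq_len(nrow(cds))) {
      cols <- (cds$start[r] + cds$frame[r]):cds$end[r]
      cols <- cols[!excluded[cols]]
      if (length(cols) %% 3 != 0)
        stop("coding interval for locus '", locus_name(locus),
             "' is not in frame after gap removal")
      codons <- matrix(cols, nrow = 3)
      for (j in seq_len(ncol(codons))) {
        codon_map[[length(codon_map) + 1L]] <- codons[, j]
        cod <- paste(ref[codons[, j]], collapse = "")
        if (grepl("N", cod)) next
        if (Biostrings::GENETIC_CODE[[cod]] == "*")
          stop("internal stop codon in reference frame of locus '",
               locus_name(locus), "'")
        fr <- frtab[[cod]]
        for (p in 1:3) {
          cc <- codons[p, j]
          syn[cc] <- fr[p]
          nonsyn[cc] <- 1 - fr[p]
          cls[cc] <- if (fr[p] > 0.5) "synonymous-eligible"
                     else "nonsynonymous-eligible"
        }
      }
    }
  }
  sites <- tibble(site = seq_len(L), class = cls, syn_frac = syn,
                  nonsyn_frac = nonsyn, reference = ref)
  structure(list(sites = sites,
                 n_syn = sum(syn),
                 n_nonsyn = sum(nonsyn),
                 n_silent_sites = sum(cls == "silent") + sum(syn),
                 locus = locus_name(locus)),
            class = "site_classification", codon_map = codon_map)
}

#' @export
print.site_classification <- function(x, ...) {
  cat("<site_classification> ", x$locus, ": ", x$n_syn,
      " synonymous / ", x$n_nonsyn, " nonsynonymous fractional sites\n",
      sep = "")
  invisible(x)
}
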