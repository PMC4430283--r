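test_that("fasta round-trip preserves a small dataset exactly", {
  ds <- generate_toy(list(
    loc1 = c("ACGTACGT", "ACGTACGA", "ACGTACGT", "ACCTACGT"),
    loc2 = c("TTTT", "TTTA", "TTTT", "TTTT")),
    populations = c("p1", "p1", "p2", "p2"))
  expect_equal(length(ds$loci), 2L)
  expect_equal(nrow(ds$pop_map), 4L)
  dir <- withr::local_tempdir()
  write_multilocus_fasta(ds, dir)
  ds2 <- read_multilocus_fasta(file.path(dir, c("loc1.fasta", "loc2.fasta")),
                               file.path(dir, "popmap.tsv"))
  for (nm in names(ds$loci))
    expect_identical(unclass(ds$loci[[nm]])[, ], unclass(ds2$loci[[nm]])[, ])
  expect_equal(as.data.frame(ds2$pop_map), as.data.frame(ds$pop_map))
})

test_that("ragged alignments and unknown individuals are rejected with context", {
  expect_error(locus_alignment(c(a = "ACGTA", b = "ACGT"), name = "locX"),
               "locX")
  lc <- locus_alignment(c(a = "ACGT", b = "ACGT"), name = "loc")
  expect_error(multilocus_dataset(list(lc),
                                  tibble::tibble(individual = "a",
                                                 population = "p",
                                                 group = "g")),
               "missing from population map")
  expect_error(locus_alignment(c(a = "ACXT"), name = "loc"), "outside")
})

test_that("haplotype collapse handles indels by recoding or exclusion", {
  lc <- locus_alignment(c(i1 = "AAT", i2 = "AAT", i3 = "A-T", i4 = "GAT"))
  rec <- collapse_haplotypes(lc, "recode")
  expect_equal(rec$count, c(2L, 1L, 1L))
  expect_equal(rec$haplotype, c("H1", "H2", "H3"))
  exc <- collapse_haplotypes(lc, "exclude")
  expect_equal(exc$count, c(3L, 1L))

  same <- locus_alignment(setNames(rep("ACGT", 4), paste0("i", 1:4)))
  expect_equal(collapse_haplotypes(same)$count, 4L)

  bad <- locus_alignment(c(a = "AC", b = "--"))
  expect_error(collapse_haplotypes(bad), "degenerate")
})

test_that("haplotype numbering is order-invariant up to relabeling and counts sum", {
  set.seed(5)
  for (rep in 1:10) {
    mat <- random_alignment(8, 30, n_var = 4)
    lc <- make_locus(mat)
    tab1 <- collapse_haplotypes(lc)
    perm <- sample(nrow(mat))
    tab2 <- collapse_haplotypes(make_locus(mat[perm, , drop = FALSE]))
    expect_equal(sort(tab1$count), sort(tab2$count))
    expect_equal(sum(tab1$count), nrow(mat))
  }
  # per-population counts sum to population sizes
  pm <- tibble::tibble(individual = paste0("ind", 1:8),
                       population = rep(c("p1", "p2"), each = 4),
                       group = "g")
  tab <- collapse_haplotypes(make_locus(random_alignment(8, 20, seed = 1)),
                             pop_map = pm)
  expect_equal(unname(colSums(attr(tab, "pop_counts"))), c(4, 4))
})

test_that("inversion blocks collapse to single characters", {
  lc <- locus_alignment(c(a = "AACGTT", b = "AGCATT", c = "AACGTT"),
                        inversions = data.frame(start = 2, end = 4))
  tab <- collapse_haplotypes(lc)
  cm <- attr(tab, "char_matrix")
  # 3 plain columns + 1 inversion character
  expect_equal(ncol(cm), 4L)
  expect_equal(tab$count, c(2L, 1L))
})

test_that("site classification matches codon enumeration", {
  # all-noncoding locus: everything silent, no synonymous fraction
  lc <- locus_alignment(c(a = "ACGTAC", b = "ACGTAC"))
  cl <- classify_sites(lc)
  expect_true(all(cl$sites$class == "silent"))
  expect_equal(cl$n_syn, 0)

  # TTT (Phe): positions 1 and 2 fully nonsynonymous, position 3 is 1/3
  # synonymous (TTC also Phe; TTA/TTG are Leu)
  lc2 <- locus_alignment(c(a = "TTT", b = "TTT"), name = "toy")
  cds <- data.frame(locus = "toy", start = 1, end = 3, frame = 0)
  cl2 <- classify_sites(lc2, cds)
  expect_equal(cl2$sites$syn_frac, c(0, 0, 1 / 3))
  expect_equal(cl2$n_syn + cl2$n_nonsyn, 3)

  # TGG (Trp): every single-base change is nonsynonymous or a stop
  lc3 <- locus_alignment(c(a = "TGG", b = "TGG"), name = "toy")
  cl3 <- classify_sites(lc3, cds)
  expect_equal(cl3$n_syn, 0)

  # internal stop codon in the reference frame is an annotation error
  lc4 <- locus_alignment(c(a = "TAAAAA", b = "TAAAAA"), name = "toy")
  expect_error(classify_sites(lc4, data.frame(locus = "toy", start = 1,
                                              end = 6, frame = 0)),
               "stop codon")
})

test_that("synthetic study-like export re-reads byte-identically", {
  ds <- generate_study_like_dataset(seed = 3)
  dir <- withr::local_tempdir()
  paths <- write_multilocus_fasta(ds, dir)
  fasta <- paths[-length(paths)]
  ds2 <- read_multilocus_fasta(fasta, paths[length(paths)])
  for (nm in names(ds$loci))
    expect_identical(unclass(ds$loci[[nm]])[, ], unclass(ds2$loci[[nm]])[, ])
})
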