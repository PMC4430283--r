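# brute-force Steiner check: minimal spanning length over observed nodes
# plus any subset of candidate median points
steiner_best <- function(cm, candidates) {
  best <- saltmigrate:::mst_length(saltmigrate:::ham_dist(cm, rep(1, ncol(cm))))
  n_cand <- nrow(candidates)
  for (mask in seq_len(2^n_cand) - 1) {
    sel <- which(bitwAnd(mask, 2^(seq_len(n_cand) - 1)) > 0)
    if (!length(sel)) next
    cm2 <- rbind(cm, candidates[sel, , drop = FALSE])
    rownames(cm2) <- c(rownames(cm), paste0("x", sel))
    best <- min(best, saltmigrate:::mst_length(
      saltmigrate:::ham_dist(cm2, rep(1, ncol(cm2)))))
  }
  best
}

toy_table <- function(seqs, counts = NULL) {
  if (is.null(counts)) counts <- rep(1, length(seqs))
  expanded <- rep(seqs, counts)
  lc <- locus_alignment(setNames(expanded, paste0("i", seq_along(expanded))))
  collapse_haplotypes(lc)
}

test_that("two haplotypes give a single weighted edge and no medians", {
  tab <- toy_table(c("AAA", "TTT"))
  net <- median_joining(tab)
  expect_equal(nrow(net$edges), 1L)
  expect_equal(net$edges$weight, 3)
  expect_false(any(net$nodes$is_median))
})

test_that("the {000,011,101} triple gains its Steiner median", {
  # encoded as bases: 0 -> A, 1 -> T
  tab <- toy_table(c("AAA", "ATT", "TAT"))
  net <- median_joining(tab)
  med <- net$char_matrix[net$nodes$node[net$nodes$is_median], , drop = FALSE]
  expect_equal(nrow(med), 1L)
  expect_equal(unname(med[1, ]), c("A", "A", "T"))  # the 001 median
  expect_equal(net$length, 3)
  # brute force over all 8 points of {A,T}^3 confirms the optimum
  cand <- as.matrix(expand.grid(c("A", "T"), c("A", "T"), c("A", "T"),
                                stringsAsFactors = FALSE))
  colnames(cand) <- NULL
  cm_obs <- attr(tab, "char_matrix")
  expect_equal(steiner_best(cm_obs, cand), 3)
  # every observed haplotype is one step from the median
  expect_true(all(net$edges$weight == 1))
})

test_that("a star of singletons around a frequent centre needs no medians", {
  centre <- "AAAAAA"
  rad <- c("TAAAAA", "ATAAAA", "AATAAA", "AAATAA")
  tab <- toy_table(c(centre, rad), counts = c(10, 1, 1, 1, 1))
  net <- median_joining(tab)
  expect_false(any(net$nodes$is_median))
  expect_equal(nrow(net$edges), 4L)
  expect_true(all(net$edges$weight == 1))
  centre_id <- net$nodes$node[which.max(net$nodes$frequency)]
  expect_true(all(net$edges$from == centre_id | net$edges$to == centre_id))
})

test_that("the network is connected, spans all haplotypes, and is deterministic", {
  set.seed(13)
  for (rep in 1:5) {
    mat <- random_alignment(10, 15, n_var = 5)
    tab <- collapse_haplotypes(make_locus(mat))
    net1 <- median_joining(tab)
    net2 <- median_joining(tab)
    expect_identical(net1$edges, net2$edges)
    expect_true(all(tab$haplotype %in% net1$nodes$node))
    expect_true(all(net1$edges$weight >= 1))
    # connectivity via reachability over the edge list
    adj <- net1$edges
    nodes <- net1$nodes$node
    reach <- nodes[1]
    repeat {
      nxt <- unique(c(reach, adj$to[adj$from %in% reach],
                      adj$from[adj$to %in% reach]))
      if (length(nxt) == length(reach)) break
      reach <- nxt
    }
    expect_setequal(reach, nodes)
    # the MJ network contains a minimum spanning tree of the final node set
    d <- saltmigrate:::ham_dist(net1$char_matrix, rep(1, ncol(net1$char_matrix)))
    mst <- saltmigrate:::mst_edges(d)
    mst_pairs <- paste(pmin(rownames(d)[mst[, 1]], rownames(d)[mst[, 2]]),
                       pmax(rownames(d)[mst[, 1]], rownames(d)[mst[, 2]]))
    net_pairs <- paste(pmin(net1$edges$from, net1$edges$to),
                       pmax(net1$edges$from, net1$edges$to))
    expect_true(all(mst_pairs %in% net_pairs))
  }
})

test_that("network export writes node frequencies and per-population counts", {
  ds <- generate_toy(list(loc = c("AAT", "AAT", "GAT", "GCT")),
                     populations = c("p1", "p1", "p2", "p2"))
  tab <- collapse_haplotypes(ds$loci$loc, pop_map = ds$pop_map)
  net <- median_joining(tab)
  dir <- withr::local_tempdir()
  write_network_tsv(net, file.path(dir, "e.tsv"), file.path(dir, "n.tsv"))
  nodes <- utils::read.delim(file.path(dir, "n.tsv"))
  expect_true(all(c("node", "frequency", "p1", "p2") %in% names(nodes)))
  expect_equal(sum(nodes$frequency), 4)
})
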