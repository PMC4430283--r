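ham_dist <- function(cm, weights) {
  k <- nrow(cm)
  d <- matrix(0, k, k, dimnames = list(rownames(cm), rownames(cm)))
  for (a in seq_len(k)) for (b in seq_len(k)) if (a < b) {
    dd <- sum(weights[cm[a, ] != cm[b, ]])
    d[a, b] <- d[b, a] <- dd
  }
  d
}

# union-find
uf_new <- function(k) seq_len(k)
uf_find <- function(uf, x) { while (uf[x] != x) x <- uf[x]; x }
uf_union <- function(uf, a, b) { uf[uf_find(uf, a)] <- uf_find(uf, b); uf }

# edges ordered by (weight, from, to) with lexicographic node-id tie-break
edge_order <- function(d) {
  k <- nrow(d)
  idx <- which(upper.tri(d), arr.ind = TRUE)
  ord <- order(d[idx], rownames(d)[idx[, 1]], colnames(d)[idx[, 2]])
  idx[ord, , drop = FALSE]
}

mst_edges <- function(d) {
  idx <- edge_order(d)
  uf <- uf_new(nrow(d))
  keep <- logical(nrow(idx))
  for (r in seq_len(nrow(idx))) {
    a <- idx[r, 1]; b <- idx[r, 2]
    if (uf_find(uf, a) != uf_find(uf, b)) {
      keep[r] <- TRUE
      uf <- uf_union(uf, a, b)
    }
  }
  idx[keep, , drop = FALSE]
}

mst_length <- function(d) sum(d[mst_edges(d)])

# epsilon-relaxed minimum spanning network: an edge is kept iff its weight
# does not exceed the connectivity threshold of its endpoints plus epsilon
msn_edges <- function(d, epsilon = 0) {
  k <- nrow(d)
  idx <- which(upper.tri(d), arr.ind = TRUE)
  w <- d[idx]
  classes <- sort(unique(w))
  conn <- matrix(Inf, k, k)  # connectivity threshold per pair
  uf <- uf_new(k)
  for (cl in classes) {
    sel <- which(w == cl)
    for (r in sel) {
      a <- idx[r, 1]; b <- idx[r, 2]
      # record threshold for all pairs that become connected at this class
      if (uf_find(uf, a) != uf_find(uf, b)) uf <- uf_union(uf, a, b)
    }
    roots <- vapply(seq_len(k), function(x) uf_find(uf, x), integer(1))
    newly <- outer(roots, roots, "==") & !is.finite(conn)
    conn[newly] <- cl
  }
  keep <- w <= conn[idx] + epsilon
  idx[keep, , drop = FALSE]
}

majority_median <- function(cm, trip) {
  apply(cm[trip, , drop = FALSE], 2, function(s) {
    tb <- table(s)
    if (max(tb) == 1) s[1] else names(tb)[which.max(tb)]
  })
}

#' Median-joining haplotype network
#'
#' Builds a median-joining network over the recoded mutational characters
#' of a haplotype table: iteratively augments the epsilon-relaxed minimum
#' spanning network with majority-consensus (median) vectors of connected
#' triples whenever they shorten the network, prunes medians that no
#' longer help, and returns the final spanning network. Median vectors have
#' frequency 0. Deterministic: ties are broken by lexicographic node id.
#'
#' @param table A [collapse_haplotypes()] result (with its `char_matrix`).
#' @param epsilon Non-negative relaxation parameter (default 0, the usual
#'   program default).
#' @param character_weights Optional per-character weights (default 1;
#'   indel and inversion characters count one step).
#' @return Object of class `haplotype_network`: list with `nodes` (tibble:
#'   `node`, `frequency`, `is_median`), `edges` (tibble: `from`, `to`,
#'   `weight`), `length` (total spanning length) and the final character
#'   matrix. Per-population frequencies are carried over when present.
#' @export
median_joining <- function(table, epsilon = 0, character_weights = NULL) {
  cm <- attr(table, "char_matrix")
  if (is.null(cm)) stop("haplotype table lacks a character matrix")
  freq <- setNames(table$count, table$haplotype)
  if (is.null(character_weights)) character_weights <- rep(1, ncol(cm))
  n_obs <- nrow(cm)
  guard <- 10 * n_obs
  n_median <- 0

  if (nrow(cm) == 1L) {
    net <- list(nodes = tibble(node = rownames(cm), frequency = unname(freq),
                               is_median = FALSE),
                edges = tibble(from = character(), to = character(),
                               weight = numeric()),
                length = 0, char_matrix = cm)
    return(structure(net, class = "haplotype_network",
                     pop_counts = attr(table, "pop_counts")))
  }

  repeat {
    d <- ham_dist(cm, character_weights)
    base_len <- mst_length(d)
    me <- msn_edges(d, epsilon)
    # candidate medians from triples with at least two links among them
    adj <- matrix(FALSE, nrow(cm), nrow(cm))
    adj[me] <- TRUE
    adj <- adj | t(adj)
    best <- NULL
    k <- nrow(cm)
    for (u in seq_len(k)) for (v in seq_len(k)) for (w2 in seq_len(k)) {
      if (u >= v || v >= w2) next
      if (sum(adj[u, v], adj[u, w2], adj[v, w2]) < 2) next
      med <- majority_median(cm, c(u, v, w2))
      if (any(apply(cm, 1, function(r) all(r == med)))) next
      cm2 <- rbind(cm, med)
      rownames(cm2)[k + 1] <- "cand"
      len2 <- mst_length(ham_dist(cm2, character_weights))
      if (len2 < base_len - 1e-9 && (is.null(best) || len2 < best$len))
        best <- list(med = med, len = len2)
    }
    if (is.null(best)) break
    n_median <- n_median + 1
    if (n_median > guard) stop("median-vector runaway: more than ",
                               guard, " medians generated")
    cm <- rbind(cm, best$med)
    rownames(cm)[nrow(cm)] <- paste0("mv", n_median)
  }

  # prune medians whose removal leaves the spanning length unchanged
  repeat {
    d <- ham_dist(cm, character_weights)
    len <- mst_length(d)
    medians <- setdiff(rownames(cm), names(freq))
    drop <- NULL
    for (m in medians) {
      keep <- setdiff(rownames(cm), m)
      if (mst_length(ham_dist(cm[keep, , drop = FALSE],
                              character_weights)) <= len + 1e-9) {
        drop <- m
        break
      }
    }
    if (is.null(drop)) break
    cm <- cm[setdiff(rownames(cm), drop), , drop = FALSE]
  }

  d <- ham_dist(cm, character_weights)
  me <- msn_edges(d, epsilon)
  edges <- tibble(from = rownames(cm)[me[, 1]], to = rownames(cm)[me[, 2]],
                  weight = d[me])
  nodes <- tibble(node = rownames(cm),
                  frequency = unname(freq[rownames(cm)]),
                  is_median = !rownames(cm) %in% names(freq))
  nodes$frequency[is.na(nodes$frequency)] <- 0L
  structure(list(nodes = nodes, edges = edges, length = mst_length(d),
                 char_matrix = cm),
            class = "haplotype_network", pop_counts = attr(table, "pop_counts"))
}

#' @export
print.haplotype_network <- function(x, ...) {
  cat("<haplotype_network> ", nrow(x$nodes), " nodes (",
      sum(x$nodes$is_median), " median vectors), ", nrow(x$edges),
      " edges, total length ", x$length, "\n", sep = "")
  invisible(x)
}

#' @export
tidy.haplotype_network <- function(x, ...) x$edges

#' Write a haplotype network as edge-list and node-table TSVs
#'
#' @param network A [median_joining()] result.
#' @param edge_path,node_path Output paths.
#' @return Invisibly the two paths.
#' @export
write_network_tsv <- function(network, edge_path, node_path) {
  utils::write.table(network$edges, edge_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  nodes <- network$nodes
  pc <- attr(network, "pop_counts")
  if (!is.null(pc)) {
    pc_tb <- as_tibble(as.data.frame.matrix(pc), rownames = "node")
    nodes <- left_join(nodes, pc_tb, by = "node")
  }
  utils::write.table(nodes, node_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(edge_path, node_path))
}
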