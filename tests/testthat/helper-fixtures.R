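# Shared in-code fixtures for the test suite.

toy_psm <- function() {
  counts <- matrix(c(5L, 0L, 3L,
                     8L, 1L, 0L,
                     2L, 2L, 2L,
                     7L, 4L, 1L), nrow = 3,
                   dimnames = list(c("TWIST1", "CHD7", "HSPA8"),
                                   c("bait_1", "bait_2", "control_1",
                                     "control_2")))
  psm_matrix(counts, c("bait", "bait", "control", "control"), c(1L, 2L, 1L, 2L))
}

# Erdos-Renyi weighted graph with scores above the construction cutoff.
random_network <- function(n = 30, p = 0.15, seed = 1) {
  set.seed(seed)
  pair <- t(utils::combn(n, 2))
  keep <- stats::runif(nrow(pair)) < p
  df <- data.frame(protein1 = sprintf("N%03d", pair[keep, 1]),
                   protein2 = sprintf("N%03d", pair[keep, 2]),
                   combined_score = stats::runif(sum(keep), 0.41, 1))
  prune_unconnected(functional_network(df))
}

triangle_pair <- function() {
  functional_network(data.frame(
    protein1 = c("A", "B", "C", "X", "Y", "Z"),
    protein2 = c("B", "C", "A", "Y", "Z", "X"),
    combined_score = c(0.9, 0.8, 0.7, 0.9, 0.8, 0.7)))
}

# Reference BH adjustment, written independently of stats::p.adjust:
# adj_(i) = min_{j >= i} min(1, p_(j) * n / j) on the sorted p-values.
bh_reference <- function(p) {
  n <- length(p)
  ord <- order(p)
  adj_sorted <- rev(cummin(rev(pmin(1, p[ord] * n / seq_len(n)))))
  adj <- numeric(n)
  adj[ord] <- adj_sorted
  adj
}

# Plain breadth-first search distances from one source, adjacency-list based;
# independent of igraph's shortest-path machinery.
bfs_distances <- function(adj, src) {
  dist <- stats::setNames(rep(Inf, length(adj)), names(adj))
  dist[src] <- 0
  queue <- src
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    for (w in adj[[v]]) {
      if (is.infinite(dist[w])) {
        dist[w] <- dist[v] + 1
        queue <- c(queue, w)
      }
    }
  }
  dist
}

as_adjlist <- function(g) {
  nodes <- igraph::V(g)$name
  el <- igraph::as_edgelist(g)
  adj <- stats::setNames(lapply(nodes, function(v)
    sort(c(el[el[, 1] == v, 2], el[el[, 2] == v, 1]))), nodes)
  adj
}

# Partition as an order-free canonical set of member sets: each set sorted,
# sets ordered by size (decreasing) then by their smallest member.
partition_sets <- function(membership) {
  sets <- unname(lapply(split(names(membership), membership), sort))
  first <- vapply(sets, `[[`, "", 1L)
  sets[order(-lengths(sets), first)]
}
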