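#' Remove unconnected nodes from a network
#'
#' @param network igraph graph.
#' @return The graph with all degree-0 nodes removed; edges unchanged.
#' @export
prune_unconnected <- function(network) {
  igraph::delete_vertices(network, which(igraph::degree(network) == 0))
}

# Column-stochastic flow matrix for MCL: weighted adjacency with a self-loop
# on each node equal to its maximum incident edge weight (standard
# regularization preventing period-2 oscillation), columns scaled to sum 1.
mcl_flow_matrix <- function(network) {
  A <- as.matrix(igraph::as_adjacency_matrix(network, attr = "weight",
                                             sparse = TRUE))
  loops <- apply(A, 1L, max)
  loops[loops == 0] <- 1          # isolated node: inert unit self-loop
  diag(A) <- loops
  sweep(A, 2L, colSums(A), `/`)
}

# One MCL iteration: expansion (matrix square), inflation (elementwise power
# + column renormalization), then pruning of entries below tol followed by a
# final renormalization.
mcl_step <- function(M, inflation, prune_tol) {
  M <- M %*% M
  M <- M^inflation
  M <- sweep(M, 2L, colSums(M), `/`)
  M[M < prune_tol] <- 0
  cs <- colSums(M)
  zero <- cs == 0
  if (any(zero)) {                # pruned an entire column: pin to itself
    M[cbind(which(zero), which(zero))] <- 1
    cs[zero] <- 1
  }
  sweep(M, 2L, cs, `/`)
}

# Read clusters off a converged MCL matrix. Attractors are nodes with mass on
# their own diagonal; attractor systems are connected sets of attractors, and
# every column is assigned to the system holding the largest share of its
# flow (ties to the smaller system id).
mcl_interpret <- function(M, nodes) {
  attr_idx <- which(diag(M) > 0)
  if (!length(attr_idx)) attr_idx <- which(rowSums(M) > 0)
  sub <- (M[attr_idx, attr_idx, drop = FALSE] > 0) |
    t(M[attr_idx, attr_idx, drop = FALSE] > 0)
  gs <- igraph::graph_from_adjacency_matrix(sub, mode = "undirected",
                                            diag = FALSE)
  sys_of_attr <- igraph::components(gs)$membership
  n_sys <- max(sys_of_attr)
  membership <- integer(ncol(M))
  for (j in seq_len(ncol(M))) {
    mass <- vapply(seq_len(n_sys), function(s) {
      sum(M[attr_idx[sys_of_attr == s], j])
    }, 0)
    if (all(mass == 0)) {         # no attractor reaches it: own singleton
      membership[j] <- NA_integer_
    } else {
      membership[j] <- which(mass == max(mass))[1L]
    }
  }
  if (anyNA(membership)) {
    extra <- seq(n_sys + 1L, n_sys + sum(is.na(membership)))
    membership[is.na(membership)] <- extra
  }
  stats::setNames(membership, nodes)
}

# Renumber a membership vector so cluster ids run 0, 1, ... by decreasing
# size, ties broken by the lexicographically smallest member symbol.
renumber_clusters <- function(membership) {
  ids <- unique(membership)
  size <- vapply(ids, function(k) sum(membership == k), 0L)
  first <- vapply(ids, function(k) min(names(membership)[membership == k]), "")
  ord <- ids[order(-size, first)]
  new <- match(membership, ord) - 1L
  stats::setNames(new, names(membership))
}

#' Markov clustering (MCL) of a weighted functional network
#'
#' Emulates random walks over the association network: the weighted adjacency
#' matrix (association scores as flow capacities, plus regularizing
#' self-loops) is column-normalized into a stochastic flow matrix, then
#' expansion (matrix squaring) and inflation (elementwise power with
#' renormalization) alternate, with pruning of negligible entries, until the
#' flow matrix is idempotent. Clusters are the attractor systems of the
#' limiting matrix.
#'
#' @param network weighted igraph graph (prune unconnected nodes first).
#' @param inflation inflation exponent (> 1); larger values give finer
#'   clusters. Default 2.
#' @param prune_tol entries below this are dropped after each iteration.
#' @param max_iter iteration cap; non-convergence yields a warning and the
#'   clusters of the final matrix, with `converged = FALSE`.
#' @return Object of class `cluster_assignment`: list with `membership`
#'   (named integer vector, ids consecutive from 0 ordered by decreasing
#'   cluster size, ties by smallest member symbol), `clusters` (list of
#'   member vectors), `converged`, `n_iter`, and an empty `annotations` slot.
#' @export
mcl_cluster <- function(network, inflation = 2, prune_tol = 1e-5,
                        max_iter = 200L) {
  if (igraph::vcount(network) == 0L) stop("network is empty")
  if (inflation <= 1) stop("inflation must be > 1")
  if (is.null(igraph::E(network)$weight))
    igraph::E(network)$weight <- 1
  nodes <- igraph::V(network)$name
  M <- mcl_flow_matrix(network)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    M_new <- mcl_step(M, inflation, prune_tol)
    if (max(abs(M_new - M)) < 1e-8) {
      M <- M_new
      converged <- TRUE
      break
    }
    M <- M_new
  }
  if (!converged)
    warning("MCL did not reach an idempotent matrix in ", max_iter,
            " iterations; returning clusters of the final matrix")
  membership <- renumber_clusters(mcl_interpret(M, nodes))
  cluster_assignment(membership, converged = converged, n_iter = iter)
}

#' Construct a cluster assignment
#'
#' @param membership named integer vector node -> cluster id.
#' @param converged,n_iter bookkeeping from the clustering run.
#' @return `cluster_assignment` object; ids are renumbered to the canonical
#'   order (decreasing size, ties by smallest member symbol, consecutive
#'   from 0).
#' @export
cluster_assignment <- function(membership, converged = TRUE, n_iter = NA_integer_) {
  membership <- renumber_clusters(membership)
  ids <- sort(unique(membership))
  clusters <- lapply(ids, function(k) sort(names(membership)[membership == k]))
  names(clusters) <- as.character(ids)
  structure(list(membership = membership, clusters = clusters,
                 converged = converged, n_iter = n_iter,
                 annotations = list()),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  sizes <- lengths(x$clusters)
  cat(sprintf("cluster_assignment: %d nodes in %d clusters (sizes %s)%s\n",
              length(x$membership), length(x$clusters),
              paste(sizes, collapse = ", "),
              if (isTRUE(x$converged)) "" else " [not converged]"))
  invisible(x)
}

#' Write cluster membership as TSV
#'
#' @param clusters a `cluster_assignment`.
#' @param path output path; columns `node`, `cluster_id`.
#' @export
write_clusters <- function(clusters, path) {
  df <- data.frame(node = names(clusters$membership),
                   cluster_id = unname(clusters$membership))
  df <- df[order(df$cluster_id, df$node), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Per-node topology metrics
#'
#' Degree (edge count), average shortest path length (mean hop distance to
#' the nodes reachable from each node) and closeness centrality, defined as
#' (number of reachable nodes) / (sum of hop distances to them). All metrics
#' are computed on the unweighted skeleton, within each node's connected
#' component.
#'
#' @param network igraph graph (pruned).
#' @return Data frame with columns `node`, `degree`, `avg_shortest_path`,
#'   `closeness`.
#' @export
topology_metrics <- function(network) {
  d <- igraph::distances(network, weights = NA)
  diag(d) <- Inf                      # exclude self from reachability
  reach <- is.finite(d)
  n_reach <- rowSums(reach)
  sum_d <- rowSums(ifelse(reach, d, 0))
  data.frame(node = igraph::V(network)$name,
             degree = unname(igraph::degree(network)),
             avg_shortest_path = ifelse(n_reach > 0, sum_d / n_reach, NA_real_),
             closeness = ifelse(n_reach > 0, n_reach / sum_d, 0),
             row.names = NULL)
}
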