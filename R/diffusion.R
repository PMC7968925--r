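#' Heat diffusion of phenotype seeds over a functional network
#'
#' Seeds carry an initial heat (default 1) that propagates to network
#' neighbors under the Laplacian heat kernel: `h(t) = exp(-L t) h0`, with
#' `L = D - W` the weighted combinatorial graph Laplacian (association scores
#' as conductances). Total heat is conserved, so the scores remain comparable
#' across diffusion times. Nodes are ranked by descending heat at time `t`,
#' ties broken lexicographically by symbol.
#'
#' For graphs of up to `eig_max_nodes` nodes the kernel is applied through a
#' symmetric eigendecomposition of `L`; beyond that a step-doubling
#' (scaling-and-squaring) Taylor series evaluation of `exp(-L t)` is used.
#'
#' @param network weighted igraph graph.
#' @param seeds named numeric vector of initial heats (e.g. from
#'   [read_seeds()]). Seeds absent from the network are dropped with a
#'   warning; if none remain, that is an error.
#' @param t diffusion time, dimensionless, `>= 0`. Default 0.25.
#' @param normalized use the symmetrically normalized Laplacian
#'   `D^-1/2 L D^-1/2` instead of the combinatorial one (heat is then not
#'   conserved). Off by default.
#' @param eig_max_nodes crossover size between the eigendecomposition and the
#'   series method.
#' @return Object of class `diffusion_result`: data frame with columns
#'   `node`, `heat`, `rank` (1 = hottest), `is_seed`, sorted by rank, with
#'   the diffusion time in attribute `"t"`.
#' @export
heat_diffuse <- function(network, seeds, t = 0.25, normalized = FALSE,
                         eig_max_nodes = 5000L) {
  stopifnot(t >= 0)
  nodes <- igraph::V(network)$name
  missing <- setdiff(names(seeds), nodes)
  if (length(missing) == length(seeds))
    stop("no seed overlaps the network; missing seeds: ",
         paste(missing, collapse = ", "))
  if (length(missing))
    warning("seeds absent from the network were dropped: ",
            paste(missing, collapse = ", "))
  seeds <- seeds[setdiff(names(seeds), missing)]
  if (any(seeds <= 0)) stop("initial seed heat must be > 0")
  h0 <- stats::setNames(numeric(length(nodes)), nodes)
  h0[names(seeds)] <- seeds
  L <- graph_laplacian(network, normalized = normalized)
  h <- kernel_apply(L, h0, t, eig_max_nodes)
  h <- pmax(h, 0)                      # clip eigendecomposition round-off
  ord <- order(-h, nodes)
  res <- data.frame(node = nodes[ord], heat = unname(h[ord]),
                    rank = seq_along(nodes),
                    is_seed = nodes[ord] %in% names(seeds),
                    row.names = NULL)
  structure(res, class = c("diffusion_result", "data.frame"), t = t)
}

graph_laplacian <- function(network, normalized = FALSE) {
  if (is.null(igraph::E(network)$weight))
    igraph::E(network)$weight <- 1
  W <- as.matrix(igraph::as_adjacency_matrix(network, attr = "weight",
                                             sparse = TRUE))
  L <- diag(rowSums(W), nrow(W)) - W
  if (normalized) {
    d <- rowSums(W)
    s <- ifelse(d > 0, 1 / sqrt(d), 0)
    L <- L * tcrossprod(s)
  }
  dimnames(L) <- list(igraph::V(network)$name, igraph::V(network)$name)
  L
}

kernel_apply <- function(L, h0, t, eig_max_nodes = 5000L) {
  n <- nrow(L)
  if (t == 0 || n == 1L) return(h0)
  if (n <= eig_max_nodes) {
    eig <- eigen(L, symmetric = TRUE)
    h <- eig$vectors %*% (exp(-eig$values * t) * crossprod(eig$vectors, h0))
  } else {
    h <- expm_series_apply(-L * t, h0)
  }
  stats::setNames(as.numeric(h), names(h0))
}

# exp(A) %*% v by step-doubling: scale A by 2^s until its 1-norm is small,
# sum the Taylor series of the scaled exponential to machine tolerance, then
# square the matrix s times.
expm_series_apply <- function(A, v) {
  nrm <- max(colSums(abs(A)))
  s <- max(0L, ceiling(log2(max(nrm, 1e-300))) + 1L)
  As <- A / 2^s
  E <- diag(nrow(A))
  term <- diag(nrow(A))
  for (k in 1:40) {
    term <- (term %*% As) / k
    E <- E + term
    if (max(abs(term)) < 1e-18) break
  }
  for (i in seq_len(s)) E <- E %*% E
  as.numeric(E %*% v)
}

#' Rank candidate interactors by diffusion heat
#'
#' Restricts a diffusion result to the called candidates, re-ranks them by
#' heat (ties lexicographic) and returns the top slice, optionally annotated
#' with cluster membership and specificity class.
#'
#' @param diffusion a [heat_diffuse()] result.
#' @param candidates character vector of candidate protein ids.
#' @param top_k number of top-ranked candidates to return (default 30).
#' @param clusters optional `cluster_assignment` supplying a `cluster_id`
#'   column.
#' @param specificity optional named class vector (from
#'   [annotate_specificity()]) supplying a `specificity` column.
#' @return Data frame of at most `top_k` rows: `node`, `heat`, `rank`
#'   (within candidates), `network_rank`, `is_seed`, plus optional
#'   annotation columns. Candidates absent from the network are reported in
#'   attribute `"missing"` (and a warning).
#' @export
rank_candidates <- function(diffusion, candidates, top_k = 30L,
                            clusters = NULL, specificity = NULL) {
  missing <- setdiff(candidates, diffusion$node)
  if (length(missing))
    warning("candidates absent from the network were excluded: ",
            paste(missing, collapse = ", "))
  sub <- diffusion[diffusion$node %in% candidates, , drop = FALSE]
  sub <- sub[order(-sub$heat, sub$node), , drop = FALSE]
  names(sub)[names(sub) == "rank"] <- "network_rank"
  sub$rank <- seq_len(nrow(sub))
  sub <- sub[, c("node", "heat", "rank", "network_rank", "is_seed")]
  if (!is.null(clusters))
    sub$cluster_id <- unname(clusters$membership[sub$node])
  if (!is.null(specificity))
    sub$specificity <- unname(specificity[sub$node])
  out <- utils::head(sub, top_k)
  rownames(out) <- NULL
  attr(out, "missing") <- missing
  out
}

#' Classify candidates against a specificity reference
#'
#' Looks each candidate up in a reference derived from a bait/control
#' interaction survey. Candidates in the reference keep their surveyed class
#' (`"specific"` or `"nonspecific"`); candidates the survey never observed
#' are labeled `"unobserved"` — the potential new interactors.
#'
#' @param candidates character vector of protein ids.
#' @param reference named character vector protein -> class (from
#'   [read_specificity()]).
#' @return Named character vector candidate -> class.
#' @export
annotate_specificity <- function(candidates, reference) {
  cls <- reference[candidates]
  cls[is.na(cls)] <- "unobserved"
  stats::setNames(as.character(cls), candidates)
}

#' Drop clusters dominated by non-specific interactors
#'
#' Background-binding proteins (heat-shock, cytoskeleton, ...) co-cluster;
#' clusters whose fraction of `"nonspecific"` members exceeds
#' `max_nonspecific_frac` are removed and the survivors renumbered
#' deterministically.
#'
#' @param clusters a `cluster_assignment`.
#' @param annotations named class vector covering every clustered node
#'   (see [annotate_specificity()]).
#' @param max_nonspecific_frac drop threshold on the nonspecific member
#'   fraction (strict `>`). Default 0.5 (majority rule).
#' @return A `cluster_assignment` over the retained nodes; dropped cluster
#'   memberships are kept in attribute `"dropped"`.
#' @export
exclude_nonspecific_clusters <- function(clusters, annotations,
                                         max_nonspecific_frac = 0.5) {
  nodes <- names(clusters$membership)
  un <- setdiff(nodes, names(annotations))
  if (length(un))
    stop("clustered nodes lack a specificity annotation: ",
         paste(utils::head(un, 5L), collapse = ", "))
  drop <- vapply(clusters$clusters, function(members) {
    mean(annotations[members] == "nonspecific") > max_nonspecific_frac
  }, NA)
  dropped <- unlist(clusters$clusters[drop], use.names = FALSE)
  keep <- clusters$membership[!nodes %in% dropped]
  if (!length(keep)) stop("all clusters were excluded as non-specific")
  out <- cluster_assignment(keep, converged = clusters$converged,
                            n_iter = clusters$n_iter)
  attr(out, "dropped") <- dropped
  out
}

#' Resampling-based gene-set over-representation
#'
#' For each category, compares the observed overlap with a target set against
#' a null distribution of overlaps obtained by drawing size-matched uniform
#' random sets from the universe. The p-value uses the add-one permutation
#' estimator `p = (1 + #{null >= observed}) / (n_resamples + 1)`, which is
#' never exactly zero.
#'
#' @param target_set character vector, subset of `universe`.
#' @param categories named list of character vectors (e.g. [read_gmt()]);
#'   each is intersected with the universe before counting.
#' @param universe character vector of all eligible symbols.
#' @param n_resamples number of null draws (default 10000).
#' @param sampler_seed integer seed for the sampler (scoped: the caller's RNG
#'   state is restored on exit).
#' @return Data frame of class `enrichment_result`: `category`, `overlap`,
#'   `p`, `n_resamples`, `seed`.
#' @export
resampling_enrichment <- function(target_set, categories, universe,
                                  n_resamples = 10000L, sampler_seed = 1L) {
  universe <- unique(universe)
  target_set <- unique(target_set)
  outside <- setdiff(target_set, universe)
  if (length(outside))
    stop("target_set members outside the universe: ",
         paste(utils::head(outside, 5L), collapse = ", "))
  if (length(target_set) > length(universe))
    stop("target_set larger than the universe")
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(sampler_seed)
  k <- length(target_set)
  n_u <- length(universe)
  draws <- replicate(n_resamples, sample.int(n_u, k))
  rows <- lapply(names(categories), function(nm) {
    cat_u <- which(universe %in% categories[[nm]])
    observed <- length(intersect(target_set, universe[cat_u]))
    in_cat <- matrix(draws %in% cat_u, nrow = k)
    null_overlap <- colSums(in_cat)
    p <- (1 + sum(null_overlap >= observed)) / (n_resamples + 1)
    data.frame(category = nm, overlap = observed, p = p,
               n_resamples = n_resamples, seed = sampler_seed)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("enrichment_result", "data.frame"))
}
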