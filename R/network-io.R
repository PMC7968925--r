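#' Build a functional association network from a scored edge table
#'
#' @param edges data frame with columns `protein1`, `protein2`,
#'   `combined_score` (STRING-style combined association confidence in (0,1]).
#' @param score_cutoff edges with score strictly greater than this are kept
#'   (intermediate-confidence default 0.4).
#' @return An undirected [igraph][igraph::graph_from_data_frame] graph with a
#'   `weight` edge attribute. Self-edges are dropped; reciprocal duplicate
#'   pairs are merged keeping the maximum score.
#' @export
functional_network <- function(edges, score_cutoff = 0.4) {
  edges <- as.data.frame(edges)
  names(edges)[1:3] <- c("protein1", "protein2", "combined_score")
  s <- edges$combined_score
  bad <- which(!is.finite(s) | s <= 0 | s > 1)
  if (length(bad))
    stop(sprintf("combined_score outside (0,1] at row %d (value %s)",
                 bad[1L], format(s[bad[1L]])))
  edges <- edges[edges$protein1 != edges$protein2, , drop = FALSE]
  edges <- edges[edges$combined_score > score_cutoff, , drop = FALSE]
  if (nrow(edges)) {
    a <- pmin(edges$protein1, edges$protein2)
    b <- pmax(edges$protein1, edges$protein2)
    key <- paste(a, b, sep = "\r")
    w <- tapply(edges$combined_score, key, max)
    pair <- do.call(rbind, strsplit(names(w), "\r", fixed = TRUE))
    edges <- data.frame(protein1 = pair[, 1L], protein2 = pair[, 2L],
                        combined_score = as.numeric(w))
    edges <- edges[order(edges$protein1, edges$protein2), , drop = FALSE]
  }
  g <- igraph::graph_from_data_frame(edges[, 1:2], directed = FALSE)
  igraph::E(g)$weight <- edges$combined_score
  g
}

#' Read a STRING-dialect weighted edge list
#'
#' Expects a tab-separated file with header `protein1  protein2
#' combined_score`, scores in (0,1]. Edges at or below `score_cutoff` are
#' dropped (the cutoff is strict, matching the usual ">0.4" intermediate-
#' confidence rule), reciprocal duplicates keep the maximum score and
#' self-edges are removed.
#'
#' @inheritParams functional_network
#' @param path path of the edge-list TSV.
#' @return An undirected weighted igraph graph.
#' @export
read_edge_list <- function(path, score_cutoff = 0.4) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE,
                           colClasses = c("character", "character", "numeric"))
  functional_network(tab, score_cutoff = score_cutoff)
}

#' Write a functional network as a 3-column TSV edge list
#'
#' @param network weighted igraph graph.
#' @param path output path.
#' @return `path`, invisibly. Rows are sorted by (protein1, protein2) with
#'   each pair in lexicographic order, so re-serialization is stable.
#' @export
write_edge_list <- function(network, path) {
  el <- igraph::as_edgelist(network)
  df <- data.frame(protein1 = pmin(el[, 1L], el[, 2L]),
                   protein2 = pmax(el[, 1L], el[, 2L]),
                   combined_score = igraph::E(network)$weight)
  df <- df[order(df$protein1, df$protein2), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a seed-gene list
#'
#' One gene symbol per line; every seed receives the same initial heat.
#'
#' @param path path of the seed file.
#' @param heat initial heat assigned to each seed (default 1).
#' @return Named numeric vector of initial heats, names = unique symbols.
#' @export
read_seeds <- function(path, heat = 1) {
  syms <- readLines(path)
  syms <- syms[nzchar(trimws(syms))]
  syms <- unique(trimws(syms))
  if (heat <= 0) stop("initial seed heat must be > 0")
  stats::setNames(rep(heat, length(syms)), syms)
}

#' @rdname read_seeds
#' @param seeds named numeric vector of seed heats.
#' @export
write_seeds <- function(seeds, path) {
  writeLines(names(seeds), path)
  invisible(path)
}

#' Read a specificity reference table
#'
#' Two-column TSV (`protein_id`, `class`) derived from a bait/control
#' interaction survey; classes are `specific` or `nonspecific`. Proteins
#' absent from the reference are treated downstream as `unobserved`
#' (potential new interactors).
#'
#' @param path path of the TSV.
#' @return Named character vector protein -> class.
#' @export
read_specificity <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character")
  bad <- setdiff(unique(tab[[2L]]), c("specific", "nonspecific"))
  if (length(bad))
    stop("unknown specificity class: ", paste(bad, collapse = ", "))
  stats::setNames(tab[[2L]], tab[[1L]])
}

#' @rdname read_specificity
#' @param reference named character vector protein -> class.
#' @export
write_specificity <- function(reference, path) {
  utils::write.table(
    data.frame(protein_id = names(reference), class = unname(reference)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' One set per line: name, description, then member symbols, tab-separated.
#'
#' @param path path of the GMT file.
#' @return Named list of character vectors (the member symbols); set
#'   descriptions are kept in the `"description"` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- vapply(parts, length, 0L) < 3L
  if (any(short))
    stop("GMT line ", which(short)[1L], " has no members")
  nm <- vapply(parts, `[[`, "", 1L)
  if (anyDuplicated(nm)) stop("duplicate gene-set names in GMT")
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- nm
  attr(sets, "description") <- stats::setNames(vapply(parts, `[[`, "", 2L), nm)
  sets
}

#' @rdname read_gmt
#' @param sets named list of character vectors.
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "description")
  if (is.null(desc)) desc <- stats::setNames(rep("na", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, desc[[nm]], sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
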