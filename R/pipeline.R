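#' Default run configuration
#'
#' All stage parameters of the pipeline with their standard values:
#' `alpha = 0.05`, `fc_min = 3`, `min_psm = 2`, `min_reps = 2`,
#' `score_cutoff = 0.4`, `inflation = 2`, `t = 0.25`, `top_k = 30`,
#' `max_nonspecific_frac = 0.5`, `n_resamples = 10000`, plus the sampler
#' seed. Input/output paths are filled by the caller.
#'
#' @param ... overrides of individual fields.
#' @return Named list of class `run_config`.
#' @export
default_config <- function(...) {
  cfg <- list(
    psm = NULL, design = NULL, edges = NULL, seeds = NULL,
    specificity = NULL, gmt = NULL, outdir = NULL,
    alpha = 0.05, fc_min = 3, min_psm = 2L, min_reps = 2L,
    score_cutoff = 0.4, inflation = 2, prune_tol = 1e-5, max_iter = 200L,
    t = 0.25, top_k = 30L, max_nonspecific_frac = 0.5,
    n_resamples = 10000L, sampler_seed = 1L,
    dispersion_method = "cr", normalized_laplacian = FALSE)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "run_config")
}

#' Write / read a run configuration as flat key=value text
#'
#' @param config a `run_config`.
#' @param path file path.
#' @return `path` (write) or the re-typed `run_config` (read); the
#'   round-trip is lossless.
#' @export
write_run_config <- function(config, path) {
  set_ <- !vapply(config, is.null, NA)
  writeLines(sprintf("%s=%s", names(config)[set_],
                     vapply(config[set_], function(v)
                       format(v, scientific = FALSE, trim = TRUE), "")),
             path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  lines <- grep("=", readLines(path), fixed = TRUE, value = TRUE)
  kv <- regmatches(lines, regexpr("=", lines, fixed = TRUE), invert = TRUE)
  vals <- stats::setNames(lapply(kv, `[[`, 2L), vapply(kv, `[[`, "", 1L))
  proto <- default_config()
  for (nm in names(vals)) {
    v <- vals[[nm]]
    proto_v <- proto[[nm]]
    vals[[nm]] <- if (is.logical(proto_v)) as.logical(v)
      else if (is.integer(proto_v)) as.integer(v)
      else if (is.numeric(proto_v)) as.numeric(v)
      else v
  }
  do.call(default_config, vals)
}

#' Run the full interactome-prioritization pipeline
#'
#' Chains every stage on the configured input files: impute missing PSM,
#' sum-normalize, detection-filter, estimate the common NB dispersion,
#' LRT per protein, BH adjustment and candidate calling, association-network
#' construction and pruning, Markov clustering, specificity annotation,
#' exclusion of nonspecific clusters, seeded heat diffusion, candidate
#' ranking, and (when category sets are supplied) resampling enrichment of
#' the top-ranked candidates. Per-stage TSVs and a JSON run manifest
#' (package version, config, and row counts of every output) are written to
#' `config$outdir`. Progress is logged to stderr with timestamped,
#' stage-tagged lines.
#'
#' @param config a [default_config()] with input paths set (`psm`, `design`,
#'   `edges`, `seeds` required; `specificity` and `gmt` optional) and
#'   `outdir` set.
#' @return The manifest list, invisibly; all stage results are attached in
#'   its `"results"` attribute.
#' @export
run_pipeline <- function(config) {
  for (f in c("psm", "design", "edges", "seeds", "outdir"))
    if (is.null(config[[f]])) stop("config field '", f, "' is required")
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  out <- function(name) file.path(config$outdir, name)
  res <- list()

  stage_log("diffexp", "reading PSM table %s", config$psm)
  psm <- impute_missing(read_psm_table(config$psm, config$design))
  norm <- sum_normalize(psm)
  detected <- filter_detected(psm, config$min_psm, config$min_reps)
  stage_log("diffexp", "%d/%d proteins pass the detection filter",
            length(detected), nrow(norm))
  norm_f <- norm[detected, , drop = FALSE]
  disp <- estimate_dispersion(norm_f, psm$condition,
                              method = config$dispersion_method)
  stage_log("diffexp", "common dispersion phi = %.4f", disp$phi)
  res$differential <- call_candidates(
    lrt_differential(norm_f, psm$condition, disp),
    alpha = config$alpha, fc_min = config$fc_min, detected = detected)
  candidates <- candidate_list(res$differential)
  stage_log("diffexp", "%d candidates at adjp < %g, FC > %g",
            length(candidates), config$alpha, config$fc_min)
  tab <- res$differential
  tab$candidate <- as.integer(tab$candidate)
  utils::write.table(tab, out("differential.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)

  stage_log("network", "reading edges %s (cutoff %g)", config$edges,
            config$score_cutoff)
  net <- prune_unconnected(read_edge_list(config$edges, config$score_cutoff))
  res$network <- net
  res$clusters <- mcl_cluster(net, inflation = config$inflation,
                              prune_tol = config$prune_tol,
                              max_iter = config$max_iter)
  stage_log("network", "%d nodes, %d edges -> %d MCL clusters",
            igraph::vcount(net), igraph::ecount(net),
            length(res$clusters$clusters))
  write_clusters(res$clusters, out("clusters.tsv"))
  res$topology <- topology_metrics(net)
  utils::write.table(res$topology, out("topology.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  nodes <- igraph::V(net)$name
  if (!is.null(config$specificity)) {
    reference <- read_specificity(config$specificity)
    res$specificity <- annotate_specificity(nodes, reference)
    res$clusters_retained <- exclude_nonspecific_clusters(
      res$clusters, res$specificity, config$max_nonspecific_frac)
    stage_log("specificity", "%d/%d clusters retained",
              length(res$clusters_retained$clusters),
              length(res$clusters$clusters))
    write_clusters(res$clusters_retained, out("clusters_retained.tsv"))
  } else {
    res$specificity <- stats::setNames(rep("unobserved", length(nodes)), nodes)
    res$clusters_retained <- res$clusters
  }

  seeds <- read_seeds(config$seeds)
  res$diffusion <- heat_diffuse(net, seeds, t = config$t,
                                normalized = config$normalized_laplacian)
  stage_log("diffuse", "heat diffused from %d seeds at t = %g",
            sum(res$diffusion$is_seed), config$t)
  res$ranked <- rank_candidates(res$diffusion, intersect(candidates, nodes),
                                top_k = config$top_k,
                                clusters = res$clusters,
                                specificity = res$specificity)
  dtab <- res$diffusion
  dtab$is_seed <- as.integer(dtab$is_seed)
  dtab$cluster_id <- unname(res$clusters$membership[dtab$node])
  dtab$specificity <- unname(res$specificity[dtab$node])
  utils::write.table(dtab, out("diffusion.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  rtab <- res$ranked
  rtab$is_seed <- as.integer(rtab$is_seed)
  utils::write.table(rtab, out("ranked_candidates.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  if (!is.null(config$gmt)) {
    sets <- read_gmt(config$gmt)
    res$enrichment <- resampling_enrichment(
      res$ranked$node, sets, universe = nodes,
      n_resamples = config$n_resamples, sampler_seed = config$sampler_seed)
    stage_log("enrich", "%d categories tested with %d resamples",
              nrow(res$enrichment), config$n_resamples)
    utils::write.table(res$enrichment, out("enrichment.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }

  write_run_config(config, out("run_config.txt"))
  outputs <- list.files(config$outdir, pattern = "\\.tsv$")
  manifest <- list(
    package = "bioidnet",
    version = as.character(utils::packageVersion("bioidnet")),
    config = config[!vapply(config, is.null, NA)],
    n_candidates = length(candidates),
    rows = stats::setNames(lapply(outputs, function(f) {
      length(readLines(file.path(config$outdir, f))) - 1L
    }), outputs))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  stage_log("done", "outputs in %s", config$outdir)
  attr(manifest, "results") <- res
  invisible(manifest)
}
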