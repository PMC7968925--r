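#' Simulate a bait/control PSM experiment with planted interactors
#'
#' Emulates the count structure of a BioID bait-versus-control design: every
#' protein's PSM count in sample `s` is drawn negative binomial with mean
#' `baseline_mean * libsize_s * fold^[planted & bait]` and dispersion `phi`
#' (variance `mu + phi mu^2`), then each cell is independently zeroed with
#' probability `zero_rate` to mimic peptides falling below detection.
#' Library-size factors are log-normal with `sdlog = libsize_sd`, emulating
#' sample-to-sample loading variation. Fully reproducible from `seed`.
#'
#' @param n_proteins total number of proteins.
#' @param n_true number of planted bait-specific interactors
#'   (`<= n_proteins`).
#' @param fold mean fold-enrichment of planted proteins in bait samples
#'   (`>= 1`).
#' @param phi NB dispersion (`>= 0`; 0 = Poisson).
#' @param baseline_mean expected PSM of an unenriched protein at unit library
#'   size.
#' @param n_bait_reps,n_control_reps replicates per condition.
#' @param zero_rate per-cell dropout probability in `[0, 1)`.
#' @param libsize_sd log-normal sdlog of the library-size factors.
#' @param seed integer seed.
#' @return List with `psm` (a [psm_matrix()]; dropout cells hold 0) and
#'   `truth`, a `psm_truth` list: `planted` symbols, `fold`, `phi`,
#'   `baseline_mean`, `libsize` (named per sample), `zero_rate`, `seed`, and
#'   the logical `dropout` mask.
#' @export
simulate_psm <- function(n_proteins = 1000L, n_true = 60L, fold = 8,
                         phi = 0.3, baseline_mean = 20,
                         n_bait_reps = 3L, n_control_reps = 3L,
                         zero_rate = 0.02, libsize_sd = 0.15, seed = 1L) {
  if (n_true > n_proteins) stop("n_true must not exceed n_proteins")
  if (fold < 1) stop("fold must be >= 1")
  if (phi < 0) stop("phi must be >= 0")
  if (zero_rate < 0 || zero_rate >= 1) stop("zero_rate must be in [0, 1)")
  if (baseline_mean <= 0) stop("baseline_mean must be > 0")
  proteins <- sprintf("P%04d", seq_len(n_proteins))
  samples <- c(sprintf("bait_%d", seq_len(n_bait_reps)),
               sprintf("control_%d", seq_len(n_control_reps)))
  condition <- rep(c("bait", "control"), c(n_bait_reps, n_control_reps))
  replicate <- c(seq_len(n_bait_reps), seq_len(n_control_reps))
  with_seed(seed, {
    planted <- sort(sample(proteins, n_true))
    libsize <- stats::setNames(stats::rlnorm(length(samples), 0, libsize_sd),
                               samples)
    mu <- outer(ifelse(proteins %in% planted, fold, 1), libsize) *
      baseline_mean
    mu[, condition == "control"] <- baseline_mean *
      rep(libsize[condition == "control"], each = n_proteins)
    draw <- if (phi == 0) {
      stats::rpois(length(mu), mu)
    } else {
      stats::rnbinom(length(mu), mu = mu, size = 1 / phi)
    }
    counts <- matrix(as.integer(draw), n_proteins,
                     dimnames = list(proteins, samples))
    dropout <- matrix(stats::runif(length(mu)) < zero_rate, n_proteins,
                      dimnames = dimnames(counts))
    counts[dropout] <- 0L
    list(
      psm = psm_matrix(counts, condition, replicate),
      truth = structure(
        list(planted = planted, fold = fold, phi = phi,
             baseline_mean = baseline_mean, libsize = libsize,
             zero_rate = zero_rate, seed = seed, dropout = dropout),
        class = "psm_truth")
    )
  })
}

#' Simulate a weighted planted-partition network with hot seeds
#'
#' Draws a stochastic block model over the supplied nodes: node pairs within
#' a block are joined with probability `p_in`, pairs across blocks with
#' `p_out`, and present edges get association scores uniform on
#' `weight_range` (above the 0.4 construction cutoff, so building the
#' network never shrinks the planted blocks). A fixed number of diffusion
#' seeds is placed inside the designated seed block; the designated
#' nonspecific block is labeled `"nonspecific"` in the returned specificity
#' reference, the rest `"specific"` except for a random `unobserved_frac`
#' left out of the reference entirely (the potential new interactors).
#'
#' @param block_sizes integer vector of block sizes.
#' @param p_in,p_out within-/between-block edge probabilities
#'   (`p_in > p_out`).
#' @param n_seeds seeds drawn from the seed block.
#' @param seed_block index of the block holding the seeds.
#' @param nonspecific_block index of the block labeled nonspecific.
#' @param weight_range range of the uniform edge-score distribution.
#' @param unobserved_frac fraction of non-nonspecific nodes missing from the
#'   specificity reference.
#' @param node_names optional node symbols (length `sum(block_sizes)`);
#'   default `G001, G002, ...`.
#' @param seed integer seed.
#' @return List: `network` (igraph, isolated nodes kept), `seeds` (named
#'   heat vector), `specificity` (named class vector), `truth`
#'   (`network_truth` list holding the generator parameters and the planted
#'   `membership`), and `truth_clusters` (the planted partition as a
#'   `cluster_assignment`).
#' @export
simulate_network <- function(block_sizes = rep(15L, 4L), p_in = 0.6,
                             p_out = 0.02, n_seeds = 3L, seed_block = 1L,
                             nonspecific_block = length(block_sizes),
                             weight_range = c(0.41, 1), unobserved_frac = 0.3,
                             node_names = NULL, seed = 1L) {
  if (p_in <= p_out) stop("p_in must exceed p_out")
  if (any(weight_range <= 0.4) || any(weight_range > 1))
    stop("weight_range must lie in (0.4, 1]")
  n <- sum(block_sizes)
  if (is.null(node_names)) node_names <- sprintf("G%03d", seq_len(n))
  if (length(node_names) != n) stop("node_names must match sum(block_sizes)")
  membership <- stats::setNames(rep(seq_along(block_sizes), block_sizes),
                                node_names)
  with_seed(seed, {
    pair <- utils::combn(n, 2L)
    same <- membership[pair[1L, ]] == membership[pair[2L, ]]
    present <- stats::runif(ncol(pair)) < ifelse(same, p_in, p_out)
    w <- stats::runif(sum(present), weight_range[1L], weight_range[2L])
    edges <- data.frame(protein1 = node_names[pair[1L, present]],
                        protein2 = node_names[pair[2L, present]],
                        combined_score = w)
    g <- functional_network(edges, score_cutoff = 0.4)
    iso <- setdiff(node_names, igraph::V(g)$name)
    if (length(iso)) g <- igraph::add_vertices(g, length(iso), name = iso)
    block_members <- split(node_names, membership)
    seeds_v <- sort(sample(block_members[[seed_block]],
                           min(n_seeds, block_sizes[seed_block])))
    nonspec <- block_members[[nonspecific_block]]
    spec_pool <- setdiff(node_names, nonspec)
    unobserved <- sample(spec_pool, round(unobserved_frac * length(spec_pool)))
    reference <- c(
      stats::setNames(rep("specific", length(spec_pool)), spec_pool),
      stats::setNames(rep("nonspecific", length(nonspec)), nonspec))
    reference <- reference[setdiff(names(reference), unobserved)]
    reference <- reference[order(names(reference))]
    list(
      network = g,
      seeds = stats::setNames(rep(1, length(seeds_v)), seeds_v),
      specificity = reference,
      truth = structure(
        list(block_sizes = as.integer(block_sizes), p_in = p_in, p_out = p_out,
             seed_block = as.integer(seed_block),
             nonspecific_block = as.integer(nonspecific_block),
             weight_range = weight_range, membership = membership,
             seeds = seeds_v, seed = seed),
        class = "network_truth"),
      truth_clusters = cluster_assignment(membership)
    )
  })
}

bundle_presets <- list(
  tiny = list(psm = list(n_proteins = 20L, n_true = 12L, fold = 8, phi = 0.3,
                         baseline_mean = 20, n_bait_reps = 2L,
                         n_control_reps = 2L, zero_rate = 0.02),
              net = list(block_sizes = rep(4L, 3L), p_in = 0.9, p_out = 0.05,
                         n_seeds = 2L)),
  default = list(psm = list(n_proteins = 1000L, n_true = 60L, fold = 8,
                            phi = 0.3, baseline_mean = 20, n_bait_reps = 3L,
                            n_control_reps = 3L, zero_rate = 0.02),
                 net = list(block_sizes = rep(15L, 4L), p_in = 0.6,
                            p_out = 0.02, n_seeds = 3L)),
  stress = list(psm = list(n_proteins = 5000L, n_true = 300L, fold = 8,
                           phi = 0.3, baseline_mean = 20, n_bait_reps = 3L,
                           n_control_reps = 3L, zero_rate = 0.02),
                net = list(block_sizes = rep(50L, 6L), p_in = 0.3,
                           p_out = 0.01, n_seeds = 3L))
)

#' Write a complete synthetic fixture bundle
#'
#' Generates a PSM experiment and a planted-module network whose nodes are
#' the planted interactors, and writes every input the pipeline consumes:
#' PSM table (dropout cells written as missing so imputation is exercised on
#' read), design, edge list, seed list, specificity reference, per-block GMT
#' category sets, and a JSON truth manifest. Byte-identical across runs with
#' the same preset and seed.
#'
#' @param outdir output directory (created if needed).
#' @param preset `"tiny"` (smoke-sized), `"default"` (the standard study
#'   conditions: 1000 proteins, 60 planted at fold 8, phi 0.3, 3+3
#'   replicates; 4 network blocks of 15), or `"stress"`.
#' @param seed integer seed; the network stage uses `seed + 1`.
#' @return Named character vector of the written file paths, invisibly
#'   returned with the in-memory `psm_sim`/`net_sim` objects attached as
#'   attributes.
#' @export
write_fixture_bundle <- function(outdir, preset = c("tiny", "default", "stress"),
                                 seed = 1L) {
  preset <- match.arg(preset)
  cfg <- bundle_presets[[preset]]
  if (!dir.exists(outdir) &&
      !dir.create(outdir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory ", outdir)
  psm_sim <- do.call(simulate_psm, c(cfg$psm, list(seed = seed)))
  net_sim <- do.call(simulate_network,
                     c(cfg$net, list(node_names = psm_sim$truth$planted,
                                     seed = seed + 1L)))
  paths <- c(psm = file.path(outdir, "psm.tsv"),
             design = file.path(outdir, "design.tsv"),
             edges = file.path(outdir, "edges.tsv"),
             seeds = file.path(outdir, "seeds.txt"),
             specificity = file.path(outdir, "specificity.tsv"),
             gmt = file.path(outdir, "categories.gmt"),
             truth = file.path(outdir, "truth.json"))
  psm_out <- psm_sim$psm
  psm_out$counts[psm_sim$truth$dropout] <- NA_integer_
  write_psm_table(psm_out, paths[["psm"]], design_path = paths[["design"]])
  write_edge_list(net_sim$network, paths[["edges"]])
  write_seeds(net_sim$seeds, paths[["seeds"]])
  write_specificity(net_sim$specificity, paths[["specificity"]])
  blocks <- split(names(net_sim$truth$membership), net_sim$truth$membership)
  sets <- stats::setNames(blocks, sprintf("block_%s", names(blocks)))
  attr(sets, "description") <- stats::setNames(
    sprintf("planted module %s", names(blocks)), names(sets))
  write_gmt(sets, paths[["gmt"]])
  psm_truth <- psm_sim$truth[c("planted", "fold", "phi", "baseline_mean",
                               "libsize", "zero_rate", "seed")]
  psm_truth$libsize <- as.list(psm_truth$libsize)   # keep names in JSON
  net_truth <- unclass(net_sim$truth)
  net_truth$membership <- as.list(net_truth$membership)
  manifest <- list(preset = preset, seed = seed,
                   psm_truth = psm_truth, network_truth = net_truth)
  jsonlite::write_json(manifest, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  out <- invisible(paths)
  attr(out, "psm_sim") <- psm_sim
  attr(out, "net_sim") <- net_sim
  out
}
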