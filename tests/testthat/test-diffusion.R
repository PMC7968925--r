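test_that("an edgeless graph keeps the seed heat in place for any t", {
  g <- igraph::make_empty_graph(3, directed = FALSE)
  igraph::V(g)$name <- c("A", "B", "C")
  for (t in c(0, 0.25, 5)) {
    d <- heat_diffuse(g, c(B = 1), t = t)
    h <- stats::setNames(d$heat, d$node)
    expect_equal(h[c("A", "B", "C")], c(A = 0, B = 1, C = 0))
  }
})

test_that("two-node unit edge reproduces the closed-form kernel", {
  g <- functional_network(data.frame("A", "B", 1), score_cutoff = 0)
  d <- heat_diffuse(g, c(A = 1), t = 0.25)
  h <- stats::setNames(d$heat, d$node)
  # eigenvalues of L are 0 and 2: h = (1 +/- exp(-2t)) / 2
  expect_equal(unname(h["A"]), 0.5 * (1 + exp(-0.5)), tolerance = 1e-12)
  expect_equal(unname(h["B"]), 0.5 * (1 - exp(-0.5)), tolerance = 1e-12)
  expect_equal(round(unname(h["A"]), 4), 0.8033)
  expect_equal(round(unname(h["B"]), 4), 0.1967)
})

test_that("eigendecomposition heat matches an independent ODE integration", {
  g <- random_network(50, 0.08, seed = 3)
  nodes <- igraph::V(g)$name
  seeds <- stats::setNames(c(1, 1), nodes[1:2])
  d <- heat_diffuse(g, seeds, t = 0.25)
  h <- stats::setNames(d$heat, d$node)

  L <- bioidnet:::graph_laplacian(g)
  h0 <- stats::setNames(numeric(length(nodes)), rownames(L))
  h0[names(seeds)] <- 1
  sol <- deSolve::ode(h0, c(0, 0.25),
                      function(t, y, p) list(-(L %*% y)[, 1]), NULL,
                      rtol = 1e-10, atol = 1e-12)
  oracle <- sol[2, -1]
  expect_lt(max(abs(h[names(oracle)] - oracle)), 1e-6)
  expect_lt(abs(sum(d$heat) - sum(seeds)), 1e-8)
})

test_that("the matrix-exponential series path agrees with the eigen path", {
  g <- random_network(30, 0.12, seed = 6)
  seeds <- stats::setNames(1, igraph::V(g)$name[1])
  a <- heat_diffuse(g, seeds, t = 0.25)
  b <- heat_diffuse(g, seeds, t = 0.25, eig_max_nodes = 1L)  # force series
  ha <- stats::setNames(a$heat, a$node)
  hb <- stats::setNames(b$heat, b$node)
  expect_equal(ha, hb[names(ha)], tolerance = 1e-10)
})

test_that("heat is conserved, linear in seeds, and seed-local at small t", {
  for (seed in c(2, 4)) {
    g <- random_network(35, 0.1, seed = seed)
    nodes <- igraph::V(g)$name
    s1 <- stats::setNames(1, nodes[1])
    s2 <- stats::setNames(1, nodes[5])
    d12 <- heat_diffuse(g, c(s1, s2), t = 0.25)
    expect_lt(abs(sum(d12$heat) - 2), 1e-8)

    h1 <- stats::setNames(heat_diffuse(g, s1, t = 0.25)$heat,
                          heat_diffuse(g, s1, t = 0.25)$node)
    h2 <- stats::setNames(heat_diffuse(g, s2, t = 0.25)$heat,
                          heat_diffuse(g, s2, t = 0.25)$node)
    h12 <- stats::setNames(d12$heat, d12$node)
    expect_equal(h12[nodes], h1[nodes] + h2[nodes], tolerance = 1e-9)

    dsmall <- heat_diffuse(g, c(s1, s2), t = 0.01)
    expect_gt(min(dsmall$heat[dsmall$is_seed]),
              max(dsmall$heat[!dsmall$is_seed]))
  }
})

test_that("long-time heat equilibrates within each connected component", {
  g <- triangle_pair()    # two components of size 3
  d <- heat_diffuse(g, c(A = 1, X = 1, Y = 1), t = 100)
  h <- stats::setNames(d$heat, d$node)
  expect_equal(unname(h[c("A", "B", "C")]), rep(1 / 3, 3), tolerance = 1e-6)
  expect_equal(unname(h[c("X", "Y", "Z")]), rep(2 / 3, 3), tolerance = 1e-6)
})

test_that("seeds outside the network are dropped with warning, all missing errors", {
  g <- functional_network(data.frame("A", "B", 0.9))
  expect_warning(d <- heat_diffuse(g, c(A = 1, QQQ = 1), t = 0.25), "QQQ")
  expect_equal(sum(d$is_seed), 1)
  expect_error(suppressWarnings(heat_diffuse(g, c(QQQ = 1), t = 0.25)), "QQQ")
})

test_that("candidate ranking slices by heat with lexicographic ties", {
  g <- functional_network(data.frame("A", "B", 1), score_cutoff = 0)
  d <- heat_diffuse(g, c(A = 1, B = 1), t = 0.25)   # symmetric: tied heat
  expect_identical(d$node, c("A", "B"))
  expect_warning(r <- rank_candidates(d, c("B", "A", "GHOST"), top_k = 5),
                 "GHOST")
  expect_identical(attr(r, "missing"), "GHOST")
  expect_identical(r$node, c("A", "B"))
  expect_identical(r$rank, 1:2)
})

test_that("diffusion ranking recovers the planted seed module", {
  sim <- simulate_network(seed = 5)
  g <- prune_unconnected(sim$network)
  d <- heat_diffuse(g, sim$seeds, t = 0.25)
  block <- names(sim$truth$membership)[
    sim$truth$membership == sim$truth$seed_block]
  k <- length(block)
  top <- rank_candidates(d, igraph::V(g)$name, top_k = k)
  expect_gte(length(intersect(top$node, block)) / k, 0.8)
})

test_that("specificity annotation is a faithful lookup with unobserved fallback", {
  ref <- c(TCF3 = "specific", HSPA8 = "nonspecific")
  ann <- annotate_specificity(c("TCF3", "HSPA8", "CHD7"), ref)
  expect_identical(unname(ann), c("specific", "nonspecific", "unobserved"))

  sim <- simulate_network(seed = 10)
  nodes <- names(sim$truth$membership)
  ann2 <- annotate_specificity(nodes, sim$specificity)
  counts <- table(ann2)
  oracle <- c(
    nonspecific = sum(nodes %in% names(sim$specificity)[
      sim$specificity == "nonspecific"]),
    specific = sum(nodes %in% names(sim$specificity)[
      sim$specificity == "specific"]),
    unobserved = sum(!nodes %in% names(sim$specificity)))
  expect_equal(as.vector(counts[names(oracle)]), unname(oracle))
})

test_that("clusters dominated by nonspecific members are dropped", {
  memb <- c(stats::setNames(rep(0L, 10), sprintf("bad%02d", 1:10)),
            stats::setNames(rep(1L, 6), sprintf("good%02d", 1:6)))
  cl <- cluster_assignment(memb)
  ann <- c(stats::setNames(rep("nonspecific", 8), sprintf("bad%02d", 1:8)),
           stats::setNames(rep("specific", 2), sprintf("bad%02d", 9:10)),
           stats::setNames(rep("specific", 6), sprintf("good%02d", 1:6)))
  kept <- exclude_nonspecific_clusters(cl, ann)      # 8/10 > 0.5 -> dropped
  expect_identical(names(kept$membership), sort(sprintf("good%02d", 1:6)))
  expect_setequal(attr(kept, "dropped"), sprintf("bad%02d", 1:10))

  all_spec <- exclude_nonspecific_clusters(cl, stats::setNames(
    rep("specific", 16), names(memb)))
  expect_length(all_spec$clusters, 2)                # nothing dropped

  expect_error(exclude_nonspecific_clusters(cl, ann[-1]), "annotation")
})

test_that("cluster exclusion agrees with a per-cluster fraction recount", {
  sim <- simulate_network(seed = 12)
  g <- prune_unconnected(sim$network)
  cl <- mcl_cluster(g)
  ann <- annotate_specificity(names(cl$membership), sim$specificity)
  frac <- 0.5
  kept <- exclude_nonspecific_clusters(cl, ann, frac)
  oracle_keep <- unlist(Filter(function(members)
    mean(ann[members] == "nonspecific") <= frac, cl$clusters))
  expect_setequal(names(kept$membership), oracle_keep)
})

test_that("resampling enrichment approximates the hypergeometric tail", {
  u <- sprintf("U%02d", 1:20)
  res <- resampling_enrichment(
    u[1:5], list(cat = u[1:8], whole = u, disjoint = u[9:16]),
    u, n_resamples = 10000, sampler_seed = 7)
  expect_equal(res$overlap, c(5, 5, 0))
  exact <- stats::phyper(4, 8, 12, 5, lower.tail = FALSE)
  expect_lt(abs(res$p[res$category == "cat"] - exact), 0.02)
  expect_equal(res$p[res$category == "whole"], 1)     # saturation
  expect_equal(res$p[res$category == "disjoint"], 1)  # disjoint
  expect_true(all(res$p >= 1 / (10000 + 1)))

  expect_error(resampling_enrichment(c(u[1], "ZZZ"), list(s = u[1:3]), u),
               "outside")
  expect_error(resampling_enrichment(rep(u, 2), list(s = u[1:3]), u[1:5]),
               "outside|larger")
})

test_that("enrichment is reproducible from its sampler seed and scoped", {
  u <- sprintf("U%02d", 1:30)
  set.seed(999)
  before <- stats::runif(1)
  set.seed(999)
  a <- resampling_enrichment(u[1:6], list(s = u[1:10]), u,
                             n_resamples = 2000, sampler_seed = 5)
  after <- stats::runif(1)
  expect_identical(before, after)      # caller RNG stream untouched
  b <- resampling_enrichment(u[1:6], list(s = u[1:10]), u,
                             n_resamples = 2000, sampler_seed = 5)
  expect_identical(a$p, b$p)
})
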