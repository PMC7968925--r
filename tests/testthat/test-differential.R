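test_that("imputation zeroes exactly the missing cells", {
  psm <- toy_psm()
  expect_identical(impute_missing(psm), psm)   # nothing missing: identity

  sim <- simulate_psm(n_proteins = 50, n_true = 5, zero_rate = 0, seed = 9)
  masked <- sim$psm
  set.seed(1)
  holes <- matrix(stats::runif(length(masked$counts)) < 0.2,
                  nrow(masked$counts))
  masked$counts[holes] <- NA_integer_
  imp <- impute_missing(masked)
  expect_false(anyNA(imp$counts))
  expect_identical(imp$counts[!holes], sim$psm$counts[!holes])
  expect_true(all(imp$counts[holes] == 0))
})

test_that("sum normalization equalizes column totals at the grand mean", {
  counts <- matrix(c(40L, 60L, 120L, 80L), 2,
                   dimnames = list(c("A", "B"), c("s1", "s2")))
  psm <- psm_matrix(counts, c("bait", "control"), c(1L, 1L))
  norm <- sum_normalize(psm)
  # totals 100 and 200 -> factors 1.5 and 0.75, both columns sum to 150
  expect_equal(norm[, "s1"], c(A = 60, B = 90))
  expect_equal(norm[, "s2"], c(A = 90, B = 60))
  expect_equal(unname(colSums(norm)), c(150, 150))

  equal <- psm_matrix(matrix(c(5L, 5L, 7L, 3L), 2,
                             dimnames = list(c("A", "B"), c("s1", "s2"))),
                      c("bait", "control"), c(1L, 1L))
  expect_equal(sum_normalize(equal), equal$counts + 0)  # already equal totals

  sim <- simulate_psm(n_proteins = 80, n_true = 10, seed = 2)
  norm2 <- sum_normalize(impute_missing(sim$psm))
  expect_lt(diff(range(colSums(norm2))), 1e-9)

  zero <- psm_matrix(matrix(c(0L, 0L, 1L, 2L), 2,
                            dimnames = list(c("A", "B"), c("s1", "s2"))),
                     c("bait", "control"), c(1L, 1L))
  expect_error(sum_normalize(zero), "s1")
})

test_that("detection filter applies the raw-count rule in bait samples only", {
  counts <- rbind(kept = c(3L, 3L, 0L, 9L, 9L, 9L),
                  dropped = c(3L, 2L, 2L, 9L, 9L, 9L),
                  zero = c(0L, 0L, 0L, 0L, 0L, 0L),
                  ctrl_only = c(0L, 0L, 1L, 9L, 9L, 9L))
  colnames(counts) <- c(sprintf("bait_%d", 1:3), sprintf("control_%d", 1:3))
  psm <- psm_matrix(counts, rep(c("bait", "control"), each = 3),
                    rep(1:3, 2))
  expect_identical(filter_detected(psm), "kept")
  expect_error(filter_detected(psm, min_reps = 4), "bait replicates")
})

test_that("detection filter agrees with an exhaustive per-protein check and is monotone", {
  sim <- simulate_psm(n_proteins = 200, n_true = 20, baseline_mean = 4,
                      zero_rate = 0.2, seed = 13)
  psm <- impute_missing(sim$psm)
  bait <- psm$counts[, psm$condition == "bait", drop = FALSE]
  for (min_psm in c(1L, 2L, 4L)) for (min_reps in c(1L, 2L, 3L)) {
    keep <- filter_detected(psm, min_psm, min_reps)
    oracle <- character()
    for (p in rownames(bait)) {
      hits <- 0L
      for (j in seq_len(ncol(bait))) if (bait[p, j] > min_psm) hits <- hits + 1L
      if (hits >= min_reps) oracle <- c(oracle, p)
    }
    expect_identical(keep, oracle)
  }
  base <- filter_detected(psm, 2L, 2L)
  expect_true(all(filter_detected(psm, 4L, 2L) %in% base))
  expect_true(all(filter_detected(psm, 2L, 3L) %in% base))
})

test_that("common dispersion is recovered from NB data and hits the Poisson limit", {
  nb <- simulate_psm(n_proteins = 500, n_true = 0, fold = 1, phi = 0.4,
                     zero_rate = 0, seed = 11)
  norm <- sum_normalize(impute_missing(nb$psm))
  est <- estimate_dispersion(norm, nb$psm$condition)
  expect_gt(est$phi, 0.3)
  expect_lt(est$phi, 0.5)

  pois <- simulate_psm(n_proteins = 500, n_true = 0, fold = 1, phi = 0,
                       zero_rate = 0, seed = 12)
  normp <- sum_normalize(impute_missing(pois$psm))
  expect_lte(estimate_dispersion(normp, pois$psm$condition)$phi, 0.05)

  const <- matrix(5, 2, 6, dimnames = list(c("A", "B"), sprintf("s%d", 1:6)))
  est0 <- estimate_dispersion(const, rep(c("bait", "control"), each = 3))
  expect_identical(est0$phi, 0)
})

test_that("LRT is null for identical counts and matches a direct refit oracle", {
  flat <- matrix(c(4, 4, 4, 4, 4, 4), 1,
                 dimnames = list("A", sprintf("s%d", 1:6)))
  cond <- rep(c("bait", "control"), each = 3)
  res <- lrt_differential(flat, cond, 0.2)
  expect_equal(res$lrt_stat, 0)
  expect_equal(res$pvalue, 1)

  y <- matrix(c(10, 10, 10, 0, 0, 0), 1,
              dimnames = list("A", sprintf("s%d", 1:6)))
  res2 <- lrt_differential(y, cond, 0.1)
  # oracle: numerically maximize each NB likelihood over its mean
  ll <- function(yy, mu) bioidnet:::nb_loglik(yy, mu, 0.1)
  opt_ll <- function(yy) {
    o <- stats::optimize(function(m) ll(yy, m), c(1e-9, 50), maximum = TRUE)
    max(o$objective, ll(yy, 1e-12))    # boundary mu -> 0
  }
  stat_oracle <- 2 * (opt_ll(c(10, 10, 10)) + opt_ll(c(0, 0, 0)) -
                        opt_ll(c(10, 10, 10, 0, 0, 0)))
  expect_equal(res2$lrt_stat, stat_oracle, tolerance = 1e-4)
  expect_equal(res2$log2fc, log2(10.5 / 0.5))

  allzero <- matrix(0, 1, 6, dimnames = list("A", sprintf("s%d", 1:6)))
  res3 <- lrt_differential(allzero, cond, 0.3)
  expect_equal(res3$pvalue, 1)
  expect_equal(res3$log2fc, 0)
})

test_that("null LRT p-values are approximately uniform", {
  sim <- simulate_psm(n_proteins = 1000, n_true = 0, fold = 1, phi = 0.3,
                      zero_rate = 0, seed = 101)
  psm <- impute_missing(sim$psm)
  norm <- sum_normalize(psm)
  keep <- filter_detected(psm)
  nf <- norm[keep, , drop = FALSE]
  disp <- estimate_dispersion(nf, psm$condition)
  res <- lrt_differential(nf, psm$condition, disp)
  ks <- suppressWarnings(stats::ks.test(res$pvalue, "punif"))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("BH adjustment matches an independent rank-based recomputation", {
  set.seed(21)
  p <- stats::runif(200)^2
  res <- data.frame(protein_id = sprintf("P%03d", 1:200),
                    log2fc = stats::rnorm(200, 2), lrt_stat = 0, pvalue = p)
  called <- call_candidates(res)
  ref <- bh_reference(p)
  expect_equal(called$adjp,
               ref[match(called$protein_id, res$protein_id)])
  expect_true(all(called$adjp >= called$pvalue))
  expect_true(all(diff(called$adjp) >= 0))   # sorted output is monotone
})

test_that("candidate calling enforces both strict thresholds and the filter", {
  res <- data.frame(protein_id = c("fc_low", "ok", "p_high", "filtered"),
                    log2fc = c(log2(2.9), log2(3.5), log2(9), log2(9)),
                    lrt_stat = 9,
                    pvalue = c(0.0005, 0.0005, 0.08, 0.0005))
  called <- call_candidates(res, alpha = 0.05, fc_min = 3,
                            detected = c("fc_low", "ok", "p_high"))
  flags <- stats::setNames(called$candidate, called$protein_id)
  expect_false(flags[["fc_low"]])     # adjp fine, FC 2.9 is not > 3
  expect_true(flags[["ok"]])
  expect_false(flags[["p_high"]])
  expect_false(flags[["filtered"]])   # fails the detection filter

  empty <- call_candidates(res[0, ])
  expect_equal(nrow(empty), 0)
  expect_identical(candidate_list(empty), character(0))
})

test_that("candidate calling is invariant to protein row order", {
  sim <- simulate_psm(n_proteins = 120, n_true = 15, seed = 31)
  psm <- impute_missing(sim$psm)
  norm <- sum_normalize(psm)
  keep <- filter_detected(psm)
  nf <- norm[keep, , drop = FALSE]
  disp <- estimate_dispersion(nf, psm$condition)
  a <- call_candidates(lrt_differential(nf, psm$condition, disp),
                       detected = keep)
  perm <- sample(nrow(nf))
  b <- call_candidates(lrt_differential(nf[perm, , drop = FALSE],
                                        psm$condition, disp),
                       detected = keep)
  expect_identical(candidate_list(a), candidate_list(b))
})

test_that("overlap statistics reproduce the 2x2 arithmetic", {
  # table [[5,5],[5,85]]: OR = (5*85)/(5*5) = 17
  u <- sprintf("g%03d", 1:100)
  a <- u[1:10]; b <- u[c(1:5, 11:15)]
  ov <- overlap_stats(a, b, 100)
  expect_equal(ov$odds_ratio, 17)
  expect_false(ov$haldane)
  # chi-squared against the textbook formula
  n11 <- 5; n10 <- 5; n01 <- 5; n00 <- 85; n <- 100
  chi <- n * (n11 * n00 - n10 * n01)^2 /
    ((n11 + n10) * (n01 + n00) * (n11 + n01) * (n10 + n00))
  expect_equal(ov$chisq_stat, chi, tolerance = 1e-9)
  expect_equal(ov$p_value, stats::pchisq(chi, 1, lower.tail = FALSE),
               tolerance = 1e-9)

  disj <- overlap_stats(u[1:10], u[11:20], 40)
  expect_true(disj$haldane)           # zero overlap cell, flagged
  # Haldane value: (0 + .5)(20 + .5) / ((10 + .5)(10 + .5))
  expect_equal(disj$odds_ratio, 0.5 * 20.5 / 10.5^2)
  expect_lt(disj$odds_ratio, 1)

  expect_error(overlap_stats(u[1:10], u[5:20], 15), "universe_size")
})
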