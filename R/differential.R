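#' Impute missing PSM observations as zero
#'
#' Peptides absent from a sample or below detection yield no spectra; such
#' missing observations are assigned a PSM of 0 so every protein has a count
#' in every sample. Observed cells are unchanged.
#'
#' @param psm a [psm_matrix()].
#' @return The same `psm_matrix` with all `NA` cells set to `0L`.
#' @export
impute_missing <- function(psm) {
  psm$counts[is.na(psm$counts)] <- 0L
  psm
}

#' Sum-normalize PSM counts across samples
#'
#' Each sample is scaled by (grand mean of sample totals) / (that sample's
#' total), equalizing the per-sample sum of PSM while preserving the overall
#' count scale that the negative binomial model expects.
#'
#' @param psm a [psm_matrix()] with no missing cells (run [impute_missing()]
#'   first).
#' @return Real-valued matrix of normalized counts, same dimnames as the
#'   input; after scaling every column total equals the grand mean total.
#' @export
sum_normalize <- function(psm) {
  counts <- psm$counts
  if (anyNA(counts)) stop("impute missing cells before normalization")
  totals <- colSums(counts)
  if (any(totals == 0))
    stop("sample(s) with zero total PSM: ",
         paste(colnames(counts)[totals == 0], collapse = ", "))
  sweep(counts, 2L, mean(totals) / totals, `*`)
}

#' Detection filter on raw PSM counts
#'
#' Retains proteins present in at least `min_reps` bait-condition replicates
#' with a raw PSM value strictly above `min_psm`. The rule describes presence
#' of the labeled protein, so it is evaluated on raw (pre-normalization)
#' counts in bait samples only.
#'
#' @param psm a [psm_matrix()] of raw counts (imputed).
#' @param min_psm PSM threshold; a replicate counts as detection when its
#'   count exceeds this (strictly).
#' @param min_reps minimum number of detecting bait replicates.
#' @return Character vector of retained protein ids, in input row order.
#' @export
filter_detected <- function(psm, min_psm = 2L, min_reps = 2L) {
  bait <- psm$counts[, bait_cols(psm), drop = FALSE]
  if (min_reps > ncol(bait))
    stop("min_reps exceeds the number of bait replicates")
  keep <- rowSums(bait > min_psm, na.rm = TRUE) >= min_reps
  rownames(psm$counts)[keep]
}

# Continuous-extension NB log-likelihood of observations y at common mean mu,
# dispersion phi (var = mu + phi mu^2). Valid for real-valued y >= 0, which
# sum-normalized counts are; phi = 0 is the Poisson limit.
nb_loglik <- function(y, mu, phi) {
  if (mu <= 0) return(if (all(y == 0)) 0 else -Inf)
  if (phi < 1e-12)
    return(sum(y * log(mu) - mu - lgamma(y + 1)))
  r <- 1 / phi
  sum(lgamma(y + r) - lgamma(r) - lgamma(y + 1) +
        r * log(r / (r + mu)) + y * log(mu / (r + mu)))
}

# Pooled profile log-likelihood of a common dispersion: per-condition means
# are profiled out in closed form (the NB score in mu is sum(y - mu) / c(mu),
# so the profiled mean is the group sample mean). With cox_reid = TRUE the
# Cox-Reid adjustment -0.5 * log det(X'WX) is applied per protein, W being
# the NB working weights mu / (1 + phi mu); this removes most of the downward
# bias of the plain MLE at small replicate numbers.
dispersion_profile_ll <- function(counts, condition, phi, cox_reid = TRUE) {
  ll <- 0
  for (cond in unique(condition)) {
    y <- counts[, condition == cond, drop = FALSE]
    n <- ncol(y)
    mu <- rowMeans(y)
    pos <- which(mu > 0)
    for (i in pos) ll <- ll + nb_loglik(y[i, ], mu[i], phi)
    if (cox_reid && length(pos)) {
      info <- n * mu[pos] / (1 + phi * mu[pos])
      ll <- ll - 0.5 * sum(log(info))
    }
  }
  ll
}

#' Estimate a common NB dispersion by adjusted profile likelihood
#'
#' A single dispersion shared by all proteins is the stable choice for
#' spectral-count designs with 2-4 replicates per condition. The estimate
#' maximizes the negative binomial profile likelihood pooled over all
#' (filtered) proteins, with each protein's per-condition means profiled out
#' in closed form. By default the Cox-Reid adjusted profile likelihood is
#' used, which corrects the small-sample downward bias of the plain maximum
#' likelihood estimate; `method = "ml"` gives the unadjusted profile.
#'
#' @param norm_counts matrix of (sum-normalized) counts, proteins x samples.
#' @param condition per-sample condition labels (column order).
#' @param method `"cr"` (Cox-Reid adjusted, default) or `"ml"`.
#' @param interval search interval for the dispersion.
#' @return Object of class `dispersion_estimate`: list with `phi`, `method`,
#'   `loglik`.
#' @export
estimate_dispersion <- function(norm_counts, condition,
                                method = c("cr", "ml"),
                                interval = c(0, 20)) {
  method <- match.arg(method)
  tab <- table(condition)
  if (max(tab) < 2L)
    stop("need >= 2 samples in at least one condition to estimate dispersion")
  cr <- method == "cr"
  f <- function(phi) dispersion_profile_ll(norm_counts, condition, phi, cr)
  opt <- stats::optimize(f, interval = interval, maximum = TRUE, tol = 1e-7)
  phi <- opt$maximum
  # boundary handling: optimize() never returns the exact endpoints, so test
  # whether the likelihood is monotone decreasing at the lower edge
  if (phi < 1e-4 && f(0) >= opt$objective) phi <- 0
  if (phi > 1e-4) {
    h <- 1e-5 * max(phi, 1)
    grad <- (f(phi + h) - f(phi - h)) / (2 * h)
    if (abs(grad) > 1e-2 * max(1, abs(opt$objective)) &&
        phi < interval[2] - 10 * h)
      stop("dispersion optimizer did not converge; |gradient| = ",
           format(abs(grad)))
  }
  structure(list(phi = phi, method = method,
                 loglik = if (phi == 0) f(0) else opt$objective),
            class = "dispersion_estimate")
}

#' @export
print.dispersion_estimate <- function(x, ...) {
  cat(sprintf("common NB dispersion phi = %.4f (%s profile likelihood)\n",
              x$phi, if (x$method == "cr") "Cox-Reid adjusted" else "plain"))
  invisible(x)
}

#' NB-GLM likelihood-ratio test per protein
#'
#' Fits, for each protein, a negative binomial model with log link and a
#' condition (bait vs control) effect against an intercept-only null, both at
#' the supplied common dispersion, and compares them with a likelihood-ratio
#' test on 1 degree of freedom. With a single binary factor the fitted means
#' are the per-condition sample means, so the fits are closed-form. The log2
#' fold-change is computed from the condition means after adding a
#' pseudo-count of 0.5 to each mean, which bounds fold-changes when controls
#' are all zero.
#'
#' @param norm_counts matrix of normalized counts (proteins x samples),
#'   usually restricted to detection-filtered proteins.
#' @param condition per-sample condition labels.
#' @param dispersion a [dispersion_estimate][estimate_dispersion()] (or a
#'   bare numeric dispersion).
#' @return Data frame with one row per protein: `protein_id`, `mean_bait`,
#'   `mean_control`, `log2fc`, `lrt_stat`, `pvalue`. Proteins with all-zero
#'   counts get statistic 0, p = 1 and fold-change 0.
#' @export
lrt_differential <- function(norm_counts, condition, dispersion) {
  phi <- if (inherits(dispersion, "dispersion_estimate")) dispersion$phi
         else as.numeric(dispersion)
  stopifnot(is.finite(phi), phi >= 0)
  bait <- condition == "bait"
  n <- nrow(norm_counts)
  mean_bait <- rowMeans(norm_counts[, bait, drop = FALSE])
  mean_control <- rowMeans(norm_counts[, !bait, drop = FALSE])
  mean_all <- rowMeans(norm_counts)
  stat <- numeric(n)
  for (i in seq_len(n)) {
    if (mean_all[i] == 0) next
    y <- norm_counts[i, ]
    ll_full <- nb_loglik(y[bait], mean_bait[i], phi) +
      nb_loglik(y[!bait], mean_control[i], phi)
    ll_null <- nb_loglik(y, mean_all[i], phi)
    stat[i] <- max(0, 2 * (ll_full - ll_null))
  }
  pvalue <- stats::pchisq(stat, df = 1L, lower.tail = FALSE)
  pvalue[mean_all == 0] <- 1
  log2fc <- ifelse(mean_all == 0, 0,
                   log2((mean_bait + 0.5) / (mean_control + 0.5)))
  data.frame(protein_id = rownames(norm_counts),
             mean_bait = mean_bait, mean_control = mean_control,
             log2fc = log2fc, lrt_stat = stat, pvalue = pvalue,
             row.names = NULL)
}

#' Call bait-specific interaction candidates
#'
#' Adjusts the LRT p-values across tested proteins with Benjamini-Hochberg
#' and flags candidates at `adjp < alpha` together with fold-change strictly
#' greater than `fc_min` (on the pseudo-counted condition-mean ratio) and
#' passage of the detection filter.
#'
#' @param results data frame from [lrt_differential()].
#' @param alpha adjusted-p threshold (strict `<`).
#' @param fc_min fold-change threshold (strict `>`, linear scale).
#' @param detected protein ids that passed [filter_detected()]; defaults to
#'   every tested protein.
#' @return The input with `adjp` and logical `candidate` columns appended,
#'   rows sorted by (`adjp`, `protein_id`).
#' @export
call_candidates <- function(results, alpha = 0.05, fc_min = 3,
                            detected = NULL) {
  if (nrow(results) == 0L) {
    results$adjp <- numeric(0)
    results$candidate <- logical(0)
    return(results)
  }
  if (is.null(detected)) detected <- results$protein_id
  results$adjp <- stats::p.adjust(results$pvalue, method = "BH")
  fold <- 2^results$log2fc
  results$candidate <- results$adjp < alpha & fold > fc_min &
    results$protein_id %in% detected
  results[order(results$adjp, results$protein_id), , drop = FALSE]
}

#' Candidate list from a called differential result
#'
#' @param results output of [call_candidates()].
#' @return Character vector of candidate protein ids, ordered by adjusted p
#'   then symbol.
#' @export
candidate_list <- function(results) results$protein_id[results$candidate]

#' Overlap of two protein sets in a finite universe
#'
#' Builds the 2x2 in/out contingency table for two sets within a universe of
#' known size and reports the odds ratio plus the Pearson chi-squared p-value
#' (no continuity correction). When the table has a zero cell the Haldane
#' correction (+0.5 to every cell) is applied to the odds ratio only, and
#' flagged.
#'
#' @param set_a,set_b character vectors (subsets of the universe).
#' @param universe_size total number of proteins considered.
#' @return List of class `overlap_stats`: `odds_ratio`, `chisq_stat`,
#'   `p_value`, `table`, `haldane` (logical flag).
#' @export
overlap_stats <- function(set_a, set_b, universe_size) {
  set_a <- unique(set_a); set_b <- unique(set_b)
  n11 <- length(intersect(set_a, set_b))
  n10 <- length(setdiff(set_a, set_b))
  n01 <- length(setdiff(set_b, set_a))
  n_union <- n11 + n10 + n01
  if (universe_size < n_union)
    stop("universe_size (", universe_size, ") smaller than |set_a U set_b| (",
         n_union, ")")
  n00 <- universe_size - n_union
  tab <- matrix(c(n11, n01, n10, n00), nrow = 2,
                dimnames = list(in_a = c("yes", "no"), in_b = c("yes", "no")))
  haldane <- any(tab == 0)
  or_tab <- if (haldane) tab + 0.5 else tab
  or <- (or_tab[1, 1] * or_tab[2, 2]) / (or_tab[1, 2] * or_tab[2, 1])
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  structure(list(odds_ratio = unname(or),
                 chisq_stat = unname(ct$statistic),
                 p_value = unname(ct$p.value),
                 table = tab, haldane = haldane),
            class = "overlap_stats")
}

#' @export
print.overlap_stats <- function(x, ...) {
  cat(sprintf("overlap odds ratio = %.2f%s, chi-squared p = %.2g\n",
              x$odds_ratio,
              if (x$haldane) " (Haldane-corrected: zero cell)" else "",
              x$p_value))
  invisible(x)
}
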