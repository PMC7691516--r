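#' Standardized genetic differentiation G''ST
#'
#' Computes GST from sample-size-corrected within-group (`HS`) and total
#' (`HT`) expected heterozygosities (Nei & Chesser estimators with the
#' harmonic-mean group size), averaged over loci, and standardizes it by its
#' maximum given `HS` with the k-group small-sample correction
#' (Meirmans & Hedrick 2011):
#' `G''ST = k * (HT - HS) / ((k * HT - HS) * (1 - HS))`.
#' G''ST is 0 for undifferentiated groups and 1 when groups share no
#' alleles, regardless of within-group diversity — the reason it is
#' preferred over FST for highly polymorphic microsatellites.
#'
#' @param ds A [genotype_dataset()].
#' @param grouping Group label per individual (vector recycled against the
#'   dataset, or the name of a metadata column such as
#'   `"breeding_ground"`). Individuals with `NA` labels are dropped.
#' @return List: `gst_double_prime` (multilocus), `gst`, `HS`, `HT`, `k`,
#'   `n_per_group`, `per_locus` (data frame of locus-wise `HS`, `HT`).
#' @export
gst_double_prime <- function(ds, grouping) {
  g <- .resolve_grouping(ds, grouping)
  keep <- !is.na(g$labels)
  ds2 <- subset_dataset(ds, individuals = which(keep))
  labels <- factor(g$labels[keep])
  if (nlevels(labels) < 2L) stop("need at least 2 groups")
  comp <- .gst_components(ds2, labels)
  .gst_from_components(comp, nlevels(labels), labels)
}

.resolve_grouping <- function(ds, grouping) {
  if (is.character(grouping) && length(grouping) == 1L &&
      grouping %in% names(ds$meta)) {
    list(labels = ds$meta[[grouping]], name = grouping)
  } else {
    if (length(grouping) != nrow(ds$geno)) {
      stop("grouping must name a metadata column or give one label per individual")
    }
    list(labels = grouping, name = "custom")
  }
}

# per-locus Nei-Chesser HS/HT estimates for a fixed group factor
.gst_components <- function(ds, labels) {
  k <- nlevels(labels)
  gidx <- as.integer(labels)
  L <- length(ds$loci)
  HS <- rep(NA_real_, L); HT <- rep(NA_real_, L)
  for (l in seq_len(L)) {
    al <- locus_alleles(ds, l)
    typed <- !is.na(al[, 1L])
    n_g <- tabulate(gidx[typed], k)
    if (any(n_g < 2L)) {
      if (all(n_g == 0L)) next
      if (any(n_g < 2L)) next  # locus unusable for this grouping
    }
    alleles <- sort(unique(c(al[typed, 1L], al[typed, 2L])))
    K <- length(alleles)
    a1 <- match(al[typed, 1L], alleles)
    a2 <- match(al[typed, 2L], alleles)
    gi <- gidx[typed]
    cnt <- matrix(0L, K, k)
    tab1 <- tabulate((gi - 1L) * K + a1, K * k)
    tab2 <- tabulate((gi - 1L) * K + a2, K * k)
    cnt <- matrix(tab1 + tab2, K, k)
    p <- sweep(cnt, 2L, 2 * n_g, "/")
    ho_g <- vapply(seq_len(k), function(gg) {
      sel <- gi == gg
      if (any(sel)) mean(a1[sel] != a2[sel]) else NA_real_
    }, numeric(1))
    ho <- mean(ho_g)
    n_harm <- k / sum(1 / n_g)
    hs_raw <- 1 - mean(colSums(p^2))
    hs <- n_harm / (n_harm - 1) * (hs_raw - ho / (2 * n_harm))
    pbar <- rowMeans(p)
    ht <- 1 - sum(pbar^2) + hs / (n_harm * k) - ho / (2 * n_harm * k)
    HS[l] <- hs; HT[l] <- ht
  }
  data.frame(locus = ds$loci, HS = HS, HT = HT, stringsAsFactors = FALSE)
}

.gst_from_components <- function(comp, k, labels = NULL) {
  ok <- !is.na(comp$HS)
  if (!any(ok)) stop("no locus usable: every group needs >= 2 typed individuals at some locus")
  HS <- mean(comp$HS[ok]); HT <- mean(comp$HT[ok])
  gst <- if (HT > 0) (HT - HS) / HT else 0
  gpp <- if (HT > 0 && HS < 1) {
    k * (HT - HS) / ((k * HT - HS) * (1 - HS))
  } else 0
  out <- list(gst_double_prime = gpp, gst = gst, HS = HS, HT = HT, k = k,
              per_locus = comp)
  if (!is.null(labels)) out$n_per_group <- table(labels)
  out
}

#' Permutation test for G''ST
#'
#' Permutes individuals among groups (holding group sizes fixed) and
#' reports the one-tailed `p = (k + 1) / (n_perm + 1)` for permuted G''ST
#' at or above the observed value.
#'
#' @param ds A [genotype_dataset()].
#' @param grouping See [gst_double_prime()].
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer RNG seed.
#' @return List: `observed` (the [gst_double_prime()] result), `p_value`,
#'   `n_perm`.
#' @export
gst_permutation_test <- function(ds, grouping, n_perm = 999L, seed = 1L) {
  g <- .resolve_grouping(ds, grouping)
  keep <- !is.na(g$labels)
  ds2 <- subset_dataset(ds, individuals = which(keep))
  labels <- factor(g$labels[keep])
  if (nlevels(labels) < 2L) stop("need at least 2 groups")
  k <- nlevels(labels)
  obs <- .gst_from_components(.gst_components(ds2, labels), k, labels)
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  hits <- 0L
  for (b in seq_len(n_perm)) {
    perm <- sample(labels)
    val <- .gst_from_components(.gst_components(ds2, perm), k)$gst_double_prime
    if (val >= obs$gst_double_prime - 1e-12) hits <- hits + 1L
  }
  list(observed = obs, p_value = (hits + 1) / (n_perm + 1), n_perm = n_perm)
}

#' Bootstrap confidence interval for multilocus G''ST
#'
#' Resamples loci with replacement — loci being the exchangeable replicates
#' of a multilocus estimate — and returns the percentile 95% interval.
#'
#' @param ds A [genotype_dataset()].
#' @param grouping See [gst_double_prime()].
#' @param n_boot Number of bootstrap replicates (default 999).
#' @param seed Integer RNG seed.
#' @param conf Confidence level (default 0.95).
#' @return List: `lower`, `upper`, `observed`, `n_boot`.
#' @export
gst_bootstrap_ci <- function(ds, grouping, n_boot = 999L, seed = 1L,
                             conf = 0.95) {
  if (n_boot < 1L) stop("n_boot must be >= 1")
  g <- .resolve_grouping(ds, grouping)
  keep <- !is.na(g$labels)
  ds2 <- subset_dataset(ds, individuals = which(keep))
  labels <- factor(g$labels[keep])
  k <- nlevels(labels)
  comp <- .gst_components(ds2, labels)
  ok <- which(!is.na(comp$HS))
  if (length(ok) < 2L) stop("bootstrap CI needs >= 2 usable loci")
  obs <- .gst_from_components(comp, k)$gst_double_prime
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  reps <- vapply(seq_len(n_boot), function(b) {
    take <- sample(ok, length(ok), replace = TRUE)
    .gst_from_components(comp[take, , drop = FALSE], k)$gst_double_prime
  }, numeric(1))
  alpha <- (1 - conf) / 2
  ci <- stats::quantile(reps, c(alpha, 1 - alpha), names = FALSE, type = 7)
  list(lower = ci[1], upper = ci[2], observed = obs, n_boot = n_boot)
}

#' Full differentiation result for a grouping
#'
#' Convenience wrapper bundling the estimate, permutation p-value and
#' locus-bootstrap confidence interval.
#'
#' @inheritParams gst_permutation_test
#' @param n_boot Bootstrap replicates.
#' @return A `differentiation_result` list: `grouping`, `gst_double_prime`,
#'   `p_value`, `ci` (`lower`/`upper`), `n_per_group`, `n_perm`, `n_boot`.
#' @export
differentiation_test <- function(ds, grouping, n_perm = 999L, n_boot = 999L,
                                 seed = 1L) {
  g <- .resolve_grouping(ds, grouping)
  perm <- gst_permutation_test(ds, grouping, n_perm = n_perm, seed = seed)
  ci <- gst_bootstrap_ci(ds, grouping, n_boot = n_boot, seed = seed + 1L)
  structure(list(grouping = g$name,
                 gst_double_prime = perm$observed$gst_double_prime,
                 p_value = perm$p_value,
                 ci = c(lower = ci$lower, upper = ci$upper),
                 n_per_group = perm$observed$n_per_group,
                 n_perm = n_perm, n_boot = n_boot),
            class = "differentiation_result")
}

#' @export
print.differentiation_result <- function(x, ...) {
  cat(sprintf("G''ST (%s) = %.4f, P = %.3f, 95%% CI [%.4f, %.4f]\n",
              x$grouping, x$gst_double_prime, x$p_value, x$ci["lower"],
              x$ci["upper"]))
  invisible(x)
}

#' Evanno delta-K from external clustering runs
#'
#' Post-processes a table of per-run log-likelihoods from an external
#' Bayesian clustering program: for each K it reports the mean and SD of
#' run log-likelihoods, the first difference `L'(K) = L(K) - L(K-1)`, the
#' absolute second difference `|L''(K)| = |L'(K+1) - L'(K)|`, and
#' `deltaK = |L''(K)| / SD(L(K))`, defined only for interior K with
#' positive SD.
#'
#' @param runs Data frame with columns `K` and `loglik` (one row per run;
#'   a `run` column is ignored). CSV files with header `K,run,loglik` can
#'   be read with `read.csv`.
#' @return Data frame per K: `K`, `n_runs`, `mean_L`, `sd_L`, `Lprime`,
#'   `Lsecond_abs`, `deltaK` (`NA` where undefined).
#' @export
evanno_delta_k <- function(runs) {
  runs <- as.data.frame(runs)
  if (is.null(runs$K) || is.null(runs$loglik)) {
    stop("runs table needs columns K and loglik")
  }
  ks <- sort(unique(runs$K))
  if (length(ks) < 3L) stop("need >= 3 distinct K values")
  mean_L <- vapply(ks, function(k) mean(runs$loglik[runs$K == k]), numeric(1))
  sd_L <- vapply(ks, function(k) stats::sd(runs$loglik[runs$K == k]),
                 numeric(1))
  n_runs <- vapply(ks, function(k) sum(runs$K == k), integer(1))
  m <- length(ks)
  lp <- c(NA, diff(mean_L))                       # L'(K), defined for K >= 2
  lsec <- rep(NA_real_, m)
  lsec[2:(m - 1)] <- abs(lp[3:m] - lp[2:(m - 1)]) # |L''| at interior K
  dk <- ifelse(!is.na(lsec) & !is.na(sd_L) & sd_L > 0, lsec / sd_L, NA_real_)
  data.frame(K = ks, n_runs = n_runs, mean_L = mean_L, sd_L = sd_L,
             Lprime = lp, Lsecond_abs = lsec, deltaK = dk)
}
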