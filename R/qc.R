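#' Monte-Carlo exact test of Hardy-Weinberg equilibrium
#'
#' Levene-conditional exact test: holding the observed allele counts fixed,
#' the `2n` allele copies are repeatedly shuffled into `n` random diploid
#' genotypes. Under the default probability ordering the p-value is the
#' proportion of shuffled tables whose conditional probability is at most
#' that of the observed table; the `"homozygote"` ordering is a one-tailed
#' score test counting shuffles with no more heterozygotes than observed
#' (sensitive to homozygote excess from inbreeding or null alleles). Both use
#' the `(k + 1) / (n_mc + 1)` convention so p-values are never zero.
#'
#' @param ds A [genotype_dataset()].
#' @param locus Locus name or index.
#' @param n_mc Number of Monte-Carlo shuffles (>= 1000 recommended).
#' @param seed Integer RNG seed.
#' @param ordering `"probability"` (default) or `"homozygote"`.
#' @return List: `p_value`, `homozygote_excess` (observed Ho below the
#'   unbiased Hardy-Weinberg expectation), `Ho`, `He`, `n_typed`.
#' @export
hwe_test <- function(ds, locus, n_mc = 10000L, seed = 1L,
                     ordering = c("probability", "homozygote")) {
  ordering <- match.arg(ordering)
  al <- locus_alleles(ds, locus)
  al <- al[!is.na(al[, 1L]), , drop = FALSE]
  n <- nrow(al)
  if (n < 2L) stop("fewer than 2 typed individuals at locus ", locus)
  copies <- c(al[, 1L], al[, 2L])
  labels <- sort(unique(copies))
  if (length(labels) < 2L) {
    return(list(p_value = 1, homozygote_excess = FALSE,
                Ho = 0, He = 0, n_typed = n))
  }
  a1 <- match(al[, 1L], labels)
  a2 <- match(al[, 2L], labels)
  K <- length(labels)
  idx <- match(copies, labels)

  stat <- function(g1, g2) {
    # variable part of the Levene conditional log-probability of the table
    lo <- pmin(g1, g2); hi <- pmax(g1, g2)
    counts <- tabulate((lo - 1L) * K + hi, K * K)
    nhet <- sum(lo != hi)
    nhet * log(2) - sum(lgamma(counts[counts > 0L] + 1))
  }
  ho <- function(g1, g2) sum(g1 != g2)

  obs_stat <- stat(a1, a2)
  obs_het <- ho(a1, a2)
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  k <- 0L
  tol <- 1e-9
  for (i in seq_len(n_mc)) {
    perm <- sample(idx)
    g1 <- perm[seq_len(n)]
    g2 <- perm[n + seq_len(n)]
    extreme <- if (ordering == "probability") {
      stat(g1, g2) <= obs_stat + tol
    } else {
      ho(g1, g2) <= obs_het
    }
    if (extreme) k <- k + 1L
  }
  p_hat <- freq_vector_from_counts(tabulate(idx, K), 2L * n)
  he <- 2 * n / (2 * n - 1) * (1 - sum(p_hat^2))
  ho_obs <- obs_het / n
  list(p_value = (k + 1) / (n_mc + 1),
       homozygote_excess = ho_obs < he,
       Ho = ho_obs, He = he, n_typed = n)
}

freq_vector_from_counts <- function(counts, total) counts / total

#' Permutation test of genotypic linkage disequilibrium
#'
#' The statistic is the log-likelihood-ratio G of the two-locus genotype
#' contingency table (individuals cross-classified by genotype at each
#' locus); the null distribution is built by permuting one locus's genotypes
#' across individuals, breaking any association while preserving both
#' single-locus genotype distributions.
#'
#' @param ds A [genotype_dataset()].
#' @param locusA,locusB Locus names or indices.
#' @param n_perm Number of permutations.
#' @param seed Integer RNG seed.
#' @return List: `p_value`, `G` (observed statistic), `n` (individuals typed
#'   at both loci).
#' @export
ld_test <- function(ds, locusA, locusB, n_perm = 1000L, seed = 1L) {
  ga <- locus_alleles(ds, locusA)
  gb <- locus_alleles(ds, locusB)
  both <- !is.na(ga[, 1L]) & !is.na(gb[, 1L])
  if (!any(both)) stop("no individuals typed at both loci")
  fa <- factor(paste(ga[both, 1L], ga[both, 2L]))
  fb <- factor(paste(gb[both, 1L], gb[both, 2L]))
  if (nlevels(fa) < 2L || nlevels(fb) < 2L) {
    stop("both loci must be polymorphic among shared typed individuals")
  }
  g_stat <- function(x, y) {
    tab <- table(x, y)
    e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    keep <- tab > 0
    2 * sum(tab[keep] * log(tab[keep] / e[keep]))
  }
  obs <- g_stat(fa, fb)
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  k <- 0L
  for (i in seq_len(n_perm)) {
    if (g_stat(fa, sample(fb)) >= obs - 1e-12) k <- k + 1L
  }
  list(p_value = (k + 1) / (n_perm + 1), G = obs, n = sum(both))
}

#' False discovery rate adjustment
#'
#' Benjamini-Hochberg step-up by default (Benjamini-Yekutieli under positive
#' or arbitrary dependence available via `method`), with the rejection set at
#' level `q`.
#'
#' @param p_values Numeric vector of raw p-values in `(0, 1]`.
#' @param q FDR level for the rejection set (default 0.05).
#' @param method `"BH"` (default) or `"BY"`.
#' @return List: `adjusted` (same length/order as input), `rejected`
#'   (logical), `q`, `method`.
#' @export
fdr_adjust <- function(p_values, q = 0.05, method = c("BH", "BY")) {
  method <- match.arg(method)
  if (length(p_values) == 0L) {
    return(list(adjusted = numeric(0), rejected = logical(0), q = q,
                method = method))
  }
  if (any(p_values <= 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values must lie in (0, 1]")
  }
  adj <- stats::p.adjust(p_values, method = method)
  list(adjusted = adj, rejected = !is.na(adj) & adj <= q, q = q,
       method = method)
}

#' Null-allele frequency estimate
#'
#' A non-amplifying (null) allele inflates apparent homozygosity. The
#' default Chakraborty-style moment estimate is
#' `(He - Ho) / (He + Ho)`; the Brookfield-1 variant
#' `(He - Ho) / (1 + He)` is available. Negative values indicate
#' heterozygote excess.
#'
#' @param ds A [genotype_dataset()].
#' @param locus Locus name or index.
#' @param method `"chakraborty"` (default) or `"brookfield1"`.
#' @return Estimate in `[-1, 1]`.
#' @export
null_allele_frequency <- function(ds, locus,
                                  method = c("chakraborty", "brookfield1")) {
  method <- match.arg(method)
  s <- locus_summaries(subset_dataset(ds, loci = locus))
  ho <- s$Ho[1]; he <- s$He[1]
  if (he <= 0) stop("He must be positive at locus ", locus)
  if (method == "chakraborty") {
    if (he + ho == 0) stop("He + Ho is zero at locus ", locus)
    (he - ho) / (he + ho)
  } else {
    (he - ho) / (1 + he)
  }
}

#' Genotyping error rate from duplicate samples
#'
#' Given pairs of independent genotype records of the same biological
#' sample, reports the per-locus fraction of comparable (both-typed) pairs
#' whose genotypes disagree, and the overall rate pooled over loci (mean
#' weighted by the number of comparisons). Loci with no comparable pair get
#' `NA`, not zero.
#'
#' @param ds A [genotype_dataset()].
#' @param duplicate_pairs Data frame (or 2-column matrix) of individual id
#'   pairs; each row references two genotype records of one sample.
#' @return List: `per_locus` (data frame `locus`, `n_compared`, `n_mismatch`,
#'   `rate`) and `overall`.
#' @export
duplicate_error_rate <- function(ds, duplicate_pairs) {
  duplicate_pairs <- as.data.frame(duplicate_pairs)
  i1 <- match(as.character(duplicate_pairs[[1]]), ds$meta$id)
  i2 <- match(as.character(duplicate_pairs[[2]]), ds$meta$id)
  if (anyNA(i1) || anyNA(i2)) stop("duplicate pair references unknown id")
  per <- data.frame(locus = ds$loci, n_compared = 0L, n_mismatch = 0L,
                    rate = NA_real_, stringsAsFactors = FALSE)
  for (l in seq_along(ds$loci)) {
    al <- locus_alleles(ds, l)
    ok <- !is.na(al[i1, 1L]) & !is.na(al[i2, 1L])
    per$n_compared[l] <- sum(ok)
    if (any(ok)) {
      mm <- al[i1[ok], 1L] != al[i2[ok], 1L] | al[i1[ok], 2L] != al[i2[ok], 2L]
      per$n_mismatch[l] <- sum(mm)
      per$rate[l] <- mean(mm)
    }
  }
  total <- sum(per$n_compared)
  list(per_locus = per,
       overall = if (total > 0L) sum(per$n_mismatch) / total else NA_real_)
}

#' Marker quality-control report
#'
#' Runs the Hardy-Weinberg test and null-allele estimate for every locus
#' (optionally on a supplied subset of individuals, e.g. an unrelated subset
#' from [select_unrelated()]), FDR-adjusts the HWE p-values, and (optionally)
#' runs all pairwise linkage-disequilibrium tests with their own FDR
#' adjustment.
#'
#' @param ds A [genotype_dataset()].
#' @param individuals Optional subset used for the tests (default: all).
#' @param n_mc Monte-Carlo shuffles for the HWE test.
#' @param n_perm Permutations for each LD test.
#' @param ld Logical: run the (quadratic-cost) pairwise LD tests?
#' @param q FDR level.
#' @param seed Integer RNG seed.
#' @return A `qc_report`: list with `hwe` (data frame per locus), `ld`
#'   (data frame per locus pair or `NULL`), `q`.
#' @export
qc_report <- function(ds, individuals = NULL, n_mc = 2000L, n_perm = 200L,
                      ld = FALSE, q = 0.05, seed = 1L) {
  sub <- if (is.null(individuals)) ds else
    subset_dataset(ds, individuals = individuals)
  hwe <- data.frame(locus = ds$loci, p = NA_real_, p_adj = NA_real_,
                    homozygote_excess = NA, null_freq = NA_real_,
                    stringsAsFactors = FALSE)
  for (l in seq_along(ds$loci)) {
    h <- hwe_test(sub, l, n_mc = n_mc, seed = seed + l)
    hwe$p[l] <- h$p_value
    hwe$homozygote_excess[l] <- h$homozygote_excess
    hwe$null_freq[l] <- if (h$He > 0)
      null_allele_frequency(sub, l) else NA_real_
  }
  hwe$p_adj <- fdr_adjust(hwe$p, q = q)$adjusted
  ld_tab <- NULL
  if (ld) {
    pairs <- utils::combn(seq_along(ds$loci), 2L)
    ld_tab <- data.frame(locusA = ds$loci[pairs[1, ]],
                         locusB = ds$loci[pairs[2, ]],
                         p = NA_real_, p_adj = NA_real_,
                         stringsAsFactors = FALSE)
    for (j in seq_len(ncol(pairs))) {
      ld_tab$p[j] <- tryCatch(
        ld_test(sub, pairs[1, j], pairs[2, j], n_perm = n_perm,
                seed = seed + 1000L + j)$p_value,
        error = function(e) NA_real_)
    }
    ok <- !is.na(ld_tab$p)
    ld_tab$p_adj[ok] <- fdr_adjust(ld_tab$p[ok], q = q)$adjusted
  }
  structure(list(hwe = hwe, ld = ld_tab, q = q), class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("qc_report:", nrow(x$hwe), "loci;",
      sum(x$hwe$p_adj <= x$q & x$hwe$homozygote_excess, na.rm = TRUE),
      "with FDR-significant homozygote excess\n")
  invisible(x)
}

#' Filter loci on quality-control evidence
#'
#' A locus is dropped only when it shows an FDR-significant Hardy-Weinberg
#' departure *with* homozygote excess *and* an estimated null-allele
#' frequency above `null_threshold` — both conditions, so a single noisy
#' signal never discards a marker.
#'
#' @param ds A [genotype_dataset()].
#' @param qc A [qc_report()].
#' @param hwe_q FDR level applied to the adjusted HWE p-values.
#' @param null_threshold Null-allele frequency cutoff (default 0.10).
#' @return Character vector of retained locus names.
#' @export
filter_loci <- function(ds, qc, hwe_q = 0.05, null_threshold = 0.10) {
  fail <- !is.na(qc$hwe$p_adj) & qc$hwe$p_adj <= hwe_q &
    qc$hwe$homozygote_excess &
    !is.na(qc$hwe$null_freq) & qc$hwe$null_freq > null_threshold
  ds$loci[!fail[match(ds$loci, qc$hwe$locus)]]
}

#' Write a QC report as TSV (+ JSON)
#' @param qc A [qc_report()].
#' @param path Base path; writes `<path>.tsv` (HWE table) and `<path>.json`.
#' @return Invisibly, the paths written.
#' @export
write_qc_report <- function(qc, path) {
  tsv <- paste0(path, ".tsv")
  utils::write.table(qc$hwe, tsv, sep = "\t", row.names = FALSE, quote = FALSE)
  js <- paste0(path, ".json")
  jsonlite::write_json(unclass(qc), js, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(c(tsv, js))
}

# RNG state helpers: seeded routines restore the caller's stream
.save_seed <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
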