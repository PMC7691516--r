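#' @name relatedness-estimators
#' @title Moment estimators of pairwise relatedness
#'
#' @description
#' Four codominant moment estimators are implemented over the loci shared
#' (typed in both members) by each dyad:
#'
#' * `"queller_goodnight"` — allele-sharing relative to population
#'   frequencies, computed with each member as reference and averaged.
#' * `"lynch_ritland"` — the regression estimator with its locus
#'   information weights, reference-averaged.
#' * `"li"` — the similarity-index estimator: per-locus similarity `S`
#'   (1 identical genotypes, 0.75 one homozygote sharing, 0.5 both
#'   heterozygous sharing one allele, 0 otherwise) corrected by the
#'   expected similarity of unrelated dyads `S0 = 2*a2 - a3`, combined as a
#'   ratio of sums.
#' * `"wang"` — a least-squares moment estimator on the similarity-category
#'   model of Wang (2002): the three category probabilities
#'   `E[P1], E[P2], E[P3]` are linear in the two- and four-gene identity
#'   coefficients `(phi, Delta)` with coefficients built from the allele
#'   frequency moments `a2, a3, a4`; the system is solved for
#'   `(phi, Delta)`, and r is `phi/2 + Delta`. Loci are weighted by `1/u`,
#'   `u = 2*a2 - a3`, and the frequency moments use multinomial unbiased
#'   small-sample corrections when sample counts are available
#'   (`bias_correct = TRUE`).
#'
#' Relatedness values range over `[-1, 1]`-ish: negative values mean a pair
#' shares fewer alleles than two random draws from the population.
#' Expected values are 0.5 for parent-offspring and full siblings, 0.25 for
#' half siblings, 0 for unrelated pairs.
NULL

.estimators <- c("wang", "queller_goodnight", "lynch_ritland", "li")

# normalise a frequency input to list(freq = <list of named vectors>,
# n_typed = <int or NA>)
.as_freqs <- function(freqs, loci) {
  if (inherits(freqs, "allele_frequency_table")) {
    return(list(freq = freqs$freq[loci], n_typed = freqs$n_typed[loci]))
  }
  if (!is.list(freqs)) stop("freqs must be an allele_frequency_table or list")
  missing_loci <- setdiff(loci, names(freqs))
  if (length(missing_loci)) {
    stop("freqs lacks loci: ", paste(missing_loci, collapse = ", "))
  }
  list(freq = freqs[loci],
       n_typed = stats::setNames(rep(NA_integer_, length(loci)), loci))
}

# frequency moments a2 = sum p^2 etc., optionally multinomial-unbiased
.freq_moments <- function(p, n_typed, bias_correct) {
  if (bias_correct && !is.na(n_typed) && 2L * n_typed >= 4L) {
    N <- 2L * n_typed
    cnt <- p * N
    a2 <- sum(cnt * (cnt - 1)) / (N * (N - 1))
    a3 <- sum(cnt * (cnt - 1) * (cnt - 2)) / (N * (N - 1) * (N - 2))
    a4 <- sum(cnt * (cnt - 1) * (cnt - 2) * (cnt - 3)) /
      (N * (N - 1) * (N - 2) * (N - 3))
  } else {
    a2 <- sum(p^2); a3 <- sum(p^3); a4 <- sum(p^4)
  }
  c(a2 = max(a2, 0), a3 = max(a3, 0), a4 = max(a4, 0))
}

# core dyad engine: G1, G2 are n_dyads x 2L allele-label matrices
.dyad_relatedness <- function(G1, G2, loci, freqs, estimator,
                              bias_correct = TRUE, min_shared = 2L) {
  fr <- .as_freqs(freqs, loci)
  nd <- nrow(G1)
  L <- length(loci)
  shared <- integer(nd)
  acc <- switch(
    estimator,
    queller_goodnight = list(nx = numeric(nd), dx = numeric(nd),
                             ny = numeric(nd), dy = numeric(nd)),
    lynch_ritland = list(nx = numeric(nd), dx = numeric(nd),
                         ny = numeric(nd), dy = numeric(nd)),
    li = list(num = numeric(nd), den = numeric(nd)),
    wang = list(sw = numeric(nd), P1 = numeric(nd), P2 = numeric(nd),
                P3 = numeric(nd), b = numeric(nd), c = numeric(nd),
                d = numeric(nd), e = numeric(nd), f = numeric(nd),
                g = numeric(nd)),
    stop("unknown estimator tag: ", estimator))

  for (l in seq_len(L)) {
    p <- fr$freq[[l]]
    if (length(p) < 2L) next  # monomorphic locus carries no information
    labels <- as.integer(names(p))
    a <- match(G1[, 2L * l - 1L], labels)
    b <- match(G1[, 2L * l], labels)
    cc <- match(G2[, 2L * l - 1L], labels)
    d <- match(G2[, 2L * l], labels)
    ok <- !is.na(a) & !is.na(b) & !is.na(cc) & !is.na(d)
    if (!any(ok)) next
    a <- a[ok]; b <- b[ok]; cc <- cc[ok]; d <- d[ok]
    shared[ok] <- shared[ok] + 1L
    Sac <- a == cc; Sad <- a == d; Sbc <- b == cc; Sbd <- b == d
    Sab <- a == b; Scd <- cc == d
    pa <- p[a]; pb <- p[b]; pc <- p[cc]; pd <- p[d]
    m <- .freq_moments(p, fr$n_typed[[l]], bias_correct)
    a2 <- m[["a2"]]; a3 <- m[["a3"]]; a4 <- m[["a4"]]

    if (estimator == "queller_goodnight") {
      sh <- Sac + Sad + Sbc + Sbd
      acc$nx[ok] <- acc$nx[ok] + 0.5 * sh - pa - pb
      acc$dx[ok] <- acc$dx[ok] + 1 + Sab - pa - pb
      acc$ny[ok] <- acc$ny[ok] + 0.5 * sh - pc - pd
      acc$dy[ok] <- acc$dy[ok] + 1 + Scd - pc - pd
    } else if (estimator == "lynch_ritland") {
      wx <- 2 * pa * pb
      nx <- pa * (Sbc + Sbd) + pb * (Sac + Sad) - 4 * pa * pb
      dx <- (1 + Sab) * (pa + pb) - 4 * pa * pb
      wy <- 2 * pc * pd
      ny <- pc * (Sad + Sbd) + pd * (Sac + Sbc) - 4 * pc * pd
      dy <- (1 + Scd) * (pc + pd) - 4 * pc * pd
      acc$nx[ok] <- acc$nx[ok] + nx / wx
      acc$dx[ok] <- acc$dx[ok] + dx / wx
      acc$ny[ok] <- acc$ny[ok] + ny / wy
      acc$dy[ok] <- acc$dy[ok] + dy / wy
    } else {
      identical_g <- Sac & Sbd  # canonical order makes this genotype identity
      sharing <- Sac | Sad | Sbc | Sbd
      cat1 <- identical_g
      cat2 <- !identical_g & sharing & xor(Sab, Scd)
      cat3 <- !identical_g & sharing & !Sab & !Scd
      if (estimator == "li") {
        S <- as.numeric(cat1) + 0.75 * cat2 + 0.5 * cat3
        S0 <- 2 * a2 - a3
        acc$num[ok] <- acc$num[ok] + (S - S0)
        acc$den[ok] <- acc$den[ok] + (1 - S0)
      } else { # wang
        u <- 2 * a2 - a3
        w <- 1 / u
        bb <- 2 * a2^2 - a4
        ccf <- a2 - 2 * a2^2 + a4
        dd <- 4 * (a3 - a4)
        ee <- 2 * (a2 - 3 * a3 + 2 * a4)
        ff <- 4 * (a2 - a2^2 - 2 * a3 + 2 * a4)
        gg <- 1 - 7 * a2 + 4 * a2^2 + 10 * a3 - 8 * a4
        acc$sw[ok] <- acc$sw[ok] + w
        acc$P1[ok] <- acc$P1[ok] + w * cat1
        acc$P2[ok] <- acc$P2[ok] + w * cat2
        acc$P3[ok] <- acc$P3[ok] + w * cat3
        acc$b[ok] <- acc$b[ok] + w * bb
        acc$c[ok] <- acc$c[ok] + w * ccf
        acc$d[ok] <- acc$d[ok] + w * dd
        acc$e[ok] <- acc$e[ok] + w * ee
        acc$f[ok] <- acc$f[ok] + w * ff
        acc$g[ok] <- acc$g[ok] + w * gg
      }
    }
  }

  r <- rep(NA_real_, nd)
  use <- shared >= min_shared
  if (estimator %in% c("queller_goodnight", "lynch_ritland")) {
    r[use] <- 0.5 * (acc$nx[use] / acc$dx[use] + acc$ny[use] / acc$dy[use])
  } else if (estimator == "li") {
    r[use] <- acc$num[use] / acc$den[use]
  } else {
    sw <- acc$sw[use]
    P1 <- acc$P1[use] / sw; P2 <- acc$P2[use] / sw; P3 <- acc$P3[use] / sw
    b <- acc$b[use] / sw; cc <- acc$c[use] / sw; d <- acc$d[use] / sw
    e <- acc$e[use] / sw; f <- acc$f[use] / sw; g <- acc$g[use] / sw
    # least squares for (phi, Delta) over the three category equations
    y1 <- P1 - b; y2 <- P2 - d; y3 <- P3 - f
    A1 <- cc; A2 <- e; A3 <- g
    B1 <- 1 - b; B2 <- -d; B3 <- -f
    SAA <- A1^2 + A2^2 + A3^2
    SBB <- B1^2 + B2^2 + B3^2
    SAB <- A1 * B1 + A2 * B2 + A3 * B3
    SAY <- A1 * y1 + A2 * y2 + A3 * y3
    SBY <- B1 * y1 + B2 * y2 + B3 * y3
    det <- SAA * SBB - SAB^2
    phi <- (SAY * SBB - SBY * SAB) / det
    delta <- (SBY * SAA - SAY * SAB) / det
    r[use] <- phi / 2 + delta
  }
  r
}

#' Pairwise relatedness matrix
#'
#' Computes one of the four moment estimators (see
#' [relatedness-estimators]) for every pair of individuals, over the loci
#' typed in both. Pairs sharing fewer than `min_shared` typed loci are
#' flagged missing (`NA`).
#'
#' @param ds A [genotype_dataset()].
#' @param estimator One of `"wang"`, `"queller_goodnight"`,
#'   `"lynch_ritland"`, `"li"`.
#' @param freqs Reference allele frequencies; defaults to the full sample
#'   (including each focal dyad, the common default of relatedness
#'   software).
#' @param bias_correct Apply small-sample corrections to the frequency
#'   moments used by the Wang and Li estimators (default `TRUE`; only
#'   effective when `freqs` carries sample counts).
#' @param min_shared Minimum shared typed loci per pair (default 2).
#' @return A `relatedness_matrix`: list with `r` (symmetric matrix, `NA`
#'   diagonal), `estimator`, `ids`, `mean`, `sd`, `n_pairs`.
#' @export
pairwise_relatedness <- function(ds, estimator = .estimators, freqs = NULL,
                                 bias_correct = TRUE, min_shared = 2L) {
  if (length(estimator) == 1L && !estimator %in% .estimators) {
    stop("unknown estimator tag: ", estimator)
  }
  estimator <- match.arg(estimator)
  n <- nrow(ds$geno)
  if (n < 2L) stop("need at least 2 individuals")
  if (is.null(freqs)) freqs <- allele_frequencies(ds)
  pr <- .pair_index(n)
  r <- .dyad_relatedness(ds$geno[pr$i, , drop = FALSE],
                         ds$geno[pr$j, , drop = FALSE],
                         ds$loci, freqs, estimator, bias_correct, min_shared)
  m <- matrix(NA_real_, n, n, dimnames = list(ds$meta$id, ds$meta$id))
  m[cbind(pr$i, pr$j)] <- r
  m[cbind(pr$j, pr$i)] <- r
  structure(list(r = m, estimator = estimator, ids = ds$meta$id,
                 mean = mean(r, na.rm = TRUE),
                 sd = stats::sd(r, na.rm = TRUE),
                 n_pairs = sum(!is.na(r))),
            class = "relatedness_matrix")
}

.pair_index <- function(n) {
  i <- rep.int(seq_len(n - 1L), times = (n - 1L):1L)
  j <- unlist(lapply(seq_len(n - 1L), function(k) (k + 1L):n), use.names = FALSE)
  list(i = i, j = j)
}

#' @export
print.relatedness_matrix <- function(x, ...) {
  cat(sprintf("relatedness_matrix (%s): %d individuals, %d pairs, mean r = %.4f +/- %.4f\n",
              x$estimator, length(x$ids), x$n_pairs, x$mean, x$sd))
  invisible(x)
}

#' Write a relatedness matrix
#' @param rel A `relatedness_matrix`.
#' @param path Output file.
#' @param format `"long_tsv"` (`id1 id2 estimator r`) or `"square_csv"`.
#' @return `path`, invisibly.
#' @export
write_relatedness <- function(rel, path, format = c("long_tsv", "square_csv")) {
  format <- match.arg(format)
  if (format == "square_csv") {
    utils::write.csv(rel$r, path, quote = FALSE)
  } else {
    pr <- .pair_index(length(rel$ids))
    out <- data.frame(id1 = rel$ids[pr$i], id2 = rel$ids[pr$j],
                      estimator = rel$estimator,
                      r = rel$r[cbind(pr$i, pr$j)])
    utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Simulate dyads of a known relationship
#'
#' Founder genotypes are drawn under Hardy-Weinberg from the supplied
#' frequencies and relatives constructed by explicit Mendelian transmission
#' (never by rejection toward a target r), so the true relatedness of each
#' dyad is exact: 0.5 for `parent_offspring` and `full_sib`, 0.25 for
#' `half_sib`, 0 for `unrelated`.
#'
#' @param freqs An [allele_frequencies()] table or named list of per-locus
#'   allele frequency vectors (names = allele labels).
#' @param relationship One of `"parent_offspring"`, `"full_sib"`,
#'   `"half_sib"`, `"unrelated"`.
#' @param n Number of dyads.
#' @param seed Integer RNG seed.
#' @return List: `g1`, `g2` (allele-label matrices, `n x 2L`, canonical
#'   order), `true_r`, `relationship`, `loci`.
#' @export
simulate_dyads <- function(freqs, relationship = c("parent_offspring",
                                                   "full_sib", "half_sib",
                                                   "unrelated"),
                           n, seed = 1L) {
  relationship <- match.arg(relationship)
  if (n < 1L) stop("n must be >= 1")
  fl <- if (inherits(freqs, "allele_frequency_table")) freqs$freq else freqs
  loci <- names(fl)
  L <- length(fl)
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  draw <- function(p, k) as.integer(sample(names(p), k, replace = TRUE,
                                           prob = p))
  pick <- function(h1, h2) ifelse(stats::runif(length(h1)) < 0.5, h1, h2)
  g1 <- matrix(NA_integer_, n, 2L * L)
  g2 <- matrix(NA_integer_, n, 2L * L)
  for (l in seq_len(L)) {
    p <- fl[[l]]
    P1a <- draw(p, n); P1b <- draw(p, n)        # parent 1
    P2a <- draw(p, n); P2b <- draw(p, n)        # parent 2
    P3a <- draw(p, n); P3b <- draw(p, n)        # second unshared parent
    x1 <- pick(P1a, P1b); x2 <- pick(P2a, P2b)  # offspring x of P1 x P2
    if (relationship == "parent_offspring") {
      m1 <- cbind(P1a, P1b)
      m2 <- cbind(x1, draw(p, n))               # other allele from population
    } else if (relationship == "full_sib") {
      m1 <- cbind(x1, x2)
      m2 <- cbind(pick(P1a, P1b), pick(P2a, P2b))
    } else if (relationship == "half_sib") {
      m1 <- cbind(pick(P1a, P1b), pick(P2a, P2b))
      m2 <- cbind(pick(P1a, P1b), pick(P3a, P3b))
    } else {
      m1 <- cbind(draw(p, n), draw(p, n))
      m2 <- cbind(draw(p, n), draw(p, n))
    }
    g1[, 2L * l - 1L] <- pmin(m1[, 1L], m1[, 2L])
    g1[, 2L * l] <- pmax(m1[, 1L], m1[, 2L])
    g2[, 2L * l - 1L] <- pmin(m2[, 1L], m2[, 2L])
    g2[, 2L * l] <- pmax(m2[, 1L], m2[, 2L])
  }
  true_r <- switch(relationship, parent_offspring = 0.5, full_sib = 0.5,
                   half_sib = 0.25, unrelated = 0)
  list(g1 = g1, g2 = g2, true_r = true_r, relationship = relationship,
       loci = loci)
}

#' Relatedness of simulated (or externally paired) dyads
#'
#' @param dyads Output of [simulate_dyads()] (or any list with `g1`, `g2`,
#'   `loci`).
#' @param freqs Reference frequencies (see [pairwise_relatedness()]).
#' @param estimator Estimator tag.
#' @param bias_correct See [pairwise_relatedness()].
#' @return Numeric vector of r estimates, one per dyad.
#' @export
dyad_relatedness <- function(dyads, freqs, estimator = .estimators,
                             bias_correct = TRUE) {
  estimator <- match.arg(estimator)
  .dyad_relatedness(dyads$g1, dyads$g2, dyads$loci, freqs, estimator,
                    bias_correct)
}

#' Compare relatedness estimators on simulated dyads
#'
#' Simulates all four relationship classes from the dataset's empirical
#' allele frequencies and reports each estimator's Pearson correlation
#' between estimated and true r over the pooled dyads — the standard way to
#' pick the estimator best suited to a marker panel.
#'
#' @param ds A [genotype_dataset()].
#' @param n_per_class Dyads per relationship class (default 250).
#' @param seed Integer RNG seed.
#' @param estimators Estimator tags to compare (default: all four).
#' @return Data frame `estimator`, `pearson_r`, `rank` (1 = best), sorted by
#'   rank.
#' @export
compare_estimators <- function(ds, n_per_class = 250L, seed = 1L,
                               estimators = .estimators) {
  freqs <- allele_frequencies(ds)
  classes <- c("parent_offspring", "full_sib", "half_sib", "unrelated")
  sims <- lapply(seq_along(classes), function(k) {
    simulate_dyads(freqs, classes[k], n_per_class, seed = seed + k)
  })
  true_r <- unlist(lapply(sims, function(s) rep(s$true_r, n_per_class)))
  res <- vapply(estimators, function(est) {
    est_r <- unlist(lapply(sims, dyad_relatedness, freqs = freqs,
                           estimator = est))
    stats::cor(est_r, true_r, use = "complete.obs")
  }, numeric(1))
  out <- data.frame(estimator = estimators, pearson_r = as.numeric(res),
                    stringsAsFactors = FALSE)
  out$rank <- rank(-out$pearson_r, ties.method = "first")
  out[order(out$rank), , drop = FALSE]
}

#' Ritland's method-of-moments individual inbreeding coefficient
#'
#' Per locus the homozygosity indicator is contrasted with its
#' Hardy-Weinberg expectation: a homozygote for allele `a` contributes
#' `1/p_a - 1`, a heterozygote `-1`, and each locus carries weight
#' `n_alleles - 1`. The multilocus estimate is the ratio of summed
#' contributions to summed weights, so more polymorphic loci count for
#' more. Values may be negative (fewer homozygotes than expected).
#'
#' @param ds A [genotype_dataset()].
#' @param freqs Reference allele frequencies (default: full sample).
#' @return Named numeric vector of F estimates, `NA` for individuals with no
#'   typed polymorphic locus.
#' @export
ritland_inbreeding <- function(ds, freqs = NULL) {
  if (is.null(freqs)) freqs <- allele_frequencies(ds)
  fr <- .as_freqs(freqs, ds$loci)
  n <- nrow(ds$geno)
  num <- numeric(n); den <- numeric(n)
  for (l in seq_along(ds$loci)) {
    p <- fr$freq[[l]]
    if (length(p) < 2L) next
    labels <- as.integer(names(p))
    al <- locus_alleles(ds, l)
    a <- match(al[, 1L], labels); b <- match(al[, 2L], labels)
    ok <- !is.na(a) & !is.na(b)
    hom <- ok & a == b
    contrib <- numeric(n)
    contrib[ok] <- -1
    contrib[hom] <- 1 / p[a[hom]] - 1
    num <- num + contrib
    den <- den + ok * (length(p) - 1L)
  }
  f <- ifelse(den > 0, num / den, NA_real_)
  stats::setNames(f, ds$meta$id)
}

#' Greedy selection of a mutually unrelated subset
#'
#' While any pair has relatedness at or above `threshold`, the individual participating in the
#' most such pairs is removed (ties broken by removing the individual
#' earliest in id order). The
#' returned subset has all pairwise r below the threshold. This is a
#' documented greedy stand-in for proprietary subset-pickers; it need not
#' find the maximum such subset.
#'
#' @param rel A `relatedness_matrix`.
#' @param threshold Relatedness cutoff (default 0.24, just below the
#'   half-sibling expectation of 0.25).
#' @return Character vector of retained individual ids.
#' @export
select_unrelated <- function(rel, threshold = 0.24) {
  adj <- !is.na(rel$r) & rel$r >= threshold
  diag(adj) <- FALSE
  keep <- rep(TRUE, nrow(adj))
  repeat {
    deg <- rowSums(adj[, keep, drop = FALSE]) * keep
    if (all(deg == 0)) break
    drop <- which.max(deg)  # tie -> remove the lower (earlier) id
    keep[drop] <- FALSE
    adj[drop, ] <- FALSE
    adj[, drop] <- FALSE
  }
  rel$ids[keep]
}
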