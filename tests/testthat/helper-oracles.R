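# independent brute-force oracles; each is a from-scratch transcription,
# deliberately sharing no code path with the package internals it checks

# ---- Hardy-Weinberg: full enumeration of Levene-conditional tables -------
# enumerates every perfect matching of the 2n allele copies into n diploid
# genotypes; matching counts are proportional to the conditional table
# probabilities under random union of gametes given allele counts
hwe_enumerate <- function(al) {
  copies <- c(al[, 1], al[, 2])
  env <- new.env()
  rec <- function(rem, acc) {
    if (!length(rem)) {
      key <- paste(sort(acc), collapse = ";")
      env[[key]] <- (if (is.null(env[[key]])) 0 else env[[key]]) + 1
      return(invisible())
    }
    a <- rem[1]
    for (k in 2:length(rem)) {
      b <- rem[k]
      rec(rem[-c(1, k)], c(acc, paste(min(a, b), max(a, b))))
    }
  }
  rec(copies, character(0))
  keys <- ls(env)
  w <- vapply(keys, function(k) env[[k]], numeric(1))
  data.frame(table = keys, prob = w / sum(w), stringsAsFactors = FALSE)
}

# exact p under probability ordering: total probability of tables no more
# probable than the observed one
hwe_exact_p <- function(al) {
  enum <- hwe_enumerate(al)
  lo <- pmin(al[, 1], al[, 2]); hi <- pmax(al[, 1], al[, 2])
  obs_key <- paste(sort(paste(lo, hi)), collapse = ";")
  obs_p <- enum$prob[enum$table == obs_key]
  sum(enum$prob[enum$prob <= obs_p + 1e-12])
}

# ---- Benjamini-Hochberg by exhaustive threshold search -------------------
bh_brute <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  # largest k with p_(k) <= k q / m; reject the k smallest
  ks <- which(p[ord] <= seq_len(m) * q / m)
  rejected <- rep(FALSE, m)
  if (length(ks)) rejected[ord[seq_len(max(ks))]] <- TRUE
  # adjusted p: min over j >= rank of m p_(j) / j, capped at 1
  sorted <- p[ord]
  adj_sorted <- rev(cummin(rev(sorted * m / seq_len(m))))
  adj <- numeric(m)
  adj[ord] <- pmin(adj_sorted, 1)
  list(adjusted = adj, rejected = rejected)
}

# ---- correlogram r by direct transcription -------------------------------
# squared genetic distance by explicit per-genotype case analysis
sq_dist_brute <- function(g1, g2) {
  # g1, g2: length-2 allele vectors
  v <- function(g) {
    alle <- sort(unique(c(g1, g2)))
    cnt <- numeric(length(alle))
    for (a in g) cnt[match(a, alle)] <- cnt[match(a, alle)] + 1
    cnt
  }
  sum((v(g1) - v(g2))^2) / 2
}

genetic_D_brute <- function(ds) {
  n <- nrow(ds$geno)
  L <- length(ds$loci)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    tot <- 0
    for (l in seq_len(L)) {
      g1 <- ds$geno[i, c(2 * l - 1, 2 * l)]
      g2 <- ds$geno[j, c(2 * l - 1, 2 * l)]
      if (anyNA(g1) || anyNA(g2)) next
      tot <- tot + sq_dist_brute(g1, g2)
    }
    D[i, j] <- tot
  }
  D
}

# class r by scalar loops from the squared-distance matrix
correlogram_r_brute <- function(D, class_of_pair) {
  n <- nrow(D)
  C <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    C[i, j] <- -0.5 * (D[i, j] - mean(D[i, ]) - mean(D[, j]) + mean(D))
  }
  ncl <- max(class_of_pair, na.rm = TRUE)
  r <- numeric(ncl)
  for (h in seq_len(ncl)) {
    num <- den <- 0
    k <- 0
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      k <- k + 1
      if (!is.na(class_of_pair[k]) && class_of_pair[k] == h) {
        num <- num + C[i, j]
        den <- den + (C[i, i] + C[j, j]) / 2
      }
    }
    r[h] <- num / den
  }
  r
}

# ---- Wang-category estimator via lm() on a single dyad -------------------
wang_brute <- function(g1, g2, freq_list, bias_correct = TRUE,
                       n_typed = NULL) {
  sw <- 0; P <- c(0, 0, 0); coefs <- rep(0, 6)
  for (l in seq_along(freq_list)) {
    p <- freq_list[[l]]
    if (length(p) < 2) next
    lab <- as.integer(names(p))
    a <- g1[2 * l - 1]; b <- g1[2 * l]
    cc <- g2[2 * l - 1]; d <- g2[2 * l]
    if (anyNA(c(a, b, cc, d))) next
    if (!all(c(a, b, cc, d) %in% lab)) next
    if (bias_correct && !is.null(n_typed)) {
      N <- 2 * n_typed[l]
      cnt <- p * N
      a2 <- sum(cnt * (cnt - 1)) / (N * (N - 1))
      a3 <- sum(cnt * (cnt - 1) * (cnt - 2)) / (N * (N - 1) * (N - 2))
      a4 <- sum(cnt * (cnt - 1) * (cnt - 2) * (cnt - 3)) /
        (N * (N - 1) * (N - 2) * (N - 3))
    } else {
      a2 <- sum(p^2); a3 <- sum(p^3); a4 <- sum(p^4)
    }
    G1 <- sort(c(a, b)); G2 <- sort(c(cc, d))
    n_shared <- length(intersect(G1, G2))
    cat <- if (identical(G1, G2)) 1
      else if (n_shared >= 1 && xor(a == b, cc == d)) 2
      else if (n_shared >= 1 && a != b && cc != d) 3
      else 4
    w <- 1 / (2 * a2 - a3)
    sw <- sw + w
    P <- P + w * (cat == 1:3)
    coefs <- coefs + w * c(2 * a2^2 - a4,
                           a2 - 2 * a2^2 + a4,
                           4 * (a3 - a4),
                           2 * (a2 - 3 * a3 + 2 * a4),
                           4 * (a2 - a2^2 - 2 * a3 + 2 * a4),
                           1 - 7 * a2 + 4 * a2^2 + 10 * a3 - 8 * a4)
  }
  P <- P / sw
  k <- coefs / sw
  y <- c(P[1] - k[1], P[2] - k[3], P[3] - k[5])
  A <- c(k[2], k[4], k[6])
  B <- c(1 - k[1], -k[3], -k[5])
  fit <- stats::lm(y ~ 0 + A + B)
  unname(stats::coef(fit)["A"] / 2 + stats::coef(fit)["B"])
}

# ---- greedy vs exhaustive unrelated subset -------------------------------
max_unrelated_brute <- function(rmat, threshold) {
  n <- nrow(rmat)
  best <- integer(0)
  for (sz in n:1) {
    combs <- utils::combn(n, sz)
    for (c_ in seq_len(ncol(combs))) {
      s <- combs[, c_]
      sub <- rmat[s, s, drop = FALSE]
      diag(sub) <- NA
      if (all(is.na(sub) | sub < threshold)) return(s)
    }
  }
  best
}
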