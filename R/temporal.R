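#' Assign breeding-timing classes by k-means
#'
#' One-dimensional Lloyd k-means on hatch day (days since the season's
#' first hatch) with `nstart` random restarts under a fixed seed; classes
#' are relabelled in ascending order of their mean hatch day, so class 1 is
#' always the earliest breeders.
#'
#' @param hatch_days Numeric vector (NA allowed; those individuals get
#'   class NA), or a [genotype_dataset()] with `hatch_day` metadata.
#' @param k Number of classes (default 4).
#' @param seed Integer RNG seed.
#' @param nstart Random restarts (default 25).
#' @return A `timing_class_assignment`: `class` (integer per input value),
#'   `class_mean`, `class_sd`, `class_size` (each length k, ascending
#'   means), `k`, `withinss` (total within-class sum of squares).
#' @export
assign_timing_classes <- function(hatch_days, k = 4L, seed = 1L,
                                  nstart = 25L) {
  if (inherits(hatch_days, "genotype_dataset")) {
    hatch_days <- hatch_days$meta$hatch_day
  }
  hatch_days <- as.numeric(hatch_days)
  ok <- !is.na(hatch_days)
  vals <- hatch_days[ok]
  if (length(unique(vals)) < k) {
    stop("fewer distinct hatch-day values (", length(unique(vals)),
         ") than classes (", k, ")")
  }
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  km <- stats::kmeans(matrix(vals, ncol = 1L), centers = k, nstart = nstart,
                      algorithm = "Lloyd", iter.max = 100L)
  ord <- order(km$centers[, 1L])
  relabel <- match(seq_len(k), ord)
  cls <- relabel[km$cluster]
  out_class <- rep(NA_integer_, length(hatch_days))
  out_class[ok] <- cls
  structure(list(
    class = out_class,
    class_mean = vapply(seq_len(k), function(c_) mean(vals[cls == c_]),
                        numeric(1)),
    class_sd = vapply(seq_len(k), function(c_) stats::sd(vals[cls == c_]),
                      numeric(1)),
    class_size = tabulate(cls, k),
    k = as.integer(k),
    withinss = km$tot.withinss), class = "timing_class_assignment")
}

#' @export
print.timing_class_assignment <- function(x, ...) {
  cat("timing classes:",
      paste(sprintf("%d: %.0f +/- %.0f d (n=%d)", seq_len(x$k),
                    x$class_mean, x$class_sd, x$class_size),
            collapse = "; "), "\n")
  invisible(x)
}

#' Silhouette-based choice of the number of timing classes
#'
#' Helper (not part of the replication path): mean silhouette width of the
#' 1-D k-means solution for each candidate k.
#'
#' @param hatch_days Numeric vector.
#' @param k_range Candidate class counts.
#' @param seed Integer RNG seed.
#' @return Data frame `k`, `mean_silhouette`; the maximising k is a
#'   reasonable default.
#' @export
choose_k_timing <- function(hatch_days, k_range = 2:8, seed = 1L) {
  hatch_days <- as.numeric(hatch_days[!is.na(hatch_days)])
  d <- abs(outer(hatch_days, hatch_days, "-"))
  sil <- vapply(k_range, function(k) {
    a <- assign_timing_classes(hatch_days, k = k, seed = seed)
    cl <- a$class
    s <- vapply(seq_along(hatch_days), function(i) {
      own <- cl == cl[i]
      ai <- if (sum(own) > 1L) mean(d[i, own & seq_along(cl) != i]) else 0
      bi <- min(vapply(setdiff(seq_len(k), cl[i]), function(c_) {
        mean(d[i, cl == c_])
      }, numeric(1)))
      if (max(ai, bi) > 0) (bi - ai) / max(ai, bi) else 0
    }, numeric(1))
    mean(s)
  }, numeric(1))
  data.frame(k = k_range, mean_silhouette = sil)
}

#' Pairwise G''ST between breeding-timing classes
#'
#' Delegates to the differentiation machinery for every class pair and
#' annotates each with the gap between class mean hatch days — the
#' isolation-by-time contrast of earliest versus latest breeders.
#'
#' @param ds A [genotype_dataset()] (individuals with class NA are dropped
#'   per pair).
#' @param classes A [assign_timing_classes()] result aligned with `ds`
#'   rows, or an integer class vector.
#' @param n_perm,n_boot Replicates per class pair.
#' @param seed Integer RNG seed.
#' @param min_class_size Smallest usable class (default 5).
#' @return Data frame per class pair: `class_a`, `class_b`,
#'   `gst_double_prime`, `p_value`, `ci_lower`, `ci_upper`, `day_gap`,
#'   `n_a`, `n_b`.
#' @export
timing_class_differentiation <- function(ds, classes, n_perm = 999L,
                                         n_boot = 999L, seed = 1L,
                                         min_class_size = 5L) {
  if (inherits(classes, "timing_class_assignment")) {
    cls <- classes$class
    means <- classes$class_mean
  } else {
    cls <- as.integer(classes)
    means <- vapply(sort(unique(cls[!is.na(cls)])), function(c_) {
      mean(ds$meta$hatch_day[which(cls == c_)], na.rm = TRUE)
    }, numeric(1))
  }
  if (length(cls) != nrow(ds$geno)) stop("classes must align with dataset rows")
  ks <- sort(unique(cls[!is.na(cls)]))
  sizes <- tabulate(cls, max(ks))
  if (any(sizes[ks] < min_class_size)) {
    stop("every class needs >= ", min_class_size, " individuals")
  }
  pairs <- utils::combn(ks, 2L)
  out <- lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    sel <- which(!is.na(cls) & cls %in% c(a, b))
    sub <- subset_dataset(ds, individuals = sel)
    res <- differentiation_test(sub, ifelse(cls[sel] == a, "A", "B"),
                                n_perm = n_perm, n_boot = n_boot,
                                seed = seed + j)
    data.frame(class_a = a, class_b = b,
               gst_double_prime = res$gst_double_prime,
               p_value = res$p_value,
               ci_lower = res$ci["lower"], ci_upper = res$ci["upper"],
               day_gap = abs(means[b] - means[a]),
               n_a = sum(cls[sel] == a), n_b = sum(cls[sel] == b))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Mantel test between two pairwise matrices
#'
#' Pearson correlation of the lower-triangle entries (e.g. pairwise
#' relatedness against absolute hatch-day difference), with significance
#' from jointly permuting the rows and columns of one matrix. Two-tailed by
#' default.
#'
#' @param matA,matB Symmetric matrices over the same individuals.
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer RNG seed.
#' @param tail `"two"` (default) or `"one"` (positive association).
#' @return List: `r`, `R2`, `p_value`, `n_perm`, `tail`.
#' @export
mantel_test <- function(matA, matB, n_perm = 999L, seed = 1L,
                        tail = c("two", "one")) {
  tail <- match.arg(tail)
  if (!all(dim(matA) == dim(matB))) stop("matrices must match in size")
  n <- nrow(matA)
  pr <- .pair_index(n)
  ij <- cbind(pr$i, pr$j)
  a <- matA[ij]; b <- matB[ij]
  ok <- !is.na(a) & !is.na(b)
  if (stats::sd(a[ok]) == 0 || stats::sd(b[ok]) == 0) {
    stop("constant matrix: correlation undefined")
  }
  obs <- stats::cor(a[ok], b[ok])
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  hits <- 0L
  for (k in seq_len(n_perm)) {
    p <- sample.int(n)
    bp <- matB[cbind(p[pr$i], p[pr$j])]
    rp <- stats::cor(a[ok], bp[ok])
    extreme <- if (tail == "two") abs(rp) >= abs(obs) - 1e-12 else
      rp >= obs - 1e-12
    if (!is.na(rp) && extreme) hits <- hits + 1L
  }
  list(r = obs, R2 = obs^2, p_value = (hits + 1) / (n_perm + 1),
       n_perm = n_perm, tail = tail)
}

#' Pairwise absolute difference matrix
#' @param values Numeric vector (e.g. hatch days).
#' @param ids Optional dimnames.
#' @return Symmetric matrix of `|v_i - v_j|`.
#' @export
pairwise_abs_diff <- function(values, ids = NULL) {
  m <- abs(outer(values, values, "-"))
  if (!is.null(ids)) dimnames(m) <- list(ids, ids)
  m
}

#' Ladder-of-powers (Tukey) transformation toward normality
#'
#' Chooses the exponent `lambda` on the grid `[-5, 5]` in steps of 0.025
#' that maximises the Shapiro-Wilk W statistic of the transformed values:
#' `x^lambda` for `lambda > 0`, `log(x)` at `lambda = 0`, `-x^lambda` for
#' `lambda < 0` (negation keeps the transform monotone increasing).
#' Non-positive inputs are shifted by `1 - min(x)` first (recorded).
#'
#' @param values Numeric vector (n between 3 and 5000 for the W statistic).
#' @return List: `transformed`, `lambda`, `shift`, `W`.
#' @export
tukey_transform <- function(values) {
  x <- as.numeric(values)
  ok <- !is.na(x)
  if (sum(ok) < 3L) stop("need >= 3 values")
  shift <- 0
  if (min(x[ok]) <= 0) {
    shift <- 1 - min(x[ok])
    x <- x + shift
  }
  if (stats::sd(x[ok]) == 0) {
    warning("constant input: returning lambda = 1")
    return(list(transformed = x - shift, lambda = 1, shift = shift, W = NA))
  }
  grid <- seq(-5, 5, by = 0.025)
  apply_l <- function(l) {
    if (l > 0) x[ok]^l else if (l == 0) log(x[ok]) else -(x[ok]^l)
  }
  w <- vapply(grid, function(l) {
    tx <- apply_l(l)
    if (any(!is.finite(tx)) || stats::sd(tx) == 0) return(-Inf)
    tryCatch(stats::shapiro.test(tx)$statistic, error = function(e) -Inf)
  }, numeric(1))
  lam <- grid[which.max(w)]
  out <- rep(NA_real_, length(x))
  out[ok] <- apply_l(lam)
  list(transformed = out, lambda = lam, shift = shift, W = max(w))
}

#' Regression of individual inbreeding on breeding timing
#'
#' Ordinary least squares of the Ritland inbreeding coefficient on
#' Tukey-transformed hatch day; reports the overall F statistic with its
#' degrees of freedom `(1, n - 2)`, R-squared and p-value.
#'
#' @param F_est Numeric vector of inbreeding coefficients (e.g. from
#'   [ritland_inbreeding()]).
#' @param hatch_days Numeric vector, same length.
#' @param transform Apply [tukey_transform()] to the predictor (default
#'   `TRUE`).
#' @return List: `F_stat`, `df` (length 2), `R2`, `p_value`, `slope`,
#'   `lambda` (NA when `transform = FALSE`), `n`.
#' @export
inbreeding_timing_regression <- function(F_est, hatch_days,
                                         transform = TRUE) {
  ok <- !is.na(F_est) & !is.na(hatch_days)
  if (sum(ok) < 3L) stop("need >= 3 paired observations")
  y <- F_est[ok]
  x <- hatch_days[ok]
  if (stats::sd(x) == 0) stop("zero variance in predictor")
  lambda <- NA_real_
  if (transform) {
    tt <- tukey_transform(x)
    x <- tt$transformed
    lambda <- tt$lambda
  }
  fit <- stats::lm(y ~ x)
  s <- summary(fit)
  fs <- s$fstatistic
  list(F_stat = unname(fs[1]), df = unname(fs[2:3]), R2 = s$r.squared,
       p_value = unname(stats::pf(fs[1], fs[2], fs[3], lower.tail = FALSE)),
       slope = unname(stats::coef(fit)[2]), lambda = lambda, n = sum(ok))
}
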