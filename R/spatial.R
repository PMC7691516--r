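#' Pairwise geographic distances
#'
#' Euclidean distances over planar metre coordinates. Longitude/latitude
#' input should be pre-projected (at colony scale an equirectangular
#' projection about the centroid is adequate; see [project_lonlat()]).
#' Individuals with missing coordinates are excluded with a warning.
#'
#' @param ds A [genotype_dataset()] with `x`/`y` metadata (or a 2-column
#'   matrix/data frame of coordinates).
#' @return Symmetric distance matrix (metres) with zero diagonal, dimnames
#'   set to individual ids; attribute `"kept"` gives the row index used.
#' @export
geographic_distances <- function(ds) {
  if (inherits(ds, "genotype_dataset")) {
    xy <- cbind(ds$meta$x, ds$meta$y)
    ids <- ds$meta$id
  } else {
    xy <- as.matrix(ds)[, 1:2, drop = FALSE]
    ids <- rownames(ds)
    if (is.null(ids)) ids <- as.character(seq_len(nrow(xy)))
  }
  keep <- stats::complete.cases(xy)
  if (!all(keep)) {
    warning(sum(!keep), " individual(s) excluded: missing coordinates")
  }
  m <- as.matrix(stats::dist(xy[keep, , drop = FALSE]))
  dimnames(m) <- list(ids[keep], ids[keep])
  attr(m, "kept") <- which(keep)
  m
}

#' Project longitude/latitude to local planar metres
#'
#' Equirectangular projection about the centroid; adequate below ~1 km
#' extent where curvature error is negligible.
#'
#' @param lon,lat Numeric degree vectors.
#' @return Data frame `x`, `y` in metres.
#' @export
project_lonlat <- function(lon, lat) {
  R <- 6371008.8
  lat0 <- mean(lat, na.rm = TRUE) * pi / 180
  data.frame(x = (lon - mean(lon, na.rm = TRUE)) * pi / 180 * R * cos(lat0),
             y = (lat - mean(lat, na.rm = TRUE)) * pi / 180 * R)
}

#' Multilocus squared genetic distance (codominant metric)
#'
#' Per locus, genotypes are coded as allele-count vectors and the squared
#' distance is half the squared Euclidean distance between them — the
#' codominant genotypic metric of multilocus spatial autocorrelation
#' analysis: identical genotypes 0; AA-AB 1; AB-AC 1; AB-CD 2; AA-BC 3;
#' AA-BB 4. Locus values are summed over loci. Pairs missing a locus get
#' that locus's mean observed pair distance (linear interpolation), so the
#' returned matrix is complete whenever every pair shares at least one
#' typed locus.
#'
#' @param ds A [genotype_dataset()].
#' @param loci Optional locus subset.
#' @return Symmetric `n x n` matrix of summed squared distances, zero
#'   diagonal.
#' @export
squared_genetic_distance <- function(ds, loci = NULL) {
  if (!is.null(loci)) ds <- subset_dataset(ds, loci = loci)
  n <- nrow(ds$geno)
  pr <- .pair_index(n)
  total <- numeric(length(pr$i))
  any_shared <- logical(length(pr$i))
  for (l in seq_along(ds$loci)) {
    al <- locus_alleles(ds, l)
    a <- al[pr$i, 1L]; b <- al[pr$i, 2L]
    cc <- al[pr$j, 1L]; d <- al[pr$j, 2L]
    ok <- !is.na(a) & !is.na(cc)
    # d2 = (|v1|^2 + |v2|^2)/2 - v1.v2 with |v|^2 = 4 (hom) or 2 (het)
    h1 <- 1 + (a == b); h2 <- 1 + (cc == d)
    dot <- (a == cc) + (a == d) + (b == cc) + (b == d)
    d2 <- h1 + h2 - dot
    if (any(ok)) {
      fill <- mean(d2[ok])
      d2[!ok] <- fill
      total <- total + d2
      any_shared <- any_shared | ok
    }
  }
  if (!all(any_shared)) {
    warning(sum(!any_shared), " pair(s) share no typed locus; distance is ",
            "locus-mean imputed throughout")
  }
  m <- matrix(0, n, n, dimnames = list(ds$meta$id, ds$meta$id))
  m[cbind(pr$i, pr$j)] <- total
  m[cbind(pr$j, pr$i)] <- total
  m
}

#' Assign pairwise distances to distance classes
#'
#' `even_width` bins pairs into fixed-width half-open classes `[lo, hi)` up
#' to `max_dist` (pairs beyond it are excluded, class `NA`); zero distances
#' fall in the first class. `even_count` splits all pairs into classes of
#' equal pair counts (sizes differing by at most 1), ties broken by pair
#' order, covering every pair.
#'
#' @param distances Symmetric geographic distance matrix (or a pair vector
#'   in row-major upper-triangle order).
#' @param mode `"even_width"` or `"even_count"`.
#' @param n_classes Number of classes.
#' @param max_dist Upper bound for `even_width` (default: max pair
#'   distance).
#' @return A `distance_classes` list: `class` (integer per pair, `NA`
#'   excluded), `edges` (for `even_width`), `n_classes`, `mode`,
#'   `pair_count` per class, `mean_dist` per class.
#' @export
build_distance_classes <- function(distances, mode = c("even_width",
                                                       "even_count"),
                                   n_classes, max_dist = NULL) {
  mode <- match.arg(mode)
  d <- if (is.matrix(distances)) {
    pr <- .pair_index(nrow(distances))
    distances[cbind(pr$i, pr$j)]
  } else as.numeric(distances)
  if (n_classes < 1L) stop("n_classes must be positive")
  if (n_classes > length(d)) stop("more classes than pairs")
  if (mode == "even_width") {
    if (is.null(max_dist)) max_dist <- max(d)
    edges <- seq(0, max_dist, length.out = n_classes + 1L)
    cl <- findInterval(d, edges, rightmost.closed = TRUE, left.open = FALSE)
    cl[d > max_dist] <- NA_integer_
    cl[cl == 0L] <- 1L
  } else {
    edges <- NULL
    ord <- order(d)  # stable: ties keep pair-id order
    sizes <- rep(length(d) %/% n_classes, n_classes)
    extra <- length(d) %% n_classes
    if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
    cl <- integer(length(d))
    cl[ord] <- rep(seq_len(n_classes), times = sizes)
  }
  structure(list(class = cl, edges = edges, n_classes = as.integer(n_classes),
                 mode = mode,
                 pair_count = tabulate(cl, n_classes),
                 mean_dist = vapply(seq_len(n_classes), function(h) {
                   if (any(cl == h, na.rm = TRUE))
                     mean(d[which(cl == h)]) else NA_real_
                 }, numeric(1))),
            class = "distance_classes")
}

# double-centered genotypic covariance surface (principal-coordinate
# centering of the squared-distance matrix)
.genetic_covariance <- function(D) {
  n <- nrow(D)
  rm_ <- rowMeans(D)
  gm <- mean(D)
  -0.5 * (D - outer(rm_, rep(1, n)) - outer(rep(1, n), rm_) + gm)
}

# class-wise autocorrelation r from a covariance surface
.class_r <- function(C, pi_, pj_, cl, n_classes, diag_C = diag(C)) {
  cij <- C[cbind(pi_, pj_)]
  dsum <- (diag_C[pi_] + diag_C[pj_]) / 2
  num <- den <- rep(NA_real_, n_classes)
  ok <- !is.na(cl)
  num_t <- rowsum(cij[ok], cl[ok])
  den_t <- rowsum(dsum[ok], cl[ok])
  idx <- as.integer(rownames(num_t))
  num[idx] <- num_t; den[idx] <- den_t
  list(r = num / den, num = num, den = den)
}

#' Multilocus spatial autocorrelation correlogram
#'
#' For each distance class the autocorrelation coefficient `r` is the sum
#' of off-diagonal entries of the double-centered genotypic covariance
#' surface over pairs in the class, divided by the matching diagonal sum —
#' a correlation-like quantity in `[-1, 1]`. Permuting genotypes over
#' locations gives a per-class null envelope and the whole-correlogram
#' omega heterogeneity statistic (the sum over classes of squared
#' permutation-standardized deviations of `r`), whose p-value comes from
#' the same permutation distribution. Bootstrap confidence intervals
#' resample pairs within each class. By convention the correlogram is
#' called significant at `alpha = 0.01`.
#'
#' @param ds A [genotype_dataset()].
#' @param coords Geographic distance matrix from [geographic_distances()]
#'   (or `NULL` to compute it from `ds`).
#' @param classes A [build_distance_classes()] result (or `NULL`: even-width
#'   classes via `n_classes`, `max_dist`).
#' @param n_classes,max_dist Used only when `classes` is `NULL`.
#' @param n_perm,n_boot Permutation and bootstrap replicates (default 999).
#' @param seed Integer RNG seed.
#' @param subset Optional individual subset (ids or index).
#' @return A `correlogram` object: data frame `classes` (per class: `r`,
#'   bootstrap CI, permutation 95% envelope, pair count, mean distance),
#'   `omega`, `omega_p`, `n_perm`, `n_boot`, `alpha`.
#' @export
spatial_correlogram <- function(ds, coords = NULL, classes = NULL,
                                n_classes = 5L, max_dist = NULL,
                                n_perm = 999L, n_boot = 999L, seed = 1L,
                                subset = NULL) {
  if (!is.null(subset)) ds <- subset_dataset(ds, individuals = subset)
  if (is.null(coords)) coords <- geographic_distances(ds)
  kept <- attr(coords, "kept")
  if (!is.null(kept) && length(kept) < nrow(ds$geno)) {
    ds <- subset_dataset(ds, individuals = kept)
  }
  n <- nrow(ds$geno)
  if (n < 4L) stop("need >= 4 individuals with coordinates")
  if (n < 10L) warning("fewer than 10 individuals: correlogram will be noisy")
  if (is.null(classes)) {
    classes <- build_distance_classes(coords, "even_width", n_classes,
                                      max_dist)
  }
  D <- squared_genetic_distance(ds)
  C <- .genetic_covariance(D)
  pr <- .pair_index(n)
  cl <- classes$class
  nc <- classes$n_classes
  empty <- which(tabulate(cl, nc) == 0L)
  if (length(empty)) {
    warning("dropping empty distance class(es): ",
            paste(empty, collapse = ", "))
  }
  obs <- .class_r(C, pr$i, pr$j, cl, nc)

  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  perm_r <- matrix(NA_real_, n_perm, nc)
  dC <- diag(C)
  for (b in seq_len(n_perm)) {
    p <- sample.int(n)
    perm_r[b, ] <- .class_r(C, p[pr$i], p[pr$j], cl, nc, dC)$r
  }
  mu <- colMeans(perm_r)
  sdv <- apply(perm_r, 2L, stats::sd)
  usable <- which(!is.na(obs$r) & !is.na(sdv) & sdv > 0)
  omega <- sum(((obs$r - mu)[usable] / sdv[usable])^2)
  omega_perm <- rowSums(((perm_r[, usable, drop = FALSE] -
                            matrix(mu[usable], n_perm, length(usable),
                                   byrow = TRUE)) /
                           matrix(sdv[usable], n_perm, length(usable),
                                  byrow = TRUE))^2)
  omega_p <- (sum(omega_perm >= omega - 1e-12) + 1) / (n_perm + 1)

  boot_lo <- boot_hi <- rep(NA_real_, nc)
  cij <- C[cbind(pr$i, pr$j)]
  dsum <- (dC[pr$i] + dC[pr$j]) / 2
  for (h in if (n_boot >= 1L) seq_len(nc) else integer(0)) {
    in_h <- which(!is.na(cl) & cl == h)
    if (length(in_h) < 2L) next
    reps <- vapply(seq_len(n_boot), function(b) {
      take <- sample(in_h, length(in_h), replace = TRUE)
      sum(cij[take]) / sum(dsum[take])
    }, numeric(1))
    qs <- stats::quantile(reps, c(0.025, 0.975), names = FALSE)
    boot_lo[h] <- qs[1]; boot_hi[h] <- qs[2]
  }
  env <- apply(perm_r, 2L, stats::quantile, probs = c(0.025, 0.975),
               na.rm = TRUE)
  tab <- data.frame(class = seq_len(nc),
                    lower_edge = if (!is.null(classes$edges))
                      classes$edges[seq_len(nc)] else NA_real_,
                    upper_edge = if (!is.null(classes$edges))
                      classes$edges[-1] else NA_real_,
                    mean_dist = classes$mean_dist,
                    n_pairs = tabulate(cl, nc),
                    r = obs$r, boot_lower = boot_lo, boot_upper = boot_hi,
                    null_lower = env[1, ], null_upper = env[2, ])
  structure(list(classes = tab, omega = omega, omega_p = omega_p,
                 n_perm = n_perm, n_boot = n_boot, alpha = 0.01,
                 mode = classes$mode),
            class = "correlogram")
}

#' @export
print.correlogram <- function(x, ...) {
  cat(sprintf("correlogram: %d classes, omega = %.2f, P = %.3f (alpha = %.2f)\n",
              nrow(x$classes), x$omega, x$omega_p, x$alpha))
  invisible(x)
}

#' Write a correlogram as TSV
#' @param cg A `correlogram`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_correlogram <- function(cg, path) {
  utils::write.table(cg$classes, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Sex-stratified correlogram comparison
#'
#' Computes per-sex correlograms on a common distance-class definition and
#' contrasts the two r-vectors with a heterogeneity statistic: the sum over
#' classes of squared sex-label-permutation-standardized differences
#' `r_M - r_F`, with p from permuting sex labels — a test for sex-biased
#' dispersal.
#'
#' @param ds A [genotype_dataset()] with `sex` metadata (`"M"`/`"F"`).
#' @param coords Optional distance matrix.
#' @param classes Optional common [build_distance_classes()] spec applied
#'   within each sex (`NULL`: even-width classes via `n_classes`,
#'   `max_dist` from the pooled pairs).
#' @param n_classes,max_dist Class construction when `classes` is `NULL`.
#' @param n_perm Sex-label permutations.
#' @param seed Integer RNG seed.
#' @return List: `omega_between_sexes`, `p_value`, `r_by_sex` (matrix class
#'   x sex), `n_perm`.
#' @export
sex_stratified_comparison <- function(ds, coords = NULL, classes = NULL,
                                      n_classes = 5L, max_dist = NULL,
                                      n_perm = 999L, seed = 1L) {
  sex <- toupper(as.character(ds$meta$sex))
  keep <- sex %in% c("M", "F") & !is.na(ds$meta$x) & !is.na(ds$meta$y)
  ds2 <- subset_dataset(ds, individuals = which(keep))
  sex <- sex[keep]
  if (length(unique(sex)) < 2L) stop("both sexes must be present")
  if (min(table(sex)) < 10L) stop("need >= 10 individuals of each sex")
  n <- nrow(ds2$geno)
  if (is.null(coords)) coords <- geographic_distances(ds2)
  pr <- .pair_index(n)
  dvec <- coords[cbind(pr$i, pr$j)]
  if (is.null(classes)) {
    if (is.null(max_dist)) max_dist <- max(dvec)
    edges <- seq(0, max_dist, length.out = n_classes + 1L)
  } else {
    edges <- classes$edges
    n_classes <- classes$n_classes
    if (is.null(edges)) stop("sex comparison needs even-width classes")
  }
  cl_all <- findInterval(dvec, edges, rightmost.closed = TRUE)
  cl_all[dvec > edges[length(edges)]] <- NA_integer_
  cl_all[cl_all == 0L] <- 1L
  D <- squared_genetic_distance(ds2)
  C <- .genetic_covariance(D)
  dC <- diag(C)
  same_sex <- function(sx) {
    # r-vector per sex over within-sex pairs, common class edges
    vapply(c("M", "F"), function(s) {
      use <- sx[pr$i] == s & sx[pr$j] == s
      .class_r(C, pr$i[use], pr$j[use], cl_all[use], n_classes, dC)$r
    }, numeric(n_classes))
  }
  obs <- same_sex(sex)
  obs_diff <- obs[, "M"] - obs[, "F"]
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  diffs <- matrix(NA_real_, n_perm, n_classes)
  for (b in seq_len(n_perm)) {
    d2 <- same_sex(sample(sex))
    diffs[b, ] <- d2[, "M"] - d2[, "F"]
  }
  mu <- colMeans(diffs, na.rm = TRUE)
  sdv <- apply(diffs, 2L, stats::sd, na.rm = TRUE)
  usable <- which(!is.na(obs_diff) & !is.na(sdv) & sdv > 0)
  omega <- sum(((obs_diff - mu)[usable] / sdv[usable])^2)
  omega_perm <- rowSums(((diffs[, usable, drop = FALSE] -
                            matrix(mu[usable], n_perm, length(usable),
                                   byrow = TRUE)) /
                           matrix(sdv[usable], n_perm, length(usable),
                                  byrow = TRUE))^2, na.rm = TRUE)
  p <- (sum(omega_perm >= omega - 1e-12) + 1) / (n_perm + 1)
  colnames(obs) <- c("M", "F")
  list(omega_between_sexes = omega, p_value = p, r_by_sex = obs,
       n_perm = n_perm)
}

#' Two-dimensional local spatial autocorrelation (2D LSA)
#'
#' For each focal individual, `lr` is the autocorrelation of the focal with
#' its `k` nearest geographic neighbours (the covariance-surface algebra
#' restricted to the focal's neighbour pairs). A one-tailed p-value per
#' individual comes from permuting genotypes among all individuals;
#' individuals with `p < alpha` are flagged as local kin neighbourhoods.
#' P-values are reported per individual without multiplicity adjustment
#' (an FDR flag is available).
#'
#' @param ds A [genotype_dataset()] with coordinates.
#' @param coords Optional distance matrix.
#' @param k Number of nearest neighbours (default 4). Distance ties are
#'   broken deterministically by individual order.
#' @param n_perm Number of permutations (default 9999; raise towards 1e5
#'   for publication-grade p-values).
#' @param seed Integer RNG seed.
#' @param alpha Flagging level (default 0.05).
#' @param fdr Apply Benjamini-Hochberg across individuals before flagging?
#' @return A data frame per individual: `id`, `lr`, `p`, `significant`,
#'   `neighbours` (comma-joined ids); attributes `k`, `n_perm`.
#' @export
local_autocorrelation_2d <- function(ds, coords = NULL, k = 4L,
                                     n_perm = 9999L, seed = 1L,
                                     alpha = 0.05, fdr = FALSE) {
  if (is.null(coords)) coords <- geographic_distances(ds)
  kept <- attr(coords, "kept")
  if (!is.null(kept) && length(kept) < nrow(ds$geno)) {
    ds <- subset_dataset(ds, individuals = kept)
  }
  n <- nrow(ds$geno)
  if (n <= k) stop("need more individuals than neighbours")
  nb <- t(vapply(seq_len(n), function(i) {
    o <- order(coords[i, ], seq_len(n))  # tie-break: lower index is nearer
    setdiff(o, i)[seq_len(k)]
  }, integer(k)))
  D <- squared_genetic_distance(ds)
  C <- .genetic_covariance(D)
  dC <- diag(C)
  fi <- rep(seq_len(n), each = k)
  fj <- as.vector(t(nb))
  lr_of <- function(p) {
    cij <- C[cbind(p[fi], p[fj])]
    dsum <- (dC[p[fi]] + dC[p[fj]]) / 2
    rowsum(cij, fi)[, 1] / rowsum(dsum, fi)[, 1]
  }
  obs <- lr_of(seq_len(n))
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  hits <- integer(n)
  for (b in seq_len(n_perm)) {
    hits <- hits + (lr_of(sample.int(n)) >= obs - 1e-12)
  }
  p <- (hits + 1) / (n_perm + 1)
  padj <- if (fdr) stats::p.adjust(p, "BH") else p
  out <- data.frame(id = ds$meta$id, lr = obs, p = p,
                    significant = padj < alpha,
                    neighbours = apply(nb, 1L, function(r)
                      paste(ds$meta$id[r], collapse = ",")),
                    stringsAsFactors = FALSE)
  attr(out, "k") <- k
  attr(out, "n_perm") <- n_perm
  out
}

#' Within- versus between-group relatedness permutation test
#'
#' The observed statistic is the mean pairwise relatedness within groups
#' (transects or sampling points). The null is built by repeatedly drawing
#' random pseudo-groups of the same sizes from all individuals and
#' recomputing; the one-tailed p-value is the fraction of null statistics
#' at or above the observed, `(k + 1) / (n_perm + 1)`. The mean
#' between-group relatedness is reported alongside.
#'
#' @param rel A `relatedness_matrix` from [pairwise_relatedness()].
#' @param labels Group label per individual (NA excluded).
#' @param n_perm Number of simulations (default 10000).
#' @param seed Integer RNG seed.
#' @return A `group_heterogeneity_result`: `mean_within`, `sd_within`,
#'   `mean_between`, `sd_between`, `p_value`, `n_perm`, `n_groups`.
#' @export
within_between_relatedness_test <- function(rel, labels, n_perm = 10000L,
                                            seed = 1L) {
  labels <- as.character(labels)
  keep <- !is.na(labels)
  m <- rel$r[keep, keep, drop = FALSE]
  labels <- labels[keep]
  f <- factor(labels)
  if (nlevels(f) < 2L) stop("need >= 2 groups")
  sizes <- table(f)
  if (all(sizes < 2L)) stop("no group of size >= 2")
  n <- nrow(m)
  pr <- .pair_index(n)
  rv <- m[cbind(pr$i, pr$j)]
  gi <- as.integer(f)
  within <- gi[pr$i] == gi[pr$j]
  obs <- mean(rv[within], na.rm = TRUE)
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  hits <- 0L
  for (b in seq_len(n_perm)) {
    gp <- gi[sample.int(n)]
    if (mean(rv[gp[pr$i] == gp[pr$j]], na.rm = TRUE) >= obs - 1e-12) {
      hits <- hits + 1L
    }
  }
  structure(list(mean_within = obs,
                 sd_within = stats::sd(rv[within], na.rm = TRUE),
                 mean_between = mean(rv[!within], na.rm = TRUE),
                 sd_between = stats::sd(rv[!within], na.rm = TRUE),
                 p_value = (hits + 1) / (n_perm + 1),
                 n_perm = n_perm, n_groups = nlevels(f)),
            class = "group_heterogeneity_result")
}

#' @export
print.group_heterogeneity_result <- function(x, ...) {
  cat(sprintf("within r = %.4f +/- %.4f vs between r = %.4f +/- %.4f, P = %.3f (%d groups)\n",
              x$mean_within, x$sd_within, x$mean_between, x$sd_between,
              x$p_value, x$n_groups))
  invisible(x)
}
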