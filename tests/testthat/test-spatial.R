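test_that("geographic distances are Euclidean, symmetric, translation-invariant", {
  xy <- data.frame(x = c(0, 3, 0), y = c(0, 0, 4))
  m <- geographic_distances(xy)
  expect_equal(m[1, 2], 3)
  expect_equal(m[1, 3], 4)
  expect_equal(m[2, 3], 5)          # 3-4-5 triangle
  expect_equal(diag(m), rep(0, 3), ignore_attr = TRUE)

  set.seed(3)
  xy2 <- data.frame(x = runif(8) * 100, y = runif(8) * 100)
  m2 <- geographic_distances(xy2)
  m3 <- geographic_distances(data.frame(x = xy2$x + 500, y = xy2$y - 200))
  expect_equal(m2, m3, tolerance = 1e-9)
  expect_equal(geographic_distances(data.frame(x = c(1, 1), y = c(2, 2)))[1, 2], 0)

  ds <- random_hwe_ds(5, equifreq(4, 2), seed = 1,
                      x = c(0, 1, 2, NA, 4), y = c(0, 0, 0, 0, 0))
  expect_warning(mm <- geographic_distances(ds), "missing coordinates")
  expect_equal(dim(mm), c(4, 4))
  expect_equal(attr(mm, "kept"), c(1L, 2L, 3L, 5L))
})

test_that("codominant squared genetic distance matches the canonical values", {
  # genotypes: AA, AB, AC, BB, BC, CD-like (two loci checked independently)
  g <- rbind(c(1L, 1L), c(1L, 2L), c(1L, 3L), c(2L, 2L), c(2L, 3L), c(3L, 4L))
  ds <- make_ds(g)
  D <- squared_genetic_distance(ds)
  expect_equal(D[1, 1], 0)           # AA vs AA
  expect_equal(D[1, 2], 1)           # AA vs AB
  expect_equal(D[2, 3], 1)           # AB vs AC
  expect_equal(D[1, 4], 4)           # AA vs BB
  expect_equal(D[1, 5], 3)           # AA vs BC
  expect_equal(D[2, 6], 2)           # AB vs CD
  # vector-algebra oracle on every pair
  for (i in 1:5) for (j in (i + 1):6) {
    expect_equal(D[i, j], sq_dist_brute(g[i, ], g[j, ]), label = paste(i, j))
  }
  # additivity over loci
  ds2 <- make_ds(cbind(g, g))
  expect_equal(squared_genetic_distance(ds2), 2 * D)
})

test_that("distance classes: even width edges, even counts, degenerate ties", {
  d <- c(5, 15, 25, 35, 55, 75, 95, 120)
  cl <- build_distance_classes(d, "even_width", 5, max_dist = 100)
  expect_equal(cl$edges, c(0, 20, 40, 60, 80, 100))
  expect_equal(cl$class, c(1L, 1L, 2L, 2L, 3L, 4L, 5L, NA))

  ec <- build_distance_classes(runif(100, 0, 50), "even_count", 37)
  expect_true(max(ec$pair_count) - min(ec$pair_count) <= 1)
  expect_equal(sum(ec$pair_count), 100)

  tied <- build_distance_classes(rep(10, 6), "even_count", 2)
  expect_equal(tied$class, c(1L, 1L, 1L, 2L, 2L, 2L))  # tie-break by pair order
  expect_error(build_distance_classes(1:3, "even_count", 5), "more classes")
})

test_that("correlogram r matches a brute-force transcription on all n <= 6 layouts", {
  set.seed(31)
  for (case in 1:8) {
    n <- sample(4:6, 1)
    ds <- random_hwe_ds(n, equifreq(4, 3), seed = 400 + case,
                        x = runif(n, 0, 50), y = runif(n, 0, 50))
    coords <- geographic_distances(ds)
    classes <- build_distance_classes(coords, "even_count", 2)
    cg <- suppressWarnings(
      spatial_correlogram(ds, coords, classes, n_perm = 99, n_boot = 0,
                          seed = case))
    D <- genetic_D_brute(ds)
    r_brute <- correlogram_r_brute(D, classes$class)
    expect_equal(cg$classes$r, r_brute, tolerance = 1e-10,
                 label = paste("case", case))
  }
})

test_that("omega matches a from-scratch transcription sharing only the seed", {
  ds <- random_hwe_ds(6, equifreq(5, 4), seed = 77,
                      x = c(0, 1, 10, 11, 30, 31), y = rep(0, 6))
  coords <- geographic_distances(ds)
  classes <- build_distance_classes(coords, "even_count", 3)
  n_perm <- 199
  cg <- suppressWarnings(spatial_correlogram(ds, coords, classes,
                                             n_perm = n_perm, n_boot = 0,
                                             seed = 5))
  # independent route: brute-force r under the same permutation stream
  D <- genetic_D_brute(ds)
  r_obs <- correlogram_r_brute(D, classes$class)
  set.seed(5)
  perm_r <- t(vapply(seq_len(n_perm), function(b) {
    p <- sample.int(6)
    Dp <- D[p, p]
    correlogram_r_brute(Dp, classes$class)
  }, numeric(3)))
  mu <- colMeans(perm_r); sdv <- apply(perm_r, 2, sd)
  omega_brute <- sum(((r_obs - mu) / sdv)^2)
  omega_perm <- rowSums(((perm_r - matrix(mu, n_perm, 3, TRUE)) /
                           matrix(sdv, n_perm, 3, TRUE))^2)
  p_brute <- (sum(omega_perm >= omega_brute - 1e-12) + 1) / (n_perm + 1)
  expect_equal(cg$omega, omega_brute, tolerance = 1e-10)
  expect_equal(cg$omega_p, p_brute, tolerance = 1e-12)
})

test_that("covariance partition is conserved across any full class partition", {
  ds <- random_hwe_ds(20, equifreq(6, 8), seed = 9,
                      x = runif(20, 0, 100), y = runif(20, 0, 100))
  coords <- geographic_distances(ds)
  classes <- build_distance_classes(coords, "even_count", 5)
  cg <- spatial_correlogram(ds, coords, classes, n_perm = 99, n_boot = 0,
                            seed = 1)
  D <- squared_genetic_distance(ds)
  C <- colonykin:::.genetic_covariance(D)
  total_offdiag <- sum(C[upper.tri(C)])
  pr <- colonykin:::.pair_index(20)
  dsum <- (diag(C)[pr$i] + diag(C)[pr$j]) / 2
  recon <- sum(vapply(1:5, function(h) {
    cg$classes$r[h] * sum(dsum[classes$class == h])
  }, numeric(1)))
  expect_equal(recon, total_offdiag, tolerance = 1e-10)
})

test_that("co-located clones dominate the first distance class", {
  # pairs of identical multilocus genotypes at identical locations
  set.seed(41)
  fl <- equifreq(8, 10)
  base <- random_hwe_ds(12, fl, seed = 51)
  geno <- base$geno
  geno[seq(2, 12, 2), ] <- geno[seq(1, 11, 2), ]   # clone partner
  x <- rep(seq(0, 100, length.out = 6), each = 2)
  ds <- make_ds(geno, x = x, y = rep(0, 12))
  coords <- geographic_distances(ds)
  classes <- build_distance_classes(coords, "even_width", 5, max_dist = 100)
  cg <- suppressWarnings(spatial_correlogram(ds, coords, classes,
                                             n_perm = 199, n_boot = 0,
                                             seed = 2))
  expect_equal(which.max(cg$classes$r), 1L)
  expect_gt(cg$classes$r[1], 0)
  expect_lt(cg$omega_p, 0.05)
})

test_that("2D LSA recovers a planted co-located family and breaks ties deterministically", {
  set.seed(43)
  sc <- colony_scenario(n_adults = 100, ground_sizes = c(75L, 25L),
                        n_loci = 25, alleles_per_locus = rep(10L, 25),
                        kin_clusters = 1L, kin_cluster_size = 5L, seed = 61)
  ds <- plant_kin_clusters(sample_panmictic(sc))
  fam <- attr(ds, "kin_members")[[1]]
  lsa <- local_autocorrelation_2d(ds, k = 4, n_perm = 999, seed = 3)
  flagged <- lsa$id[lsa$significant]
  expect_gte(length(intersect(fam, flagged)), 4)  # >= 4 of 5 sibs found
  expect_true(all(lsa$lr[match(fam, lsa$id)] > 0))
  expect_true(all(lsa$p > 0 & lsa$p <= 1))

  # coincident coordinates: neighbour choice deterministic (repeatable)
  ds2 <- random_hwe_ds(8, equifreq(4, 4), seed = 4,
                       x = rep(0, 8), y = rep(0, 8))
  l1 <- local_autocorrelation_2d(ds2, k = 3, n_perm = 99, seed = 1)
  l2 <- local_autocorrelation_2d(ds2, k = 3, n_perm = 99, seed = 1)
  expect_identical(l1, l2)
  expect_equal(l1$neighbours[1], "i2,i3,i4")
})

test_that("sex comparison is label-symmetric and calibrated-ish under the null", {
  sc <- colony_scenario(n_adults = 80, ground_sizes = c(60L, 20L),
                        n_loci = 10, alleles_per_locus = rep(8L, 10),
                        seed = 71)
  ds <- sample_panmictic(sc)
  res <- sex_stratified_comparison(ds, n_classes = 4, max_dist = 100,
                                   n_perm = 199, seed = 5)
  expect_true(res$p_value > 0 && res$p_value <= 1)
  # swapping all sex labels leaves the statistic unchanged
  ds_swap <- ds
  ds_swap$meta$sex <- ifelse(ds$meta$sex == "M", "F", "M")
  res_swap <- sex_stratified_comparison(ds_swap, n_classes = 4,
                                        max_dist = 100, n_perm = 199,
                                        seed = 5)
  expect_equal(res_swap$omega_between_sexes, res$omega_between_sexes,
               tolerance = 1e-10)
  # one sex absent errors
  ds_m <- ds; ds_m$meta$sex <- "M"
  expect_error(sex_stratified_comparison(ds_m), "both sexes")
})

test_that("within/between test needs real groups and is seed-reproducible", {
  ds <- random_hwe_ds(30, equifreq(6, 8), seed = 81)
  rel <- pairwise_relatedness(ds, "queller_goodnight")
  labs <- rep(letters[1:5], each = 6)
  r1 <- within_between_relatedness_test(rel, labs, n_perm = 199, seed = 7)
  r2 <- within_between_relatedness_test(rel, labs, n_perm = 199, seed = 7)
  expect_identical(r1, r2)
  expect_true(r1$p_value > 0 && r1$p_value <= 1)
  expect_error(within_between_relatedness_test(rel, rep("a", 30)),
               ">= 2 groups")
})

test_that("within/between test detects planted half-sib clusters with power", {
  detected <- 0
  for (i in 1:5) {
    sc <- colony_scenario(n_adults = 240, ground_sizes = c(180L, 60L),
                          n_loci = 25, alleles_per_locus = rep(10L, 25),
                          kin_clusters = 20L, kin_cluster_size = 4L,
                          kin_relationship = "half_sib", seed = 90 + i)
    ds <- plant_kin_clusters(sample_panmictic(sc))
    rel <- pairwise_relatedness(ds, "wang")
    p <- within_between_relatedness_test(rel, ds$meta$sampling_point,
                                         n_perm = 199, seed = i)$p_value
    if (p < 0.05) detected <- detected + 1
  }
  expect_gte(detected, 4)  # power >= 0.8
})
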