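test_that("k-means timing classes recover planted waves and order by mean", {
  set.seed(3)
  hatch <- c(rnorm(50, 74, 2), rnorm(50, 82, 2), rnorm(50, 91, 2),
             rnorm(50, 108, 2))
  tc <- assign_timing_classes(hatch, k = 4, seed = 1)
  expect_equal(tc$class_mean, c(74, 82, 91, 108), tolerance = 1 / 74)
  expect_true(all(diff(tc$class_mean) > 0))
  expect_equal(sum(tc$class_size), 200)

  # k = number of distinct values: zero within-class variance
  tc2 <- assign_timing_classes(c(1, 1, 5, 5, 9), k = 3, seed = 1)
  expect_equal(tc2$withinss, 0)
  expect_error(assign_timing_classes(c(1, 1, 2, 2), k = 3), "distinct")

  # permuting input order leaves the solution unchanged (fixed seed/restarts)
  perm <- sample(length(hatch))
  tc3 <- assign_timing_classes(hatch[perm], k = 4, seed = 1)
  expect_equal(tc3$class[order(perm)], tc$class)
  expect_equal(tc3$class_mean, tc$class_mean)

  # NA hatch days pass through as NA classes
  tc4 <- assign_timing_classes(c(hatch, NA, NA), k = 4, seed = 1)
  expect_true(all(is.na(tail(tc4$class, 2))))
})

test_that("chosen k-means solution beats random assignments on objective", {
  set.seed(5)
  hatch <- runif(80, 60, 120)
  tc <- assign_timing_classes(hatch, k = 4, seed = 2)
  wss <- function(cl) sum(vapply(unique(cl), function(c_) {
    sum((hatch[cl == c_] - mean(hatch[cl == c_]))^2)
  }, numeric(1)))
  rand_best <- min(replicate(100, wss(sample.int(4, 80, TRUE))))
  expect_lte(tc$withinss, rand_best)
})

test_that("class-wise differentiation annotates day gaps and respects sizes", {
  sc <- colony_scenario(n_adults = 120, ground_sizes = c(90L, 30L),
                        n_loci = 10, alleles_per_locus = rep(8L, 10),
                        seed = 31)
  ds <- sample_panmictic(sc)
  tc <- assign_timing_classes(ds$meta$hatch_day, k = 4, seed = 1)
  tab <- timing_class_differentiation(ds, tc, n_perm = 99, n_boot = 99,
                                      seed = 2)
  expect_equal(nrow(tab), choose(4, 2))
  expect_equal(tab$day_gap[tab$class_a == 1 & tab$class_b == 4],
               tc$class_mean[4] - tc$class_mean[1])
  expect_true(all(tab$p_value > 0 & tab$p_value <= 1))
  expect_true(all(tab$n_a >= 5 & tab$n_b >= 5))
})

test_that("isolation-by-time planted at study-like size is detected with power", {
  hits <- 0; g14s <- g23s <- numeric(0)
  for (i in 1:5) {
    sc <- colony_scenario(temporal_target_gst = 0.012, seed = 210 + i)
    ds <- plant_temporal_divergence(sample_panmictic(sc))
    realized <- attr(ds, "realized_gst")
    expect_true(realized >= 0.8 * 0.012 && realized <= 1.2 * 0.012)
    tc <- assign_timing_classes(ds$meta$hatch_day, k = 4, seed = 1)
    sel <- which(tc$class %in% c(1, 4))
    g14 <- gst_permutation_test(subset_dataset(ds, individuals = sel),
                                ifelse(tc$class[sel] == 1, "A", "B"),
                                n_perm = 199, seed = i)
    if (g14$p_value < 0.05) hits <- hits + 1
    # the extreme-class contrast should dominate an interior one
    sel23 <- which(tc$class %in% c(2, 3))
    g23 <- gst_double_prime(subset_dataset(ds, individuals = sel23),
                            ifelse(tc$class[sel23] == 2, "A", "B"))
    g14s <- c(g14s, g14$observed$gst_double_prime)
    g23s <- c(g23s, g23$gst_double_prime)
  }
  expect_gte(hits, 3)              # detection power well above half
  expect_gt(mean(g14s), mean(g23s))  # earliest-vs-latest dominates on average
})

test_that("Mantel test: identity, constancy error, permutation multiset", {
  set.seed(7)
  n <- 25
  v <- runif(n)
  A <- abs(outer(v, v, "-"))
  res <- mantel_test(A, A, n_perm = 199, seed = 1)
  expect_equal(res$R2, 1)
  expect_equal(res$p_value, 1 / 200)

  B <- matrix(1, n, n)
  expect_error(mantel_test(A, B), "constant")

  res2 <- mantel_test(A, A, n_perm = 199, seed = 1)
  expect_identical(res, res2)  # seed-reproducible
})

test_that("Mantel correlation agrees with an independent implementation", {
  set.seed(19)
  n <- 30
  v1 <- rnorm(n); v2 <- rnorm(n)
  A <- abs(outer(v1, v1, "-"))
  B <- A + abs(outer(v2, v2, "-"))
  ours <- mantel_test(A, B, n_perm = 199, seed = 1)
  ref <- vegan::mantel(as.dist(A), as.dist(B), permutations = 199)
  expect_equal(ours$r, unname(ref$statistic), tolerance = 1e-10)
})

test_that("Mantel p is uniform under independence", {
  set.seed(9)
  ps <- replicate(300, {
    n <- 20
    A <- abs(outer(rnorm(n), rnorm(n), "-"))
    B <- abs(outer(rnorm(n), rnorm(n), "-"))
    mantel_test(A, B, n_perm = 99, seed = sample.int(1e6, 1))$p_value
  })
  rej <- mean(ps <= 0.05)
  expect_lt(abs(rej - 0.05), 2.5 * sqrt(0.05 * 0.95 / 300) + 1e-9)
})

test_that("Tukey transform finds sensible exponents and preserves order", {
  set.seed(11)
  ln <- tukey_transform(rlnorm(200, 3, 0.5))
  expect_lte(abs(ln$lambda), 0.3)     # lognormal wants ~log

  lam_norm <- replicate(20, tukey_transform(rnorm(200, 50, 5))$lambda)
  expect_lte(stats::median(abs(lam_norm - 1)), 0.5)  # near-identity regime

  x <- runif(50, 1, 9)
  tt <- tukey_transform(x)
  if (tt$lambda > 0) expect_equal(order(tt$transformed), order(x))

  # non-positive values are shifted, recorded
  ts <- tukey_transform(c(-3, 0, 2, 5, 9, 1, 4))
  expect_equal(ts$shift, 4)
  expect_warning(tukey_transform(rep(2, 10)), "constant")
})

test_that("inbreeding-timing regression matches the closed form and reports df", {
  # hand-checkable 5-point fixture, no transform
  x <- c(1, 2, 3, 4, 5); y <- c(2.1, 3.9, 6.2, 8.1, 9.8)
  fit <- inbreeding_timing_regression(y, x, transform = FALSE)
  sxx <- sum((x - mean(x))^2); sxy <- sum((x - mean(x)) * (y - mean(y)))
  beta <- sxy / sxx
  res <- y - (mean(y) + beta * (x - mean(x)))
  r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
  f_stat <- r2 / (1 - r2) * 3
  expect_equal(fit$slope, beta, tolerance = 1e-10)
  expect_equal(fit$R2, r2, tolerance = 1e-10)
  expect_equal(fit$F_stat, f_stat, tolerance = 1e-10)
  expect_equal(fit$df, c(1, 3))

  # perfectly linear: R2 = 1
  lin <- suppressWarnings(
    inbreeding_timing_regression(2 * x + 1, x, transform = FALSE))
  expect_equal(lin$R2, 1, tolerance = 1e-12)

  # slope magnitude invariant under predictor centering
  shifted <- inbreeding_timing_regression(y, x + 100, transform = FALSE)
  expect_equal(shifted$slope, fit$slope, tolerance = 1e-10)

  # null at n = 203 gives df (1, 201) as expected
  set.seed(13)
  nullfit <- inbreeding_timing_regression(rnorm(203), runif(203, 60, 120))
  expect_equal(nullfit$df, c(1, 201))
  expect_error(inbreeding_timing_regression(rnorm(10), rep(5, 10)),
               "zero variance")
})
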