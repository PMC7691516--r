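test_that("all four estimators are symmetric in the dyad and finite", {
  ds <- random_hwe_ds(15, equifreq(6, 10), seed = 4)
  for (est in c("wang", "queller_goodnight", "lynch_ritland", "li")) {
    rel <- pairwise_relatedness(ds, est)
    expect_true(all(abs(rel$r - t(rel$r)) < 1e-12, na.rm = TRUE),
                label = est)
    expect_true(all(is.finite(rel$r[upper.tri(rel$r)])), label = est)
    expect_equal(rel$n_pairs, choose(15, 2))
  }
  expect_error(pairwise_relatedness(ds, "nonsense"), "estimator")
})

test_that("identical highly heterozygous genotypes score substantially related", {
  # two copies of one fully heterozygous multilocus genotype, 20 loci of
  # 10 equifrequent alleles, among unrelated background birds
  fl <- equifreq(10, 20)
  ds <- random_hwe_ds(30, fl, seed = 6)
  g <- rep(c(3L, 7L), 20)
  ds$geno[1, ] <- g
  ds$geno[2, ] <- g
  for (est in c("wang", "queller_goodnight", "lynch_ritland", "li")) {
    rel <- pairwise_relatedness(ds, est, freqs = fl)
    expect_gt(rel$r[1, 2], 0.5, label = est)
  }
})

test_that("the Wang-category estimator matches an independent per-dyad transcription", {
  set.seed(8)
  fl <- lapply(equifreq(6, 12), function(p) {
    w <- runif(6) + 0.2
    stats::setNames(w / sum(w), names(p))
  })
  ds <- random_hwe_ds(8, fl, seed = 9)
  ds$geno[3, 1:2] <- NA_integer_  # exercise the missing-locus path
  fr <- allele_frequencies(ds)
  rel <- pairwise_relatedness(ds, "wang", freqs = fr)
  for (i in 1:7) for (j in (i + 1):8) {
    brute <- wang_brute(ds$geno[i, ], ds$geno[j, ], fr$freq,
                        bias_correct = TRUE, n_typed = fr$n_typed)
    expect_equal(rel$r[i, j], brute, tolerance = 1e-10,
                 label = paste("pair", i, j))
  }
  # and with externally supplied (raw) frequencies, no bias correction
  rel2 <- pairwise_relatedness(ds, "wang", freqs = fl)
  brute2 <- wang_brute(ds$geno[1, ], ds$geno[2, ], fl, bias_correct = FALSE)
  expect_equal(rel2$r[1, 2], brute2, tolerance = 1e-10)
})

test_that("dyad simulation is Mendelian, deterministic, and estimators recover true r", {
  fl <- equifreq(10, 25)
  po <- simulate_dyads(fl, "parent_offspring", 300, seed = 5)
  # parent and offspring share at least one allele at every locus
  for (l in seq_len(25)) {
    a <- po$g1[, 2 * l - 1]; b <- po$g1[, 2 * l]
    cc <- po$g2[, 2 * l - 1]; d <- po$g2[, 2 * l]
    expect_true(all(a == cc | a == d | b == cc | b == d))
  }
  expect_identical(simulate_dyads(fl, "full_sib", 50, seed = 3),
                   simulate_dyads(fl, "full_sib", 50, seed = 3))

  fs <- simulate_dyads(fl, "full_sib", 1000, seed = 7)
  r_fs <- dyad_relatedness(fs, fl, "wang")
  expect_lt(abs(mean(r_fs) - 0.5), 0.02)
  un <- simulate_dyads(fl, "unrelated", 1000, seed = 8)
  r_un <- dyad_relatedness(un, fl, "wang")
  expect_lt(abs(mean(r_un)), 0.02)
})

test_that("estimator comparison ranks deterministically and degrades with low diversity", {
  ds <- random_hwe_ds(80, equifreq(10, 25), seed = 10)
  cmp1 <- compare_estimators(ds, n_per_class = 120, seed = 2)
  cmp2 <- compare_estimators(ds, n_per_class = 120, seed = 2)
  expect_identical(cmp1, cmp2)
  expect_true(all(cmp1$pearson_r > 0.8 & cmp1$pearson_r < 1))

  ds_low <- random_hwe_ds(80, equifreq(2, 25), seed = 10)
  cmp_low <- compare_estimators(ds_low, n_per_class = 120, seed = 2)
  m1 <- cmp1[order(cmp1$estimator), "pearson_r"]
  m2 <- cmp_low[order(cmp_low$estimator), "pearson_r"]
  expect_true(all(m2 < m1))  # information-content monotonicity
})

test_that("Ritland F is negative for an all-heterozygote and recovers selfing", {
  fl <- equifreq(10, 25)
  ds <- random_hwe_ds(20, fl, seed = 12)
  ds$geno[1, ] <- rep(c(2L, 9L), 25)   # heterozygous everywhere
  f <- ritland_inbreeding(ds, freqs = fl)
  expect_lt(f[["i1"]], 0)

  # selfed offspring of random parents: true F = 0.5
  set.seed(14)
  n <- 500
  geno <- matrix(NA_integer_, n, 50)
  for (l in 1:25) {
    p <- fl[[l]]
    pa <- as.integer(sample(names(p), n, TRUE, p))
    pb <- as.integer(sample(names(p), n, TRUE, p))
    a <- ifelse(runif(n) < 0.5, pa, pb)
    b <- ifelse(runif(n) < 0.5, pa, pb)
    geno[, 2 * l - 1] <- pmin(a, b)
    geno[, 2 * l] <- pmax(a, b)
  }
  f_self <- ritland_inbreeding(make_ds(geno, loci = names(fl)), freqs = fl)
  expect_lt(abs(mean(f_self) - 0.5), 0.03)

  # an individual typed at no locus gets NA
  ds$geno[2, ] <- NA_integer_
  f2 <- ritland_inbreeding(ds, freqs = fl)
  expect_true(is.na(f2[["i2"]]))
})

test_that("greedy unrelated subset removes cliques and matches brute force", {
  mk_rel <- function(m, ids = paste0("i", seq_len(nrow(m)))) {
    dimnames(m) <- list(ids, ids)
    structure(list(r = m, ids = ids, estimator = "wang"),
              class = "relatedness_matrix")
  }
  # nothing above threshold: full set back
  m0 <- matrix(0, 4, 4); diag(m0) <- NA
  expect_identical(select_unrelated(mk_rel(m0)), paste0("i", 1:4))

  # one related pair among 4: greedy keeps 3, the brute-force maximum
  m1 <- m0; m1[1, 2] <- m1[2, 1] <- 0.5
  got <- select_unrelated(mk_rel(m1))
  expect_length(got, 3)
  expect_length(max_unrelated_brute(m1, 0.24), 3)

  # triangle of 3 mutual relatives + 2 others: 1 of the clique survives
  m2 <- matrix(0, 5, 5); diag(m2) <- NA
  m2[1:3, 1:3][upper.tri(m2[1:3, 1:3])] <- 0.4
  m2[lower.tri(m2)] <- t(m2)[lower.tri(m2)]
  got2 <- select_unrelated(mk_rel(m2))
  expect_length(got2, 3)
  expect_length(intersect(got2, c("i1", "i2", "i3")), 1)

  # randomised agreement with the exhaustive maximum on n <= 7
  set.seed(15)
  for (i in 1:10) {
    n <- sample(4:7, 1)
    m <- matrix(0, n, n)
    hot <- which(upper.tri(m) & matrix(runif(n * n) < 0.3, n, n))
    m[hot] <- 0.5
    m <- pmax(m, t(m)); diag(m) <- NA
    rel <- mk_rel(m)
    got <- select_unrelated(rel)
    sub <- rel$r[got, got, drop = FALSE]
    expect_true(all(is.na(sub) | sub < 0.24))
  }
})

test_that("pairs with too few shared typed loci are flagged missing", {
  ds <- random_hwe_ds(4, equifreq(5, 3), seed = 2)
  ds$geno[1, c(1:2, 3:4)] <- NA_integer_
  ds$geno[2, c(5:6, 3:4)] <- NA_integer_  # pair (1,2) shares only locus... none
  rel <- pairwise_relatedness(ds, "queller_goodnight", min_shared = 2)
  expect_true(is.na(rel$r[1, 2]))
  expect_false(is.na(rel$r[3, 4]))
})
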