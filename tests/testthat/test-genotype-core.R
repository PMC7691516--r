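test_that("plain CSV parsing handles missing cells and rejects malformed input", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,LA_1,LA_2,LB_1,LB_2",
               "a,101,103,200,200",
               "b,101,101,0,0"), tmp)
  ds <- read_genotype_table(tmp, "plain_csv", quiet = TRUE)
  expect_equal(nrow(ds$geno), 2L)
  expect_equal(ds$loci, c("LA", "LB"))
  expect_equal(sum(is.na(ds$geno[, c(1, 3)])), 1L)  # one missing genotype
  expect_equal(unname(ds$geno["a", ]), c(101L, 103L, 200L, 200L))

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,LA_1,LA_2,LB_1", "a,1,2,3"), bad)
  expect_error(read_genotype_table(bad, "plain_csv", quiet = TRUE),
               "odd number of allele columns")

  dup <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,LA_1,LA_2", "a,1,2", "a,1,2"), dup)
  expect_error(read_genotype_table(dup, "plain_csv", quiet = TRUE),
               "duplicate individual id")

  tok <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,LA_1,LA_2", "a,1,x7"), tok)
  expect_error(read_genotype_table(tok, "plain_csv", quiet = TRUE),
               "unparseable allele token")
})

test_that("write/read round trip preserves allele multisets and missing cells", {
  ds <- random_hwe_ds(10, equifreq(5, 5), seed = 3)
  ds$geno[2, 1:2] <- NA_integer_
  ds$geno[7, 9:10] <- NA_integer_
  for (dialect in c("plain_csv", "genalex_csv", "structure_tworow")) {
    tmp <- withr::local_tempfile(fileext = ".txt")
    write_genotype_table(ds, tmp, dialect)
    back <- read_genotype_table(tmp, dialect, quiet = TRUE)
    expect_identical(unname(back$geno), unname(ds$geno), label = dialect)
    expect_identical(back$meta$id, ds$meta$id)
    # idempotence: a second round trip is byte-identical
    tmp2 <- withr::local_tempfile(fileext = ".txt")
    write_genotype_table(back, tmp2, dialect)
    expect_identical(readLines(tmp2), readLines(tmp))
  }
})

test_that("GenAlEx header is parsed and locus count matches it", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("3,4,2,2,2,,,",
               "demo colony,,,popA,popB,,,",
               "Sample,Pop,Ofu01,,Ofu02,,Ofu03,",
               "s1,popA,150,154,200,202,99,99",
               "s2,popA,150,150,200,200,97,99",
               "s3,popB,154,158,0,0,97,97",
               "s4,popB,158,158,202,204,99,101"), tmp)
  ds <- read_genotype_table(tmp, "genalex_csv", quiet = TRUE)
  expect_equal(length(ds$loci), 3L)
  expect_equal(ds$loci, c("Ofu01", "Ofu02", "Ofu03"))
  expect_equal(ds$meta$breeding_ground, c("popA", "popA", "popB", "popB"))
  expect_true(is.na(ds$geno["s3", 3]))
  expect_equal(unname(ds$geno["s1", 1:2]), c(150L, 154L))
})

test_that("allele pairs are order-free and half-missing cells are rejected", {
  ds1 <- make_ds(rbind(c(3L, 1L), c(1L, 3L)))
  expect_identical(ds1$geno[1, ], ds1$geno[2, ])
  expect_error(make_ds(rbind(c(1L, NA))), "half-missing")
})

test_that("allele frequencies count copies and normalise to 1", {
  ds <- make_ds(rbind(c(1L, 1L), c(1L, 2L)))
  fr <- allele_frequencies(ds)
  expect_equal(unname(fr$freq$L1), c(0.75, 0.25))  # 3 of 4 copies are allele 1
  expect_equal(unname(fr$n_typed["L1"]), 2L)

  ds2 <- random_hwe_ds(40, equifreq(6, 4), seed = 5)
  fr2 <- allele_frequencies(ds2)
  for (l in names(fr2$freq)) {
    expect_equal(sum(fr2$freq[[l]]), 1, tolerance = 1e-12)
    expect_true(all(fr2$freq[[l]] > 0))
  }
})

test_that("subset frequencies equal brute-force counting on tiny fixtures", {
  ds <- make_ds(rbind(c(1L, 2L), c(2L, 2L), c(1L, 3L), c(3L, 3L), c(1L, 1L)))
  sub <- c(1, 3, 5)
  fr <- allele_frequencies(ds, individuals = sub)
  copies <- as.vector(ds$geno[sub, 1:2])
  brute <- table(copies) / length(copies)
  expect_equal(unname(fr$freq$L1[names(brute)]), unname(as.numeric(brute)))
})

test_that("locus summaries give Ho, unbiased He and missing fraction", {
  # two typed individuals, p = (0.5, 0.5): He_unbiased = 4/3 * 0.5
  ds <- make_ds(rbind(c(1L, 2L), c(1L, 2L)))
  s <- locus_summaries(ds)
  expect_equal(s$Ho, 1)
  expect_equal(s$He_uncorrected, 0.5)
  expect_equal(s$He, 2 / 3, tolerance = 1e-12)

  mono <- make_ds(rbind(c(1L, 1L), c(1L, 1L)))
  sm <- locus_summaries(mono)
  expect_equal(sm$Ho, 0)
  expect_equal(sm$He, 0)

  # hand-built check: He_uncorrected == 1 - sum p^2, correction inflates it
  ds3 <- random_hwe_ds(15, equifreq(4, 3), seed = 9)
  ds3$geno[4, 1:2] <- NA_integer_
  s3 <- locus_summaries(ds3)
  fr3 <- allele_frequencies(ds3)
  for (l in seq_len(3)) {
    expect_equal(s3$He_uncorrected[l], 1 - sum(fr3$freq[[l]]^2),
                 tolerance = 1e-12)
    expect_gte(s3$He[l], s3$He_uncorrected[l])
  }
  expect_equal(s3$missing_frac, c(1 / 15, 0, 0))
})

test_that("per-individual missingness filter keeps the <= 15% default", {
  ds <- random_hwe_ds(6, equifreq(4, 10), seed = 2)
  ds$geno[1, 1:8] <- NA_integer_   # 40% missing
  ds$geno[2, 1:2] <- NA_integer_   # 10% missing
  out <- filter_individuals(ds)
  expect_identical(attr(out, "dropped"), "i1")
  expect_equal(nrow(out$geno), 5L)
})

test_that("the shipped synthetic example colony loads with its metadata", {
  gen <- system.file("extdata", "synthetic_colony_genalex.csv",
                     package = "colonykin")
  met <- system.file("extdata", "synthetic_colony_metadata.csv",
                     package = "colonykin")
  ds <- read_genotype_table(gen, "genalex_csv", metadata = met, quiet = TRUE)
  expect_equal(nrow(ds$geno), 12L)
  expect_equal(length(ds$loci), 4L)
  expect_true(all(!is.na(ds$meta$x)))
  expect_equal(sort(unique(ds$meta$breeding_ground)),
               c("ground1", "ground2"))
  expect_silent(locus_summaries(ds))
})

test_that("metadata attaches by id and rejects unknown individuals", {
  ds <- random_hwe_ds(3, equifreq(3, 2), seed = 1)
  ds <- attach_metadata(ds, data.frame(id = c("i3", "i1"), x = c(5, 0),
                                       y = c(1, 2), sex = c("F", "M")))
  expect_equal(ds$meta$x, c(0, NA, 5))
  expect_equal(ds$meta$sex, c("M", NA, "F"))
  expect_error(attach_metadata(ds, data.frame(id = "nope", x = 1)),
               "unknown individual")
})
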