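# small programmatic fixtures shared across test files

# a genotype_dataset from an explicit allele matrix
make_ds <- function(geno, loci = NULL, ids = NULL, ...) {
  geno <- as.matrix(geno)
  if (is.null(loci)) loci <- paste0("L", seq_len(ncol(geno) / 2))
  if (is.null(ids)) ids <- paste0("i", seq_len(nrow(geno)))
  meta <- data.frame(id = ids, stringsAsFactors = FALSE)
  extra <- list(...)
  for (nm in names(extra)) meta[[nm]] <- extra[[nm]]
  genotype_dataset(geno, loci, meta)
}

# random HWE dataset from explicit per-locus frequencies
random_hwe_ds <- function(n, freq_list, seed = 1, ...) {
  set.seed(seed)
  geno <- matrix(NA_integer_, n, 2 * length(freq_list))
  for (l in seq_along(freq_list)) {
    p <- freq_list[[l]]
    a <- as.integer(sample(names(p), n, TRUE, p))
    b <- as.integer(sample(names(p), n, TRUE, p))
    geno[, 2 * l - 1] <- pmin(a, b)
    geno[, 2 * l] <- pmax(a, b)
  }
  ds <- make_ds(geno, loci = names(freq_list), ...)
  ds
}

equifreq <- function(K, n_loci) {
  fl <- replicate(n_loci, stats::setNames(rep(1 / K, K), seq_len(K)),
                  simplify = FALSE)
  names(fl) <- paste0("L", seq_len(n_loci))
  fl
}

# a fast small study-like scenario for unit tests
small_scenario <- function(seed = 1, ...) {
  colony_scenario(n_adults = 60, ground_sizes = c(45L, 15L), n_loci = 8,
                  alleles_per_locus = rep(8L, 8), seed = seed, ...)
}
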