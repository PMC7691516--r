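#' Allele frequencies per locus
#'
#' Counts allele copies per locus (optionally over a subset of individuals)
#' and normalises by `2 * n_typed`. These frequencies feed every estimator in
#' the package (Hardy-Weinberg expectation, null alleles, relatedness,
#' inbreeding, differentiation).
#'
#' @param ds A [genotype_dataset()].
#' @param individuals Optional subset (ids, integer or logical index).
#' @return An `allele_frequency_table`: list with `freq` (per locus a named
#'   numeric vector, allele label to relative frequency, all entries > 0 and
#'   summing to 1) and `n_typed` (named integer, individuals typed per locus).
#' @export
allele_frequencies <- function(ds, individuals = NULL) {
  if (!is.null(individuals)) ds <- subset_dataset(ds, individuals = individuals)
  freq <- vector("list", length(ds$loci))
  names(freq) <- ds$loci
  n_typed <- integer(length(ds$loci))
  for (l in seq_along(ds$loci)) {
    al <- locus_alleles(ds, l)
    copies <- c(al[, 1L], al[, 2L])
    copies <- copies[!is.na(copies)]
    if (length(copies) == 0L) {
      stop("no typed individuals at locus ", ds$loci[l])
    }
    tab <- table(copies)
    freq[[l]] <- stats::setNames(as.numeric(tab) / length(copies),
                                 names(tab))
    n_typed[l] <- length(copies) %/% 2L
  }
  structure(list(freq = freq, n_typed = stats::setNames(n_typed, ds$loci)),
            class = "allele_frequency_table")
}

#' @export
print.allele_frequency_table <- function(x, ...) {
  cat("allele_frequency_table:", length(x$freq), "loci;",
      "alleles/locus", paste(range(lengths(x$freq)), collapse = "-"), "\n")
  invisible(x)
}

#' Per-locus diversity and quality summaries
#'
#' Observed heterozygosity `Ho` is the fraction of typed individuals that are
#' heterozygous. Expected heterozygosity is reported both uncorrected
#' (`He_uncorrected = 1 - sum(p^2)`) and with Nei's unbiased small-sample
#' correction (`He = 2n/(2n-1) * He_uncorrected`), matching the output of
#' common genotyping software; the unbiased value is the headline `He`.
#'
#' @param ds A [genotype_dataset()].
#' @param freqs Optional precomputed [allele_frequencies()] table.
#' @return Data frame with one row per locus: `locus`, `n_typed`, `n_alleles`,
#'   `Ho`, `He`, `He_uncorrected`, `missing_frac`.
#' @export
locus_summaries <- function(ds, freqs = NULL) {
  if (is.null(freqs)) freqs <- allele_frequencies(ds)
  n <- nrow(ds$geno)
  out <- data.frame(locus = ds$loci, n_typed = NA_integer_,
                    n_alleles = NA_integer_, Ho = NA_real_, He = NA_real_,
                    He_uncorrected = NA_real_, missing_frac = NA_real_,
                    stringsAsFactors = FALSE)
  for (l in seq_along(ds$loci)) {
    al <- locus_alleles(ds, l)
    typed <- !is.na(al[, 1L])
    nt <- sum(typed)
    p <- freqs$freq[[ds$loci[l]]]
    he0 <- 1 - sum(p^2)
    out$n_typed[l] <- nt
    out$n_alleles[l] <- length(p)
    out$Ho[l] <- if (nt > 0L) mean(al[typed, 1L] != al[typed, 2L]) else NA_real_
    out$He_uncorrected[l] <- he0
    out$He[l] <- if (nt > 0L) 2 * nt / (2 * nt - 1) * he0 else NA_real_
    out$missing_frac[l] <- 1 - nt / n
  }
  out
}

#' Overall missing-genotype rate
#' @param ds A [genotype_dataset()].
#' @return Fraction of genotype cells missing, in `[0, 1]`.
#' @export
missing_rate <- function(ds) {
  a1 <- ds$geno[, seq(1L, ncol(ds$geno), by = 2L), drop = FALSE]
  mean(is.na(a1))
}
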