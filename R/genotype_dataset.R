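#' Construct a codominant genotype dataset
#'
#' The central container of the package: a diploid allele table (one row per
#' individual, an unordered pair of integer allele labels per locus) together
#' with per-individual metadata used by the spatial and temporal analyses.
#'
#' Allele pairs are order-free: genotypes are canonicalised so the smaller
#' label is stored first, which makes `(a,b)` and `(b,a)` identical. A
#' genotype cell is either fully missing (both alleles `NA`) or fully typed;
#' half-typed cells are rejected.
#'
#' @param geno Integer matrix with `n` rows and `2 * length(loci)` columns:
#'   the two allele columns of locus `l` are columns `2l - 1` and `2l`.
#'   Missing genotypes are `NA` in both columns (0 is also accepted as a
#'   missing code and converted).
#' @param loci Character vector of unique locus names.
#' @param meta Data frame with one row per individual. Must contain `id`
#'   (unique character). Optional columns: `breeding_ground`, `transect`,
#'   `sampling_point`, `x`, `y` (planar metres), `sex` (`"M"`, `"F"` or `NA`),
#'   `hatch_day` (integer days since the season's first hatch), `life_stage`
#'   (`"adult"`/`"chick"`, default `"adult"`).
#' @return An object of class `genotype_dataset`.
#' @seealso [read_genotype_table()], [allele_frequencies()], [locus_summaries()]
#' @export
genotype_dataset <- function(geno, loci, meta) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  loci <- as.character(loci)
  if (anyDuplicated(loci)) stop("locus names must be unique")
  if (ncol(geno) != 2L * length(loci)) {
    stop("geno must have two columns per locus (", length(loci), " loci, ",
         ncol(geno), " columns)")
  }
  if (!is.data.frame(meta) || is.null(meta$id)) {
    stop("meta must be a data.frame with an 'id' column")
  }
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  meta$id <- as.character(meta$id)
  if (anyDuplicated(meta$id)) {
    stop("duplicate individual id: ",
         paste(unique(meta$id[duplicated(meta$id)]), collapse = ", "))
  }
  if (nrow(meta) != nrow(geno)) stop("meta rows must match geno rows")
  geno[!is.na(geno) & geno == 0L] <- NA_integer_

  # enforce both-or-neither missing and canonical (low, high) order
  for (l in seq_along(loci)) {
    c1 <- 2L * l - 1L
    c2 <- 2L * l
    half <- xor(is.na(geno[, c1]), is.na(geno[, c2]))
    if (any(half)) {
      stop("half-missing genotype at locus ", loci[l], ", individual ",
           paste(meta$id[half], collapse = ", "))
    }
    a <- geno[, c1]; b <- geno[, c2]
    geno[, c1] <- pmin(a, b)
    geno[, c2] <- pmax(a, b)
  }

  defaults <- list(breeding_ground = NA_character_, transect = NA_character_,
                   sampling_point = NA_character_, x = NA_real_, y = NA_real_,
                   sex = NA_character_, hatch_day = NA_integer_,
                   life_stage = "adult")
  for (nm in names(defaults)) {
    if (is.null(meta[[nm]])) meta[[nm]] <- rep(defaults[[nm]], nrow(meta))
  }
  rownames(geno) <- meta$id
  colnames(geno) <- paste(rep(loci, each = 2L), c(1L, 2L), sep = ".")

  structure(list(geno = geno, loci = loci, meta = meta),
            class = "genotype_dataset")
}

#' @export
print.genotype_dataset <- function(x, ...) {
  n_missing <- sum(is.na(x$geno[, seq(1L, ncol(x$geno), by = 2L), drop = FALSE]))
  cat("genotype_dataset:", nrow(x$geno), "individuals x", length(x$loci),
      "loci;", n_missing, "missing genotype cells\n")
  has <- function(v) any(!is.na(x$meta[[v]]))
  avail <- c("breeding_ground", "transect", "sampling_point", "x", "sex",
             "hatch_day")[vapply(c("breeding_ground", "transect",
                                   "sampling_point", "x", "sex", "hatch_day"),
                                 has, logical(1))]
  if (length(avail)) cat("metadata:", paste(avail, collapse = ", "), "\n")
  invisible(x)
}

#' Number of individuals in a dataset
#' @param ds A `genotype_dataset`.
#' @return Integer count.
#' @export
n_individuals <- function(ds) nrow(ds$geno)

#' Extract the two allele columns of one locus
#' @param ds A `genotype_dataset`.
#' @param locus Locus name or index.
#' @return Integer matrix with columns `a1`, `a2` (canonical order), `NA` when
#'   missing.
#' @export
locus_alleles <- function(ds, locus) {
  l <- if (is.character(locus)) match(locus, ds$loci) else as.integer(locus)
  if (is.na(l) || l < 1L || l > length(ds$loci)) stop("unknown locus: ", locus)
  m <- ds$geno[, c(2L * l - 1L, 2L * l), drop = FALSE]
  colnames(m) <- c("a1", "a2")
  m
}

#' Subset a dataset by individuals and/or loci
#' @param ds A `genotype_dataset`.
#' @param individuals Character ids or integer/logical row index (default all).
#' @param loci Locus names or index (default all).
#' @return A `genotype_dataset`.
#' @export
subset_dataset <- function(ds, individuals = NULL, loci = NULL) {
  ri <- seq_len(nrow(ds$geno))
  if (!is.null(individuals)) {
    ri <- if (is.character(individuals)) match(individuals, ds$meta$id)
          else ri[individuals]
    if (anyNA(ri)) stop("unknown individual id(s)")
  }
  li <- seq_along(ds$loci)
  if (!is.null(loci)) {
    li <- if (is.character(loci)) match(loci, ds$loci) else li[loci]
    if (anyNA(li)) stop("unknown locus name(s)")
  }
  cols <- as.vector(rbind(2L * li - 1L, 2L * li))
  genotype_dataset(ds$geno[ri, cols, drop = FALSE], ds$loci[li],
                   ds$meta[ri, , drop = FALSE])
}

#' Drop individuals exceeding a per-individual missingness threshold
#'
#' Individuals whose fraction of missing genotype cells exceeds
#' `max_missing` are removed. The default of 0.15 keeps every individual
#' with at most 15% missing loci.
#'
#' @param ds A `genotype_dataset`.
#' @param max_missing Maximum tolerated missing fraction (default 0.15).
#' @return A filtered `genotype_dataset` (attribute `"dropped"` lists removed
#'   ids).
#' @export
filter_individuals <- function(ds, max_missing = 0.15) {
  a1 <- ds$geno[, seq(1L, ncol(ds$geno), by = 2L), drop = FALSE]
  frac <- rowMeans(is.na(a1))
  keep <- frac <= max_missing
  out <- subset_dataset(ds, individuals = which(keep))
  attr(out, "dropped") <- ds$meta$id[!keep]
  out
}

#' Per-individual missing-genotype fraction
#' @param ds A `genotype_dataset`.
#' @return Named numeric vector (fraction of loci missing per individual).
#' @export
individual_missingness <- function(ds) {
  a1 <- ds$geno[, seq(1L, ncol(ds$geno), by = 2L), drop = FALSE]
  stats::setNames(rowMeans(is.na(a1)), ds$meta$id)
}
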