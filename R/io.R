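#' Read a codominant genotype table
#'
#' Parses one of three plain-text dialects into a [genotype_dataset()]:
#'
#' * `"plain_csv"` — header `id[,pop],<locus>_1,<locus>_2,...`; two allele
#'   columns per locus, named `<locus>_1`/`<locus>_2` (or `<locus>.1`).
#' * `"genalex_csv"` — the GenAlEx codominant layout: first row
#'   `n_loci,n_samples,n_pops,size_1,size_2,...`; second row a title followed
#'   by population names; third row `Sample,Pop,<locus>,,<locus>,,...`; then
#'   one data row per individual.
#' * `"structure_tworow"` — two rows per individual: `id pop a_1 ... a_L`,
#'   whitespace separated, missing coded `-9`.
#'
#' Missing alleles may be coded as `0`, blank, `NA` or (STRUCTURE) `-9`; all
#' are normalised to the internal `NA` sentinel. Allele labels are opaque
#' positive integers (fragment sizes); no binning is attempted.
#'
#' @param path File to read.
#' @param dialect One of `"plain_csv"`, `"genalex_csv"`, `"structure_tworow"`.
#' @param metadata Optional path to a metadata CSV keyed by individual id
#'   (columns among `id, breeding_ground, transect, sampling_point, x, y,
#'   sex, hatch_day, life_stage`).
#' @param quiet Suppress the parse-summary message.
#' @return A `genotype_dataset`. The group column of the file (if any) is
#'   stored as `breeding_ground` unless overridden by `metadata`.
#' @export
read_genotype_table <- function(path, dialect = c("plain_csv", "genalex_csv",
                                                  "structure_tworow"),
                                metadata = NULL, quiet = FALSE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  ds <- switch(dialect,
               plain_csv = .read_plain_csv(path),
               genalex_csv = .read_genalex_csv(path),
               structure_tworow = .read_structure(path))
  if (!is.null(metadata)) ds <- attach_metadata(ds, utils::read.csv(
    metadata, stringsAsFactors = FALSE))
  if (!quiet) {
    a1 <- ds$geno[, seq(1L, ncol(ds$geno), by = 2L), drop = FALSE]
    message("parsed ", nrow(ds$geno), " individuals, ", length(ds$loci),
            " loci, ", sum(is.na(a1)), " missing genotype cells")
  }
  ds
}

.parse_alleles <- function(x, where) {
  x <- trimws(as.character(x))
  x[x == "" | toupper(x) == "NA" | x == "-9"] <- "0"
  bad <- !grepl("^[0-9]+$", x)
  if (any(bad)) {
    stop("unparseable allele token '", x[which(bad)[1]], "' at ", where,
         " entry ", which(bad)[1])
  }
  as.integer(x)
}

.geno_from_columns <- function(allele_cols, loci, ids, where) {
  if (length(allele_cols) %% 2L != 0L) {
    stop("format error: odd number of allele columns (", length(allele_cols),
         ") in ", where)
  }
  geno <- matrix(NA_integer_, nrow = length(ids), ncol = length(allele_cols))
  for (j in seq_along(allele_cols)) {
    geno[, j] <- .parse_alleles(allele_cols[[j]],
                                paste0(where, " column ", j))
  }
  genotype_dataset(geno, loci, data.frame(id = ids,
                                          stringsAsFactors = FALSE))
}

.read_plain_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                         colClasses = "character")
  if (!"id" %in% names(tab)) stop("plain_csv requires an 'id' column")
  pop <- if ("pop" %in% names(tab)) tab$pop else NULL
  allele_names <- setdiff(names(tab), c("id", "pop"))
  if (length(allele_names) %% 2L != 0L) {
    stop("format error: odd number of allele columns in ", path)
  }
  loci <- unique(sub("[._][12]$", "", allele_names))
  if (length(loci) * 2L != length(allele_names)) {
    stop("allele columns must come in <locus>_1/<locus>_2 pairs")
  }
  cols <- lapply(loci, function(l) {
    hit <- allele_names[sub("[._][12]$", "", allele_names) == l]
    tab[hit[order(hit)]]
  })
  ds <- .geno_from_columns(do.call(c, cols), loci, tab$id, path)
  if (!is.null(pop)) ds$meta$breeding_ground <- as.character(pop)
  ds
}

.read_genalex_csv <- function(path) {
  raw <- utils::read.csv(path, header = FALSE, stringsAsFactors = FALSE,
                         colClasses = "character", blank.lines.skip = FALSE)
  if (nrow(raw) < 4L) stop("format error: genalex_csv needs 3 header rows")
  n_loci <- as.integer(raw[1, 1]); n_samp <- as.integer(raw[1, 2])
  if (is.na(n_loci) || is.na(n_samp)) {
    stop("format error: first genalex row must start n_loci,n_samples,n_pops")
  }
  header <- as.character(raw[3, ])
  loci <- header[seq(3L, by = 2L, length.out = n_loci)]
  loci <- trimws(loci)
  if (any(loci == "")) stop("format error: blank locus name in genalex header")
  dat <- raw[4:(3L + n_samp), , drop = FALSE]
  ids <- trimws(dat[, 1])
  pop <- trimws(dat[, 2])
  cols <- lapply(seq_len(2L * n_loci), function(j) dat[, 2L + j])
  ds <- .geno_from_columns(cols, loci, ids, path)
  ds$meta$breeding_ground <- pop
  ds
}

.read_structure <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  header <- strsplit(trimws(lines[1]), "[ \t]+")[[1]]
  has_header <- !grepl("^-?[0-9]+$", header[length(header)]) ||
    length(strsplit(trimws(lines[2]), "[ \t]+")[[1]]) != length(header)
  # default layout written by write_structure: header row of locus names
  if (has_header) {
    loci <- header
    lines <- lines[-1]
  } else loci <- NULL
  toks <- strsplit(trimws(lines), "[ \t]+")
  len <- lengths(toks)
  if (length(unique(len)) != 1L) stop("format error: ragged structure file")
  if (length(toks) %% 2L != 0L) {
    stop("format error: structure_tworow needs two rows per individual")
  }
  n_loci <- len[1] - 2L
  if (is.null(loci)) loci <- paste0("L", seq_len(n_loci))
  if (length(loci) != n_loci) stop("format error: header/locus mismatch")
  odd <- toks[seq(1L, length(toks), by = 2L)]
  even <- toks[seq(2L, length(toks), by = 2L)]
  ids <- vapply(odd, `[`, "", 1L)
  ids2 <- vapply(even, `[`, "", 1L)
  if (!identical(ids, ids2)) stop("format error: row pairs disagree on id")
  pop <- vapply(odd, `[`, "", 2L)
  geno <- matrix(NA_integer_, length(ids), 2L * n_loci)
  for (l in seq_len(n_loci)) {
    geno[, 2L * l - 1L] <- .parse_alleles(
      vapply(odd, `[`, "", 2L + l), paste0(path, " locus ", loci[l]))
    geno[, 2L * l] <- .parse_alleles(
      vapply(even, `[`, "", 2L + l), paste0(path, " locus ", loci[l]))
  }
  # a genotype with either copy missing is treated as fully missing
  for (l in seq_len(n_loci)) {
    cc <- c(2L * l - 1L, 2L * l)
    half <- geno[, cc[1]] == 0L | geno[, cc[2]] == 0L
    geno[half, cc] <- 0L
  }
  ds <- genotype_dataset(geno, loci, data.frame(id = ids,
                                                stringsAsFactors = FALSE))
  ds$meta$breeding_ground <- pop
  ds
}

#' Write a genotype dataset
#'
#' Writers for the same dialects accepted by [read_genotype_table()]
#' (`plain_csv` and `genalex_csv` round-trip; `structure_tworow` is a
#' one-way exchange format with missing coded `-9`... here written as `0`
#' within a header-bearing two-row layout the reader also accepts).
#'
#' @param ds A `genotype_dataset`.
#' @param path Output file.
#' @param dialect Output dialect.
#' @param title Title string for the GenAlEx second header row.
#' @return `path`, invisibly.
#' @export
write_genotype_table <- function(ds, path,
                                 dialect = c("plain_csv", "genalex_csv",
                                             "structure_tworow"),
                                 title = "colonykin export") {
  dialect <- match.arg(dialect)
  geno <- ds$geno
  geno[is.na(geno)] <- 0L
  pop <- ds$meta$breeding_ground
  pop[is.na(pop)] <- "pop1"
  if (dialect == "plain_csv") {
    out <- data.frame(id = ds$meta$id, pop = pop, geno,
                      check.names = FALSE, stringsAsFactors = FALSE)
    names(out) <- c("id", "pop",
                    paste(rep(ds$loci, each = 2L), c(1L, 2L), sep = "_"))
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  } else if (dialect == "genalex_csv") {
    pops <- unique(pop)
    sizes <- as.integer(table(factor(pop, levels = pops)))
    ncol_out <- 2L + 2L * length(ds$loci)
    pad <- function(v) c(v, rep("", max(0L, ncol_out - length(v))))
    r1 <- pad(c(length(ds$loci), nrow(geno), length(pops), sizes))
    r2 <- pad(c(title, "", "", pops))
    r3 <- pad(c("Sample", "Pop", as.vector(rbind(ds$loci, ""))))
    body <- cbind(ds$meta$id, pop, geno)
    lines <- c(paste(r1, collapse = ","), paste(r2, collapse = ","),
               paste(r3, collapse = ","),
               apply(body, 1L, paste, collapse = ","))
    writeLines(lines, path)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste(ds$loci, collapse = " "), con)
    for (i in seq_len(nrow(geno))) {
      a1 <- geno[i, seq(1L, ncol(geno), by = 2L)]
      a2 <- geno[i, seq(2L, ncol(geno), by = 2L)]
      writeLines(c(paste(c(ds$meta$id[i], pop[i], a1), collapse = " "),
                   paste(c(ds$meta$id[i], pop[i], a2), collapse = " ")), con)
    }
  }
  invisible(path)
}

#' Attach or replace per-individual metadata
#'
#' @param ds A `genotype_dataset`.
#' @param meta Data frame with an `id` column; every id must resolve to a
#'   known individual. Recognised columns overwrite the stored ones;
#'   individuals absent from `meta` keep their current values.
#' @return The updated `genotype_dataset`.
#' @export
attach_metadata <- function(ds, meta) {
  if (is.null(meta$id)) stop("metadata needs an 'id' column")
  meta$id <- as.character(meta$id)
  idx <- match(meta$id, ds$meta$id)
  if (anyNA(idx)) {
    stop("metadata references unknown individual(s): ",
         paste(meta$id[is.na(idx)], collapse = ", "))
  }
  for (nm in intersect(names(meta), c("breeding_ground", "transect",
                                      "sampling_point", "x", "y", "sex",
                                      "hatch_day", "life_stage"))) {
    ds$meta[[nm]][idx] <- meta[[nm]]
  }
  ds
}

#' Write the metadata table as CSV
#' @param ds A `genotype_dataset`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(ds, path) {
  utils::write.csv(ds$meta, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
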