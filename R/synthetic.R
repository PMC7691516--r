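#' Define a synthetic colony scenario
#'
#' The scenario captures the study design the generator emulates: a
#' two-ground tropical seabird colony sampled along 90-m transects with
#' sampling points at 0/30/60/90 m, ~15 nests per point, 25 highly
#' polymorphic microsatellite loci (6-38 alleles each), 287 breeding
#' adults, hatch dates spread over a ~42-day season in four timing waves,
#' and ~0.3% missing genotypes. Every default is a study-design constant;
#' override only to explore other regimes.
#'
#' @param n_adults Total adults (default 287, split 217/70 between grounds).
#' @param n_loci Number of loci (default 25).
#' @param alleles_per_locus Integer vector of allele counts per locus.
#'   The default 25-locus panel spans 6-38 alleles with mean ~17.5,
#'   matching a highly polymorphic microsatellite panel; recycled/sampled
#'   for other `n_loci`.
#' @param dirichlet_alpha Symmetric Dirichlet concentration for allele
#'   frequencies (default 0.4, giving expected heterozygosity ~0.82 at 17
#'   alleles).
#' @param ground_sizes Adults per breeding ground (default `c(217, 70)`).
#' @param transects_per_ground Transects per ground (default `c(4, 1)`).
#' @param point_offsets Sampling-point offsets along each transect in
#'   metres (default `c(0, 30, 60, 90)`).
#' @param nests_per_point Nests available at each point (default 15).
#' @param nest_spread Radius (m) of nest scatter about a point (default 5,
#'   the GPS accuracy scale).
#' @param transect_gap Metres between transects (default 500) and
#'   `ground_gap` between grounds (default 5000).
#' @param ground_gap See above.
#' @param class_means,class_sds,class_weights Hatch-day timing waves
#'   (defaults 74/82/91/108 days since first hatch, SDs 1/2/3/3, weights
#'   53/27/58/65): four breeding pulses over a ~42-day window.
#' @param sex_ratio Proportion male (default 0.5).
#' @param missing_rate Genotype missingness (default 0.0032).
#' @param dropout_rate Per-allele dropout rate (default 0).
#' @param kin_clusters,kin_cluster_size,kin_relationship Co-located family
#'   clusters to plant (defaults: none, size 4, `"full_sib"`).
#' @param temporal_target_gst Target earliest-vs-latest class G''ST planted
#'   by drift (default 0 = no divergence).
#' @param seed Scenario seed; all randomness flows from it through named
#'   substreams (genotypes, layout, kin, temporal, corruption).
#' @return A `colony_scenario` list.
#' @export
colony_scenario <- function(n_adults = 287L, n_loci = 25L,
                            alleles_per_locus = NULL, dirichlet_alpha = 0.4,
                            ground_sizes = c(217L, 70L),
                            transects_per_ground = c(4L, 1L),
                            point_offsets = c(0, 30, 60, 90),
                            nests_per_point = 15L, nest_spread = 5,
                            transect_gap = 500, ground_gap = 5000,
                            class_means = c(74, 82, 91, 108),
                            class_sds = c(1, 2, 3, 3),
                            class_weights = c(53, 27, 58, 65),
                            sex_ratio = 0.5, missing_rate = 0.0032,
                            dropout_rate = 0, kin_clusters = 0L,
                            kin_cluster_size = 4L,
                            kin_relationship = "full_sib",
                            temporal_target_gst = 0, seed = 1L) {
  if (is.null(alleles_per_locus)) {
    alleles_per_locus <- rep_len(
      c(6L, 7L, 8L, 9L, 10L, 11L, 12L, 12L, 13L, 14L, 14L, 15L, 16L,
        16L, 17L, 18L, 19L, 20L, 21L, 23L, 25L, 28L, 31L, 34L, 38L), n_loci)
  }
  if (sum(ground_sizes) != n_adults) {
    stop("ground_sizes must sum to n_adults")
  }
  stopifnot(length(transects_per_ground) == length(ground_sizes))
  stopifnot(missing_rate >= 0, missing_rate < 1, dropout_rate >= 0,
            dropout_rate < 1, temporal_target_gst >= 0,
            temporal_target_gst < 1)
  structure(as.list(environment()), class = "colony_scenario")
}

#' @export
print.colony_scenario <- function(x, ...) {
  cat("colony_scenario:", x$n_adults, "adults,", x$n_loci, "loci,",
      sum(x$transects_per_ground), "transects x", length(x$point_offsets),
      "points, seed", x$seed, "\n")
  invisible(x)
}

#' Read / write a scenario as YAML
#' @param path YAML file.
#' @return For `read_scenario`, a `colony_scenario`.
#' @export
read_scenario <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(colony_scenario, vals)
}

#' @rdname read_scenario
#' @param scenario A `colony_scenario`.
#' @return For `write_scenario`, `path` invisibly.
#' @export
write_scenario <- function(scenario, path) {
  yaml::write_yaml(unclass(scenario), path)
  invisible(path)
}

# substream seeds derived once from the scenario seed (kept < 2^31)
.scenario_seeds <- function(seed) {
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  stats::setNames(sample.int(2^30, 5L),
                  c("genotypes", "layout", "kin", "temporal", "corruption"))
}

#' Draw per-locus allele frequencies for a scenario
#' @param scenario A `colony_scenario`.
#' @return Named list of per-locus frequency vectors (names = allele
#'   labels 1..K).
#' @export
scenario_frequencies <- function(scenario) {
  seeds <- .scenario_seeds(scenario$seed)
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seeds[["genotypes"]])
  fl <- lapply(seq_len(scenario$n_loci), function(l) {
    K <- scenario$alleles_per_locus[l]
    g <- stats::rgamma(K, shape = scenario$dirichlet_alpha, rate = 1)
    g <- pmax(g, 1e-9)
    stats::setNames(g / sum(g), seq_len(K))
  })
  names(fl) <- sprintf("L%02d", seq_len(scenario$n_loci))
  fl
}

#' Sample a panmictic synthetic colony
#'
#' Per-locus allele frequencies are drawn from a symmetric Dirichlet;
#' genotypes are drawn independently under Hardy-Weinberg (no spatial or
#' temporal genetic signal — the calibration null). Coordinates follow the
#' transect/point layout with nests scattered around each point, hatch
#' days are drawn from the timing-wave mixture with zero genetic linkage,
#' and sexes are assigned independently. Genotyping noise is applied last
#' via [corrupt_genotypes()].
#'
#' @param scenario A [colony_scenario()].
#' @return A [genotype_dataset()] with full metadata; attributes
#'   `"frequencies"` (the generating frequencies) and `"scenario"`.
#' @export
sample_panmictic <- function(scenario) {
  seeds <- .scenario_seeds(scenario$seed)
  fl <- scenario_frequencies(scenario)
  n <- scenario$n_adults
  old <- .save_seed(); on.exit(.restore_seed(old))

  set.seed(seeds[["genotypes"]] + 1L)
  L <- scenario$n_loci
  geno <- matrix(NA_integer_, n, 2L * L)
  for (l in seq_len(L)) {
    p <- fl[[l]]
    a <- as.integer(sample(names(p), n, replace = TRUE, prob = p))
    b <- as.integer(sample(names(p), n, replace = TRUE, prob = p))
    geno[, 2L * l - 1L] <- pmin(a, b)
    geno[, 2L * l] <- pmax(a, b)
  }

  set.seed(seeds[["layout"]])
  meta <- .scenario_layout(scenario)
  meta$sex <- ifelse(stats::runif(n) < scenario$sex_ratio, "M", "F")
  w <- scenario$class_weights / sum(scenario$class_weights)
  cls <- sample.int(length(w), n, replace = TRUE, prob = w)
  meta$hatch_day <- as.integer(round(stats::rnorm(
    n, scenario$class_means[cls], scenario$class_sds[cls])))

  ds <- genotype_dataset(geno, names(fl), meta)
  ds <- corrupt_genotypes(ds, scenario$missing_rate, scenario$dropout_rate,
                          seed = seeds[["corruption"]])
  attr(ds, "frequencies") <- fl
  attr(ds, "scenario") <- scenario
  ds
}

.scenario_layout <- function(scenario) {
  grounds <- length(scenario$ground_sizes)
  rows <- list()
  tr_global <- 0L
  for (g in seq_len(grounds)) {
    n_tr <- scenario$transects_per_ground[g]
    n_pt <- length(scenario$point_offsets)
    slots <- n_tr * n_pt
    sz <- scenario$ground_sizes[g]
    per_point <- rep(sz %/% slots, slots)
    extra <- sz %% slots
    if (extra > 0L) per_point[seq_len(extra)] <- per_point[seq_len(extra)] + 1L
    s <- 0L
    for (t in seq_len(n_tr)) {
      tr_global <- tr_global + 1L
      for (pp in seq_len(n_pt)) {
        s <- s + 1L
        np <- per_point[s]
        if (np == 0L) next
        cx <- (g - 1L) * scenario$ground_gap +
          (t - 1L) * scenario$transect_gap
        cy <- scenario$point_offsets[pp]
        ang <- stats::runif(np, 0, 2 * pi)
        rad <- scenario$nest_spread * sqrt(stats::runif(np))
        rows[[length(rows) + 1L]] <- data.frame(
          breeding_ground = paste0("ground", g),
          transect = paste0("T", tr_global),
          sampling_point = paste0("T", tr_global, "P", pp),
          x = cx + rad * cos(ang), y = cy + rad * sin(ang),
          stringsAsFactors = FALSE)
      }
    }
  }
  meta <- do.call(rbind, rows)
  meta <- meta[sample.int(nrow(meta)), , drop = FALSE]  # decouple row order
  meta$id <- sprintf("bird%03d", seq_len(nrow(meta)))
  meta$life_stage <- "adult"
  rownames(meta) <- NULL
  meta
}

#' Plant co-located kin clusters into a colony
#'
#' Replaces selected individuals with simulated sibling groups (built by
#' explicit Mendelian transmission from the generating frequencies) placed
#' at adjacent nests of a single sampling point — the signal the spatial
#' kin-structure tests are designed to detect.
#'
#' @param ds A dataset from [sample_panmictic()].
#' @param n_clusters Number of family clusters (default: from the
#'   scenario).
#' @param cluster_size Individuals per cluster.
#' @param relationship `"full_sib"` or `"half_sib"`.
#' @param seed Integer RNG seed (default: the scenario kin substream).
#' @return The modified dataset; attribute `"kin_members"` lists planted
#'   ids per cluster.
#' @export
plant_kin_clusters <- function(ds, n_clusters = NULL, cluster_size = NULL,
                               relationship = NULL, seed = NULL) {
  scenario <- attr(ds, "scenario")
  if (is.null(n_clusters)) n_clusters <- scenario$kin_clusters
  if (is.null(cluster_size)) cluster_size <- scenario$kin_cluster_size
  if (is.null(relationship)) relationship <- scenario$kin_relationship
  if (is.null(seed)) seed <- .scenario_seeds(scenario$seed)[["kin"]]
  if (n_clusters == 0L) return(ds)
  fl <- attr(ds, "frequencies")
  if (is.null(fl)) fl <- allele_frequencies(ds)$freq
  pts <- split(seq_len(nrow(ds$geno)), ds$meta$sampling_point)
  pts <- pts[lengths(pts) >= cluster_size]
  if (length(pts) < n_clusters) {
    stop("not enough sampling points with >= ", cluster_size, " nests")
  }
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  chosen <- sample(names(pts), n_clusters)
  members <- list()
  for (ci in seq_len(n_clusters)) {
    idx <- sort(sample(pts[[chosen[ci]]], cluster_size))
    # one shared brood: draw sibs pairwise-consistently via common parents
    sibs <- .simulate_sibship(fl, cluster_size, relationship,
                              seed = sample.int(2^30, 1L))
    ds$geno[idx, ] <- sibs
    # co-locate at adjacent nests (~1.5 m apart) around the point centre
    cx <- mean(ds$meta$x[idx]); cy <- mean(ds$meta$y[idx])
    ang <- 2 * pi * seq_len(cluster_size) / cluster_size
    ds$meta$x[idx] <- cx + 1.5 * cos(ang)
    ds$meta$y[idx] <- cy + 1.5 * sin(ang)
    members[[ci]] <- ds$meta$id[idx]
  }
  attr(ds, "kin_members") <- members
  ds
}

# a sibship of size m: full sibs share both parents, half sibs share one
.simulate_sibship <- function(fl, m, relationship = c("full_sib",
                                                      "half_sib"),
                              seed = 1L) {
  relationship <- match.arg(relationship)
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  L <- length(fl)
  out <- matrix(NA_integer_, m, 2L * L)
  for (l in seq_len(L)) {
    p <- fl[[l]]
    draw <- function(k) as.integer(sample(names(p), k, replace = TRUE,
                                          prob = p))
    shared <- draw(2L)                       # shared parent
    if (relationship == "full_sib") {
      other <- matrix(draw(2L), nrow = m, ncol = 2L, byrow = TRUE)
    } else {
      other <- matrix(draw(2L * m), m, 2L)   # distinct other parents
    }
    a <- shared[1L + (stats::runif(m) < 0.5)]
    b <- other[cbind(seq_len(m), 1L + (stats::runif(m) < 0.5))]
    out[, 2L * l - 1L] <- pmin(a, b)
    out[, 2L * l] <- pmax(a, b)
  }
  out
}

#' Plant temporal genetic divergence (isolation by time)
#'
#' Simulates an early and a late source pool by Wright-Fisher drift from
#' the colony's generating frequencies, advancing generation by generation
#' until the realized earliest-vs-latest-class G''ST (computed from the
#' pool frequencies) falls within +/-20% of the target, then redraws the
#' genotypes of the earliest and latest timing-class members from their
#' pool. Drift (rather than ad-hoc frequency perturbation) gives the
#' realized divergence realistic locus-to-locus variance.
#'
#' @param ds A dataset from [sample_panmictic()].
#' @param target_gst Target G''ST (default from the scenario). 0 returns
#'   the dataset unchanged.
#' @param ne Effective pool size per generation (default 2000; large pools
#'   make per-generation divergence increments fine enough to land inside
#'   the target band).
#' @param max_generations Bounded search horizon (default 2000).
#' @param max_restarts Drift restarts before giving up (default 20).
#' @param seed Integer RNG seed (default: the scenario temporal substream).
#' @return The modified dataset; attribute `"realized_gst"` records the
#'   pool-level G''ST attained.
#' @export
plant_temporal_divergence <- function(ds, target_gst = NULL, ne = 2000L,
                                      max_generations = 2000L,
                                      max_restarts = 20L, seed = NULL) {
  scenario <- attr(ds, "scenario")
  if (is.null(target_gst)) target_gst <- scenario$temporal_target_gst
  if (is.null(seed)) seed <- .scenario_seeds(scenario$seed)[["temporal"]]
  if (target_gst == 0) return(ds)
  fl <- attr(ds, "frequencies")
  if (is.null(fl)) fl <- allele_frequencies(ds)$freq
  cls <- assign_timing_classes(ds$meta$hatch_day,
                               k = length(scenario$class_means),
                               seed = seed)$class
  early <- which(!is.na(cls) & cls == 1L)
  late <- which(!is.na(cls) & cls == max(cls, na.rm = TRUE))

  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  lo <- 0.8 * target_gst; hi <- 1.2 * target_gst
  for (attempt in seq_len(max_restarts)) {
    pa <- fl; pb <- fl
    realized <- 0
    done <- FALSE
    for (g in seq_len(max_generations)) {
      pa <- lapply(pa, function(p) {
        stats::setNames(as.numeric(stats::rmultinom(1L, 2L * ne, p)) /
                          (2 * ne), names(p))
      })
      pb <- lapply(pb, function(p) {
        stats::setNames(as.numeric(stats::rmultinom(1L, 2L * ne, p)) /
                          (2 * ne), names(p))
      })
      realized <- .pool_gst(pa, pb)
      if (realized >= lo && realized <= hi) { done <- TRUE; break }
      if (realized > hi) break  # overshot: restart drift
    }
    if (done) {
      for (idx_set in list(early, late)) {
        pool <- if (identical(idx_set, early)) pa else pb
        for (l in seq_along(pool)) {
          p <- pool[[l]]
          keep <- p > 0
          lab <- as.integer(names(p)[keep])
          a <- lab[sample.int(sum(keep), length(idx_set), replace = TRUE,
                              prob = p[keep])]
          b <- lab[sample.int(sum(keep), length(idx_set), replace = TRUE,
                              prob = p[keep])]
          ds$geno[idx_set, 2L * l - 1L] <- pmin(a, b)
          ds$geno[idx_set, 2L * l] <- pmax(a, b)
        }
      }
      attr(ds, "realized_gst") <- realized
      attr(ds, "timing_classes_planted") <- cls
      return(ds)
    }
  }
  stop("target G''ST ", target_gst, " unattainable with the given diversity ",
       "after ", max_restarts, " drift searches")
}

# frequency-level G''ST between two pools (k = 2, no sampling correction)
.pool_gst <- function(pa, pb) {
  hs <- ht <- numeric(length(pa))
  for (l in seq_along(pa)) {
    p1 <- pa[[l]]; p2 <- pb[[l]]
    hs[l] <- 1 - (sum(p1^2) + sum(p2^2)) / 2
    pbar <- (p1 + p2) / 2
    ht[l] <- 1 - sum(pbar^2)
  }
  HS <- mean(hs); HT <- mean(ht)
  if (HT <= 0 || HS >= 1) return(0)
  2 * (HT - HS) / ((2 * HT - HS) * (1 - HS))
}

#' Apply genotyping noise
#'
#' Sets whole genotype cells missing at random at `missing_rate`, and
#' simulates allelic dropout: each allele copy of a genotype independently
#' fails to amplify with probability `dropout_rate`; a heterozygote losing
#' one copy becomes an apparent homozygote, a genotype losing both becomes
#' missing. Dropout therefore only ever reduces observed heterozygosity.
#'
#' @param ds A [genotype_dataset()].
#' @param missing_rate Probability a genotype cell is set missing.
#' @param dropout_rate Per-allele dropout probability.
#' @param seed Integer RNG seed.
#' @return The corrupted dataset (attributes preserved).
#' @export
corrupt_genotypes <- function(ds, missing_rate = 0, dropout_rate = 0,
                              seed = 1L) {
  stopifnot(missing_rate >= 0, missing_rate < 1, dropout_rate >= 0,
            dropout_rate < 1)
  if (missing_rate == 0 && dropout_rate == 0) return(ds)
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  n <- nrow(ds$geno); L <- length(ds$loci)
  att <- attributes(ds)
  if (dropout_rate > 0) {
    for (l in seq_len(L)) {
      c1 <- 2L * l - 1L; c2 <- 2L * l
      typed <- !is.na(ds$geno[, c1])
      d1 <- stats::runif(n) < dropout_rate & typed
      d2 <- stats::runif(n) < dropout_rate & typed
      both <- d1 & d2
      ds$geno[d1 & !both, c1] <- ds$geno[d1 & !both, c2]
      ds$geno[d2 & !both, c2] <- ds$geno[d2 & !both, c1]
      ds$geno[both, c(c1, c2)] <- NA_integer_
      # re-canonicalise (copies are equal where dropped, already ordered)
    }
  }
  if (missing_rate > 0) {
    drop <- matrix(stats::runif(n * L) < missing_rate, n, L)
    for (l in seq_len(L)) {
      ds$geno[drop[, l], c(2L * l - 1L, 2L * l)] <- NA_integer_
    }
  }
  attributes(ds) <- att
  ds
}

#' Build the full study-mimic colony
#'
#' Convenience wrapper: panmictic base, then optional kin clusters and
#' temporal divergence per the scenario, with genotyping noise applied
#' last so planted genotypes are corrupted at the same rate as the
#' background.
#'
#' @param scenario A [colony_scenario()].
#' @return A [genotype_dataset()].
#' @export
simulate_colony <- function(scenario) {
  clean <- scenario
  clean$missing_rate <- 0
  clean$dropout_rate <- 0
  ds <- sample_panmictic(clean)
  attr(ds, "scenario") <- scenario
  if (scenario$kin_clusters > 0L) ds <- plant_kin_clusters(ds)
  if (scenario$temporal_target_gst > 0) ds <- plant_temporal_divergence(ds)
  corrupt_genotypes(ds, scenario$missing_rate, scenario$dropout_rate,
                    seed = .scenario_seeds(scenario$seed)[["corruption"]])
}
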