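#' Analysis configuration
#'
#' Bundles every tunable of the full pipeline with the study-convention
#' defaults: Wang relatedness, 999 permutations and bootstraps for
#' differentiation and correlograms, 10,000 simulations for the
#' within/between-group heterogeneity tests, 100,000 permutations for the
#' per-individual local autocorrelation, 4 timing classes, unrelated-subset
#' threshold 0.24, correlogram alpha 0.01 and 0.05 elsewhere. `fast = TRUE`
#' divides all resampling counts by 10 for CI-speed runs.
#'
#' @param estimator Relatedness estimator tag (default `"wang"`).
#' @param n_perm,n_boot Differentiation/correlogram replicates.
#' @param n_perm_heterogeneity Within/between-group simulations.
#' @param n_perm_lsa Local-autocorrelation permutations.
#' @param n_mc_hwe Monte-Carlo shuffles per Hardy-Weinberg test.
#' @param n_distance_classes,max_dist Even-width correlogram classes.
#' @param n_even_count_classes All-distance even-count classes (default 37).
#' @param k_timing Number of timing classes.
#' @param lsa_k Nearest neighbours for local autocorrelation.
#' @param unrelated_threshold Relatedness cutoff for the unrelated subset.
#' @param alpha_correlogram,alpha Significance conventions.
#' @param seed Master seed; every stochastic stage derives its own stream.
#' @param fast Divide all resampling counts by 10.
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(estimator = "wang", n_perm = 999L, n_boot = 999L,
                            n_perm_heterogeneity = 10000L,
                            n_perm_lsa = 100000L, n_mc_hwe = 2000L,
                            n_distance_classes = 5L, max_dist = 100,
                            n_even_count_classes = 37L, k_timing = 4L,
                            lsa_k = 4L, unrelated_threshold = 0.24,
                            alpha_correlogram = 0.01, alpha = 0.05,
                            seed = 1L, fast = FALSE) {
  cfg <- as.list(environment())
  if (fast) {
    for (nm in c("n_perm", "n_boot", "n_perm_heterogeneity", "n_perm_lsa",
                 "n_mc_hwe")) {
      cfg[[nm]] <- max(99L, as.integer(cfg[[nm]] %/% 10L))
    }
  }
  with(cfg, stopifnot(n_perm >= 99L, n_boot >= 99L,
                      n_perm_heterogeneity >= 99L, n_perm_lsa >= 99L,
                      unrelated_threshold > 0, unrelated_threshold <= 1,
                      alpha > 0, alpha < 1, alpha_correlogram > 0,
                      alpha_correlogram < 1))
  structure(cfg, class = "analysis_config")
}

#' Run the full within-colony analysis
#'
#' Executes the stages in order — marker QC, relatedness and inbreeding,
#' breeding-ground differentiation, spatial structure (correlogram and
#' omega test, sex comparison, local autocorrelation, within/between
#' transect and sampling-point tests), temporal structure (timing classes,
#' class-wise G''ST, inbreeding-timing regression, Mantel test) — skipping
#' stages whose metadata is absent (no coordinates: spatial skipped with a
#' notice; no hatch days: temporal skipped). Stage failures are recorded
#' per stage and the pipeline continues where later stages do not depend
#' on the failed one. Every stochastic step records its seed beside its
#' results.
#'
#' @param ds A [genotype_dataset()]. Chicks (`life_stage == "chick"`) enter
#'   the relatedness matrix but are excluded from the spatial and temporal
#'   stages.
#' @param config An [analysis_config()].
#' @return An `analysis_report` (nested list; see [write_report()]).
#' @export
run_full_analysis <- function(ds, config = analysis_config()) {
  report <- list(schema = "colonykin-report/1",
                 settings = unclass(config),
                 n_individuals = nrow(ds$geno),
                 n_loci = length(ds$loci))
  seed <- config$seed
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      message("stage '", name, "' failed: ", conditionMessage(e))
      list(error = conditionMessage(e))
    })
    report[[name]] <<- res
    invisible(res)
  }

  adults <- which(ds$meta$life_stage != "chick")
  ds_ad <- subset_dataset(ds, individuals = adults)

  stage("diversity", {
    s <- locus_summaries(ds)
    list(per_locus = s,
         mean_alleles_per_locus = mean(s$n_alleles),
         sd_alleles_per_locus = stats::sd(s$n_alleles),
         range_alleles = range(s$n_alleles),
         mean_Ho = mean(s$Ho, na.rm = TRUE), sd_Ho = stats::sd(s$Ho, na.rm = TRUE),
         mean_He = mean(s$He, na.rm = TRUE), sd_He = stats::sd(s$He, na.rm = TRUE),
         missing_pct = 100 * missing_rate(ds))
  })

  rel <- stage("relatedness", {
    r <- pairwise_relatedness(ds, estimator = config$estimator)
    list(estimator = config$estimator, mean = r$mean, sd = r$sd,
         n_pairs = r$n_pairs, matrix = r, seed = seed)
  })

  stage("inbreeding", {
    f <- ritland_inbreeding(ds_ad)
    list(mean = mean(f, na.rm = TRUE), sd = stats::sd(f, na.rm = TRUE),
         range = range(f, na.rm = TRUE), values = f)
  })

  stage("qc", {
    unrel <- if (!is.null(rel$matrix)) {
      select_unrelated(rel$matrix, config$unrelated_threshold)
    } else ds$meta$id
    qc <- qc_report(ds, individuals = unrel, n_mc = config$n_mc_hwe,
                    seed = seed + 10L)
    list(n_unrelated = length(unrel), hwe = qc$hwe,
         retained_loci = filter_loci(ds, qc), seed = seed + 10L)
  })

  grounds <- ds_ad$meta$breeding_ground
  if (length(unique(grounds[!is.na(grounds)])) >= 2L) {
    stage("differentiation", {
      d <- differentiation_test(ds_ad, "breeding_ground",
                                n_perm = config$n_perm,
                                n_boot = config$n_boot, seed = seed + 20L)
      list(gst_double_prime = d$gst_double_prime, p_value = d$p_value,
           ci = d$ci, n_per_group = as.list(d$n_per_group),
           seed = seed + 20L)
    })
  } else {
    report$differentiation <- list(skipped = "needs >= 2 breeding grounds")
  }

  has_coords <- sum(!is.na(ds_ad$meta$x) & !is.na(ds_ad$meta$y)) >= 10L
  if (has_coords) {
    stage("spatial", {
      coords <- geographic_distances(ds_ad)
      cg <- spatial_correlogram(ds_ad, coords,
                                n_classes = config$n_distance_classes,
                                max_dist = config$max_dist,
                                n_perm = config$n_perm,
                                n_boot = config$n_boot, seed = seed + 30L)
      cls_ec <- build_distance_classes(coords, "even_count",
                                       config$n_even_count_classes)
      cg_ec <- spatial_correlogram(ds_ad, coords, classes = cls_ec,
                                   n_perm = config$n_perm,
                                   n_boot = config$n_boot, seed = seed + 31L)
      sexes <- table(ds_ad$meta$sex)
      sex_cmp <- if (length(sexes) >= 2L && min(sexes) >= 10L) {
        s <- sex_stratified_comparison(ds_ad, coords,
                                       n_classes = config$n_distance_classes,
                                       max_dist = config$max_dist,
                                       n_perm = config$n_perm,
                                       seed = seed + 32L)
        s[c("omega_between_sexes", "p_value")]
      } else list(skipped = "needs >= 10 of each sex")
      lsa <- local_autocorrelation_2d(ds_ad, coords, k = config$lsa_k,
                                      n_perm = config$n_perm_lsa,
                                      seed = seed + 33L,
                                      alpha = config$alpha)
      rel_ad <- pairwise_relatedness(ds_ad, estimator = config$estimator)
      het <- lapply(c(transect = "transect", sampling_point = "sampling_point"),
                    function(v) {
        labs <- ds_ad$meta[[v]]
        if (length(unique(labs[!is.na(labs)])) < 2L) {
          return(list(skipped = "needs >= 2 groups"))
        }
        h <- within_between_relatedness_test(
          rel_ad, labs, n_perm = config$n_perm_heterogeneity,
          seed = seed + 34L)
        unclass(h)
      })
      list(correlogram_even_width = cg,
           correlogram_even_count = list(omega = cg_ec$omega,
                                         omega_p = cg_ec$omega_p),
           sex_comparison = sex_cmp,
           lsa = list(n_flagged = sum(lsa$significant),
                      flagged = lsa[lsa$significant, c("id", "lr", "p")],
                      k = config$lsa_k, n_perm = config$n_perm_lsa),
           heterogeneity = het, seed = seed + 30L)
    })
  } else {
    report$spatial <- list(skipped = "no coordinates")
  }

  has_hatch <- sum(!is.na(ds_ad$meta$hatch_day)) >=
    max(3L, config$k_timing * 5L)
  if (has_hatch) {
    stage("temporal", {
      hd <- ds_ad$meta$hatch_day
      tc <- assign_timing_classes(hd, k = config$k_timing, seed = seed + 40L)
      cls_gst <- timing_class_differentiation(ds_ad, tc,
                                              n_perm = config$n_perm,
                                              n_boot = config$n_boot,
                                              seed = seed + 41L)
      f <- ritland_inbreeding(ds_ad)
      reg <- inbreeding_timing_regression(f, hd)
      rel_t <- pairwise_relatedness(ds_ad, estimator = config$estimator)
      okh <- which(!is.na(hd))
      mt <- mantel_test(rel_t$r[okh, okh],
                        pairwise_abs_diff(hd[okh]),
                        n_perm = config$n_perm, seed = seed + 42L)
      list(classes = list(mean = tc$class_mean, sd = tc$class_sd,
                          size = tc$class_size),
           class_gst = cls_gst,
           regression = reg[c("F_stat", "df", "R2", "p_value", "lambda")],
           mantel = mt[c("R2", "p_value")], seed = seed + 40L)
    })
  } else {
    report$temporal <- list(skipped = "no hatch dates")
  }

  structure(report, class = "analysis_report")
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("analysis_report:", x$n_individuals, "individuals,", x$n_loci,
      "loci\n")
  for (s in c("diversity", "relatedness", "differentiation", "spatial",
              "temporal")) {
    st <- if (!is.null(x[[s]]$skipped)) paste("skipped:", x[[s]]$skipped)
          else if (!is.null(x[[s]]$error)) paste("FAILED:", x[[s]]$error)
          else "ok"
    cat(sprintf("  %-15s %s\n", s, st))
  }
  invisible(x)
}

#' Write an analysis report
#'
#' JSON (full nested report, deterministic for a fixed config and seed)
#' plus TSV side-tables: per-locus QC and diversity, the timing-class
#' differentiation matrix and the correlogram.
#'
#' @param report An `analysis_report`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  slim <- rapply(unclass(report), function(x) x, how = "replace")
  slim$relatedness$matrix <- NULL  # matrix goes to its own file
  js <- file.path(dir, "report.json")
  jsonlite::write_json(slim, js, auto_unbox = TRUE, digits = NA,
                       na = "null", force = TRUE)
  paths <- js
  if (is.null(report$relatedness$error) &&
      !is.null(report$relatedness$matrix)) {
    p <- file.path(dir, "relatedness.tsv")
    write_relatedness(report$relatedness$matrix, p)
    paths <- c(paths, p)
  }
  if (is.null(report$qc$error) && !is.null(report$qc$hwe)) {
    p <- file.path(dir, "qc.tsv")
    utils::write.table(report$qc$hwe, p, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    paths <- c(paths, p)
  }
  if (is.null(report$temporal$skipped) && is.null(report$temporal$error) &&
      !is.null(report$temporal$class_gst)) {
    p <- file.path(dir, "timing_classes.tsv")
    utils::write.table(report$temporal$class_gst, p, sep = "\t",
                       row.names = FALSE, quote = FALSE)
    paths <- c(paths, p)
  }
  if (is.null(report$spatial$skipped) && is.null(report$spatial$error) &&
      !is.null(report$spatial$correlogram_even_width)) {
    p <- file.path(dir, "correlogram.tsv")
    write_correlogram(report$spatial$correlogram_even_width, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
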