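# colonykin

Fine-scale spatial and temporal population genetics **within** a breeding
colony, from codominant microsatellite genotypes plus nest coordinates,
hatch dates, sex and group labels.

Most population-genetic toolkits ask whether *populations* differ. This
package asks the within-colony questions a colonial-seabird (or any
colonial-breeder) dataset poses: Is the colony panmictic? Do birds nest
near their relatives? Do early breeders form a different gene pool from
late breeders — isolation by *time* rather than by distance?

## What it computes

* **Marker QC** — Monte-Carlo exact Hardy–Weinberg tests (Levene
  conditional), genotypic linkage-disequilibrium G-tests, Benjamini–
  Hochberg FDR control, Chakraborty/Brookfield null-allele estimates,
  duplicate-sample genotyping error rates, and a two-condition locus
  filter (FDR-significant homozygote excess *and* null frequency > 10%).
* **Relatedness & inbreeding** — four moment estimators of pairwise
  relatedness (Wang-category least squares, Queller–Goodnight,
  Lynch–Ritland, Li similarity), dyad simulation by Mendelian transmission
  for estimator comparison, Ritland's method-of-moments individual
  inbreeding coefficient F, and a greedy mutually-unrelated subset
  (threshold 0.24 by default, just under the half-sib expectation).
* **Differentiation** — Hedrick/Meirmans standardized G″ST from
  Nei–Chesser sample-size-corrected HS/HT:
  `G″ST = k(HT − HS) / ((k·HT − HS)(1 − HS))`,
  with label-permutation p-values, locus-bootstrap CIs, and Evanno ΔK
  post-processing of external clustering runs.
* **Spatial structure** — the Smouse–Peakall multilocus machinery:
  codominant squared genotypic distances, double-centered covariance
  surface, distance-class autocorrelation r with permutation envelopes and
  pair bootstraps, the omega whole-correlogram heterogeneity test
  (significance convention alpha = 0.01), sex-stratified comparison, 2D
  local autocorrelation (`lr` with k = 4 nearest neighbours), and
  within/between transect- and sampling-point relatedness permutation
  tests.
* **Temporal structure** — k-means breeding-timing classes, class-pair
  G″ST with hatch-day gaps, Mantel tests of relatedness vs hatch-date
  difference, and OLS of F on ladder-of-powers (Tukey) transformed hatch
  dates.
* **Synthetic colonies** — a generator emulating a two-ground,
  transect-sampled tropical-seabird colony (287 adults, 25 loci of 6–38
  alleles, 0/30/60/90 m sampling points, a 42-day four-wave hatching
  season, ~0.3% missing data) with controllable planted kin clusters and
  drift-calibrated temporal divergence, so every stage is testable without
  field data.

## Worked example

```r
library(colonykin)

sc <- colony_scenario(kin_clusters = 3, temporal_target_gst = 0.012,
                      seed = 11)
ds <- simulate_colony(sc)
ds
#> genotype_dataset: 287 individuals x 25 loci; 21 missing genotype cells
#> metadata: breeding_ground, transect, sampling_point, x, sex, hatch_day

rel <- pairwise_relatedness(ds, "wang")
rel
#> relatedness_matrix (wang): 287 individuals, 41041 pairs,
#>   mean r = -0.0029 +/- 0.0998

report <- run_full_analysis(ds, analysis_config(fast = TRUE, seed = 4))
report
#> analysis_report: 287 individuals, 25 loci
#>   diversity       ok
#>   relatedness     ok
#>   differentiation ok
#>   spatial         ok
#>   temporal        ok
report$differentiation$gst_double_prime   # 0.0038 — grounds undifferentiated
report$spatial$lsa$n_flagged              # 24 individuals with kin neighbours
report$temporal$mantel                    # R2 ~ 1e-4, p = 0.38
```

Reading: mean pairwise relatedness near zero with SD ~0.09 and a
breeding-ground G″ST of ~0.004 say the colony is effectively panmictic at
the landscape scale; the local-autocorrelation flags and the
timing-class G″ST (earliest vs latest classes) carry the fine-scale
spatial and temporal signal that was planted in the scenario.

Real data enter through `read_genotype_table()` (GenAlEx codominant CSV,
plain CSV, or STRUCTURE two-row) plus a metadata CSV keyed by individual
id (`attach_metadata()`).

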