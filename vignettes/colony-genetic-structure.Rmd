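---
title: "Within-colony spatial and temporal genetic structure: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Within-colony spatial and temporal genetic structure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(colonykin)
```

`colonykin` analyses a single breeding colony from the inside: diploid
microsatellite genotypes tied to nest coordinates, hatch dates, sex and
sampling design. This vignette is the package's account of the science —
the models, their assumptions, the tunable parameters and the numerical
choices — and of what the synthetic colony generator does and does not
emulate.

## The data model

A `genotype_dataset` holds one unordered pair of integer allele labels per
individual per locus, plus per-individual metadata. Two conventions are
enforced at construction: allele pairs are canonicalised (low label first),
so `(a,b)` and `(b,a)` are the same genotype, and a genotype is either
fully typed or fully missing. Allele labels are opaque fragment sizes —
nothing assumes stepwise mutation, and no size binning is attempted.
Individuals with any typed loci are retained by default;
`filter_individuals()` implements a per-individual missingness cutoff
(default 15%) for stricter workflows.

Expected heterozygosity is reported with Nei's unbiased small-sample
correction, `He = 2n/(2n-1) * (1 - sum p^2)`, the convention of common
genotyping software; the uncorrected value is exposed alongside because
downstream formulas (null-allele estimates, Dirichlet calibration) are
sometimes stated in terms of it.

## Marker quality control

**Hardy–Weinberg.** The exact test conditions on the observed allele
counts: the `2n` allele copies are shuffled into `n` random diploid
genotypes, which samples genotype tables with probability proportional to
their Levene conditional probability. The default *probability ordering*
counts tables no more probable than the observed one; a one-tailed
*homozygote score ordering* (no more heterozygotes than observed) is
exposed because homozygote excess — the signature of inbreeding and null
alleles — is usually the alternative of interest. All permutation-type
p-values in the package use `(k+1)/(N+1)`, so zero never occurs and the
attainable null rejection probability at level alpha is exactly
`floor(alpha (N+1))/(N+1)`.

**Linkage disequilibrium** uses the log-likelihood-ratio G of the
two-locus genotype contingency table with a genotype-permutation null;
this tests genotypic association without needing gametic phase.

**Null alleles** default to the Chakraborty moment estimate
`(He − Ho)/(He + Ho)`, chosen for its closed form and monotonicity in
homozygote excess (Brookfield-1 by option). **Locus filtering** requires
*both* an FDR-significant Hardy–Weinberg departure with homozygote excess
*and* a null-allele estimate above 10% — a deliberate two-key rule so one
noisy statistic never discards a marker. FDR control is
Benjamini–Hochberg (Benjamini–Yekutieli by flag). Running the
Hardy–Weinberg tests on a mutually unrelated subset
(`select_unrelated()`, threshold 0.24) avoids the spurious departures kin
structure induces.

**Genotyping error** is estimated from re-amplified duplicate samples as
per-locus mismatch fractions (missing comparisons excluded, undefined
rates reported as absent). A maximum-likelihood dropout/false-allele
decomposition is out of scope.

## Pairwise relatedness

Four codominant moment estimators share one engine
(`pairwise_relatedness()`, tags `queller_goodnight`, `lynch_ritland`,
`li`, `wang`), all computed over the loci typed in both members and
referenced to full-sample allele frequencies by default (the common
convention; a supplied frequency table overrides it). Expected values are
0.5 for parent–offspring and full siblings, 0.25 for half siblings, 0 for
unrelated pairs; moment estimates go negative for pairs sharing less than
random expectation.

The `wang` tag deserves its numerical note. It is built on the
similarity-category model of Wang (2002): each dyad-locus falls in one of
four categories (identical genotypes; one homozygote sharing its allele;
two heterozygotes sharing one allele; no sharing), whose probabilities are
linear in the two- and four-gene identity coefficients `(phi, Delta)` with
coefficients that are polynomials in the frequency moments
`a2, a3, a4 = sum p^2, sum p^3, sum p^4` (derived from first principles in
the source, with the identities `b = 2 a2^2 - a4` for the unrelated
identical-genotype probability and so on). We estimate `(phi, Delta)` by
ordinary least squares on the three category equations and report
`r = phi/2 + Delta`; loci are weighted by `1/u`, `u = 2 a2 - a3` (the
expected unrelated similarity), and the moments use multinomial-unbiased
small-sample corrections when sample counts are available. This is a
least-squares variant of the published estimator rather than a verbatim
transcription of its variance-optimal weights; simulation shows it
unbiased at r in {0, 0.25, 0.5} with efficiency close to
Queller–Goodnight on polymorphic panels, and a per-dyad `lm()`
transcription in the test suite pins the implementation to 1e-10.

`simulate_dyads()` builds dyads by explicit Mendelian transmission from
founder genotypes — never by rejection toward a target r — so true
relatedness is exact by construction. `compare_estimators()` simulates all
four relationship classes from a dataset's empirical frequencies (250
dyads per class by default) and ranks estimators by the Pearson
correlation of estimate with truth; on highly polymorphic 25-locus panels
all four land in the 0.85–0.95 range with Lynch–Ritland trailing, and the
ranking degrades uniformly on low-diversity panels.

**Inbreeding** uses Ritland's method of moments: per locus a homozygote
for allele `a` contributes `1/p_a − 1`, a heterozygote `−1`, each locus
carrying weight `n_alleles − 1`, combined as a ratio of sums so
information-rich loci dominate. It is unbiased but noisy for single
individuals — the SD near 0.05 on 25-locus panels is a property of the
marker count, not a defect.

**Unrelated subset.** The published pedigree-free subset-pickers are
proprietary; we use a documented greedy rule — repeatedly remove the
individual in the most pairs at or above the threshold, ties broken
toward the earlier id — which guarantees all retained pairs are below
threshold but not a maximum subset.

## Standardized differentiation

GST computed from heterozygosities tops out far below 1 when within-group
diversity is high — exactly the microsatellite regime — so groups are
compared with the Meirmans–Hedrick standardization:
`HS` and `HT` are Nei–Chesser estimators with the harmonic mean group
size and observed-heterozygosity correction, averaged over loci, and
`G''ST = k (HT − HS) / ((k HT − HS)(1 − HS))`, 0 for identical groups and
1 for groups sharing no alleles regardless of diversity. The permutation
test shuffles individuals among groups (sizes fixed; one-tailed, since the
alternative is differentiation); the bootstrap CI resamples **loci**, the
exchangeable replicates of a multilocus estimate — a deliberate design
choice documented here because individual-bootstrap CIs answer a different
question. Monomorphic or single-individual-group loci drop out of the
locus average rather than poisoning it.

`evanno_delta_k()` only post-processes a table of external clustering
log-likelihoods (`K`, `loglik` per run): first differences, absolute
second differences, and `deltaK = |L''(K)| / SD(L(K))`, undefined at the
boundary or at zero SD. The clustering MCMC itself is out of scope.

## Spatial autocorrelation

The multilocus machinery follows the Smouse–Peakall construction.
Genotypes become allele-count vectors; the squared genotypic distance is
half the squared Euclidean distance between them (identical 0; AA–AB 1;
AB–AC 1; AB–CD 2; AA–BC 3; AA–BB 4), summed over loci. Missing
dyad-loci take the locus mean observed pair distance, keeping the matrix
complete without biasing typed pairs. Double-centering the squared
distance matrix (as in principal-coordinate analysis) gives a covariance
surface `C`; the autocorrelation of a set of pairs is the sum of their
off-diagonal `C` entries over the matching mean diagonal sum, a
correlation-like quantity in `[-1, 1]`.

Distance classes come in the two field conventions: even-width half-open
bins up to a maximum (default 5 x 20 m to 100 m — the transect scale;
pairs beyond the maximum, e.g. between transects, are excluded), and
even-count bins covering all pairs (default 37 classes), ties broken by
pair order. Pairs at distance zero (shared nests) sit in the first class.

Significance is two-layered. Per class, a permutation envelope (genotypes
shuffled over locations) and a within-class pair bootstrap CI. For the
whole correlogram, the omega heterogeneity statistic: the sum over classes
of squared permutation-standardized deviations of r, with p from the same
permutation distribution, judged at alpha = 0.01 by convention. The
sex-stratified comparison computes per-sex correlograms on common class
edges and applies the same omega construction to the difference vector
`r_M − r_F`, permuting sex labels.

**2D local autocorrelation** restricts the covariance algebra to each
focal individual and its k = 4 nearest geographic neighbours (four
surrounding nests being the natural neighbourhood of a ground-nesting
colony; coordinate ties break deterministically by individual order), with
a one-tailed genotype-permutation p per individual. P-values are
deliberately *not* multiplicity-adjusted — the convention is per-individual
reporting at alpha = 0.05, and roughly 5% false flags under panmixia are
expected and observed — an FDR flag exists for conservative use.

The within/between-group heterogeneity test takes a relatedness matrix
and group labels (transects or sampling points), compares the mean
within-group r against a null built from random pseudo-groups of the same
sizes (default 10,000 draws), one-tailed, and reports the between-group
mean alongside. Group means here are over all within-group pairs;
same-individual comparisons do not exist because the matrix diagonal is
undefined.

## Temporal structure

Breeding-timing classes come from 1-D Lloyd k-means on hatch day
(best of 25 seeded random restarts; classes relabelled by ascending mean
so class 1 is always the earliest). k defaults to 4; a silhouette helper
(`choose_k_timing()`) exists but is not part of the replication path,
because the class count is treated as a design constant. Both adults of a
nest carry the nest's hatch day; class membership is per individual.

Class-pair differentiation delegates to the G''ST machinery and annotates
each pair with the gap between class mean hatch days — the
isolation-by-time contrast. The Mantel test correlates lower-triangle
relatedness against absolute hatch-day differences with joint row/column
permutation of one matrix; two-tailed by default (the sign of a
relatedness–time association is not prescribed a priori), one-tailed by
option.

The inbreeding–timing regression is OLS of Ritland F on hatch day after a
ladder-of-powers (Tukey) transform: exponent lambda chosen on the grid
[-5, 5] in steps of 0.025 to maximise the Shapiro–Wilk W of the
transformed predictor (`x^lambda`; `log x` at 0; `-x^lambda` below 0 to
keep the transform increasing; non-positive inputs shifted by `1 − min`
and the shift recorded). The grid bounds and step follow the common
ladder-of-powers implementation convention and are reported with the fit
for reproducibility.

## The synthetic colony generator

`colony_scenario()` encodes the emulated study design, and its defaults
*are* the study conditions rather than tuning knobs: 287 breeding adults
split 217/70 between two breeding grounds; five 90-m transects (4 + 1)
with sampling points at 0/30/60/90 m and ~15 nests scattered within 5 m
(the GPS accuracy scale) of each point; 25 loci with a fixed allele-count
panel spanning 6–38 (mean ~17.5); symmetric Dirichlet allele frequencies
with concentration 0.4, giving expected heterozygosity near 0.82 at ~17
alleles (`E[1 − sum p^2] = (K−1)a/(Ka+1)`); hatch days from four Gaussian
waves at 74/82/91/108 days (SDs 1/2/3/3, weights 53/27/58/65), spanning a
~42-day season; 0.32% missing genotypes. Where the design needed a value
the study conditions do not fix (transect spacing 500 m, ground gap 5 km,
nest scatter radius), we chose once what a field layout of this kind looks
like and do not revisit it.

Structure is *planted*, never assumed: `plant_kin_clusters()` replaces
chosen individuals with Mendelian sibships co-located at one sampling
point; `plant_temporal_divergence()` drifts an early and a late allele
pool by Wright–Fisher resampling (pool size 2000, so each generation moves
standardized divergence by a fine increment) until the frequency-level
G''ST between pools is within ±20% of the target, then redraws the
earliest and latest timing classes from their pools — drift rather than
ad-hoc frequency perturbation so the realized divergence has realistic
locus-to-locus variance. `corrupt_genotypes()` adds missingness and
allelic dropout (a heterozygote losing one copy becomes an apparent
homozygote; losing both becomes missing), which can only reduce observed
heterozygosity. All randomness flows from one scenario seed through named
substreams (genotypes, layout, kin, temporal, corruption), so stages are
independently reproducible.

What the generator does **not** emulate — and hence what passing tests do
not certify about field data: genotyping artefacts beyond random
missingness and symmetric dropout (no stutter, no size-dependent dropout,
no null-allele loci unless planted), uneven nest density and habitat
structure, assortative mating, age structure and multi-season dynamics,
and heritable breeding timing (temporal divergence is imposed on one
season, not evolved). Calibration results transfer to real colonies only
to the extent these simplifications hold.

## Numerical conventions and edge cases

* p-values: always `(k+1)/(N+1)`, one-tailed toward the stated
  alternative except the Mantel test (two-tailed default); ties counted as
  extreme with a 1e-12 tolerance.
* Monomorphic loci: Hardy–Weinberg p defined as 1; skipped by relatedness
  and inbreeding estimators (zero information); contribute HS = HT = 0 to
  the differentiation averages.
* Pairs with fewer than 2 shared typed loci: relatedness flagged `NA`,
  excluded from means and pair counts.
* Distance-class edges: half-open `[lo, hi)`, last bin closed; zero
  distances in class 1; even-count ties broken by pair order, so results
  are permutation-stable.
* Seeded routines save and restore the caller's RNG state.
* The pipeline (`run_full_analysis()`) records the seed beside every
  stochastic stage, skips stages whose metadata is absent with an explicit
  notice, and records stage errors without aborting independent stages.

## Problem sizes used by the shipped checks

The test suite calibrates the permutation tests on 500 null colonies at
the study scale (25 loci, n = 250) with 99 permutations per test —
chosen because `(k+1)/(N+1)` makes the attainable null rejection rate at
alpha = 0.05 (and 0.01 for omega) exact at N = 99 — and verifies estimator
recovery on 1000 dyads per relationship class. Oracle-equivalence checks
(full-enumeration Hardy–Weinberg, brute-force correlogram algebra,
exhaustive FDR search, exhaustive unrelated subsets) run at n <= 6 where
enumeration is feasible. The acceptance script runs the full battery once
at reduced permutation counts (199–4999 depending on the stage); its
results are estimates with the correspondingly wider Monte-Carlo error.

## Known limitations

* The `wang` tag is a least-squares estimator on the Wang category model,
  not the published variance-optimal weighting; its sampling variance is
  a few percent higher.
* The greedy unrelated subset does not guarantee the maximum subset.
* The correlogram imputes missing dyad-loci with locus means, which
  shrinks r very slightly toward 0 at high missingness (negligible at the
  sub-percent missingness this data type shows).
* Evanno ΔK requires consecutive integer K with replicate runs and
  nonzero SD; it is reported as undefined otherwise rather than
  extrapolated.
* 1-D k-means with 25 restarts is deterministic for a fixed seed but not
  guaranteed globally optimal on adversarial inputs; the within-class
  sum of squares is reported so solutions can be compared.
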