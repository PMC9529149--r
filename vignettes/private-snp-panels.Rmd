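---
title: "Selecting and validating species-diagnostic private SNP panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting and validating species-diagnostic private SNP panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(privsnp)
```

## The problem

Morphologically similar species — freshwater prawns are the motivating
case — are routinely misidentified in the field, which matters for
fisheries, aquaculture and conservation. Genome-wide genotyping (thousands
of SNPs) separates such species cleanly, but routine use calls for a small,
cheap marker panel. `privsnp` reduces a genome-wide biallelic SNP set to a
panel of *private* SNPs — loci that segregate in exactly one population and
are fixed in all others — and then quantifies how well that panel assigns
individuals to their species.

The input is an individuals × loci matrix of alternate-allele counts
(0/1/2, with missing calls) plus a map from individual to species label.
Nothing downstream needs genomic coordinates, so the pipeline works equally
for reduced-representation data where most markers are unplaced.

## The selection procedure

1. **Quality control** (`qc_filter()`): keep loci with overall call rate
   strictly above 80% and pooled minor-allele frequency strictly above 5%
   (both thresholds configurable). Call rate is tested first so every
   removed locus is attributed to exactly one filter.
2. **Per-population allele frequencies** (`allele_frequencies()`): for each
   population and locus, the alternate-allele frequency
   $p = \sum g / (2 n)$, the count $n$ of non-missing genotypes, and the
   observed heterozygote proportion, all over non-missing calls only.
3. **Private-locus detection** (`detect_private_loci()`): a locus is
   private to population $s$ when it segregates there with
   segregating-allele frequency in $[0.03, 0.97]$ and every other
   population is fixed — for the *same* allele — within `fixed_tol`
   (default exactly fixed). The lower bound avoids calling effectively
   fixed loci "segregating"; the upper bound is its mirror image, so a
   locus nearly fixed for the alternate allele in its host is equally
   rejected. The segregating allele is defined as the allele absent from
   the non-host populations, which is what makes the reported host
   frequency comparable across loci regardless of reference/alternate
   orientation.
4. **Resampling stability selection** (`stability_select()`): re-run
   detection on 100 random subsets holding $\lceil 0.8\,n_s \rceil$
   individuals of each population (ceiling, so a population of 5 keeps 4),
   and count for each full-data private locus the runs that re-detect it
   with the *same* host. The relaxed panel ("panel-50") keeps loci detected
   in more than 50 runs; the core panel ("panel-80") more than 80. A locus
   that flips host population between runs is not a stable diagnostic
   marker and such runs count as non-detections (they are logged).
5. **Fst filter** (`wc_fst()`, `apply_fst_filter()`): per-locus Weir &
   Cockerham (1984) $\theta = a/(a+b+c)$ across all populations, computed
   from the three variance components (among populations, among individuals
   within populations, within individuals). Panel entries with
   $\theta \le 0.7$ — or with undefined $\theta$ — are excluded and
   reported with a reason. Populations without calls at a locus are dropped
   from that locus's estimate rather than imputed: heavy missingness must
   not manufacture either privacy or differentiation.

`summarize_panel()` then reports, per population, the panel size, the
within-host MAF range and mean, the mean observed and mean unbiased
expected heterozygosity, and the $\theta$ range.

### Decisions worth knowing about

* **Strict inequalities everywhere** (`>` 80% call rate, `>` 5% MAF,
  `>` 50/80 runs, `>` 0.7 theta): the bounds themselves are excluded.
* **QC MAF is pooled**, not per-population, matching the array-style QC
  stage this filter emulates. A side effect worth knowing: a locus private
  to one of $k$ equally sized populations has pooled MAF $\approx$ host
  frequency $/k$, so private loci with modest host frequency can fall below
  a pooled 5% cut when there are many populations. The threshold is a
  parameter precisely because discovery studies may want it lower.
* **Missingness rules**: a population with zero calls at a locus makes the
  locus ineligible for privacy in that evaluation (not "fixed by absence of
  evidence"), and undefined statistics are `NA` with a recorded reason,
  never silently 0.
* **Expected heterozygosity** defaults to the unbiased
  $2n/(2n-1)$-corrected gene diversity, the convention of the standard
  per-population summaries this mirrors; the uncorrected variant is a flag
  away.
* **Multi-population versus pairwise $\theta$**: for a locus private to one
  of $r$ equal populations, the all-population $\theta$ is bounded well
  below 1 unless the host frequency approaches fixation (about 0.16 at host
  frequency 0.2 with seven populations, about 0.48 at 0.5, about 0.95 at
  0.95 — direct evaluation of the estimator). Published per-species Fst
  ranges for private panels are often far higher than the all-population
  estimator can produce at moderate host MAF; the exact grouping behind
  such values is usually not recoverable. `privsnp` therefore exposes both
  `wc_fst()` (all populations) and `pairwise_wc_fst()` (two populations)
  and makes no attempt to reproduce any particular published magnitude.

## Validation

`impute_center()` replaces missing calls by the locus mean and centers each
locus; `pca_fit()` gives deterministic principal components (sign fixed by
the largest-magnitude loading); `kmeans_bic_scan()` evaluates
$\mathrm{BIC}(K) = n \ln(W_K/n) + K \ln n$ over best-of-restarts K-means
fits, where $W_K$ is the total within-cluster sum of squares; `dapc_fit()`
performs discriminant analysis of principal components — PCA reduction,
then linear discriminant analysis on the retained scores — yielding
posterior membership probabilities under equal cluster priors, so that
uneven sample sizes (5 versus 18 per species is typical) do not bias the
posterior. `assignment_accuracy()` maps clusters to true labels (majority
vote, or optimal one-to-one matching) and reports the fraction assigned
correctly together with the mean maximum posterior membership.

Numerical and design choices:

* The K-means BIC form above is the standard penalized within-cluster
  criterion; the curve is always returned so an elbow ("point of
  deflection") reading can be applied by eye, but the default `chosen_k` is
  the argmin with ties broken towards smaller $K$. For strongly separated
  clusters the two coincide.
* **K-means restarts default to 50** (300 iterations, seeded). With the
  default 90%-of-variance retention the clustering space has dozens of
  nearly isotropic noise dimensions, and measured failure rates for
  best-of-10 K-means on such scores were above 50% (a cluster pair merged
  while another split); best-of-50 eliminated every such failure at
  negligible cost. If $K$ exceeds the number of distinct score points, a
  zero-within-SS clustering exists and the scan records $W_K = 0$ rather
  than failing.
* **DAPC dimensions**: `n_pca` defaults to the smallest number of
  components explaining 90% of variance, capped at $n - K - 1$ so the
  within-group scatter stays invertible; `n_da` defaults to $K - 1$. The
  `MASS::lda()` tolerance is lowered to $10^{-9}$ because the leading PCs
  of a well-separated panel have *small within-group variance by
  construction* — that is the signal, not a degenerate variable.
* DAPC supports both the supervised assignment test (`grouping =` known
  species labels — the standard way to validate a diagnostic panel) and
  unsupervised cluster inference (`k =` with K-means on the retained
  scores). The two answer different questions: the supervised posterior
  asks "can the panel discriminate the species?", the unsupervised route
  additionally asks "is the species structure recoverable de novo?".
  With few loci per species and strong heterozygote deficit, individuals
  carrying zero copies of their species' private alleles can form a
  central K-means cluster even though the supervised discriminant assigns
  them perfectly; reporting both guards against over-reading either.

## The synthetic genotype generator

`simulate_dataset()` builds datasets with the statistical structure the
pipeline assumes, plus ground truth, so that every stage is testable
without any external download:

* **Shared loci**: an ancestral frequency from a truncated
  Beta$(\alpha,\beta)$, then each underlying population's frequency from
  the Balding–Nichols distribution
  Beta$(p(1-\theta)/\theta,\,(1-p)(1-\theta)/\theta)$ — a parameter-sparse
  drift model that with $\alpha < 1$ reproduces the low-MAF-dominated
  spectra typical of reduced-representation genotyping of poorly annotated
  genomes.
* **Private loci**: host-population frequency uniform on a configurable
  range, exactly zero elsewhere.
* **Genotypes**: drawn with an inbreeding-style heterozygote deficit,
  $P(\mathrm{het}) = 2p(1-p)(1-F)$, because empirical panels of this kind
  show observed heterozygosity an order of magnitude below the
  Hardy–Weinberg expectation at the observed MAFs; $F$ is exposed, not
  hard-coded.
* **Conspecific labels**: distinct labels may share one underlying
  population, emulating morphological oversplitting; missingness is
  missing-completely-at-random.

The demonstration configuration (`demo_simulation_config()`) mirrors a
seven-species survey: sample sizes 18, 18, 18, 17, 12, 5, 5; two
conspecific label pairs (hence five underlying populations); $F = 0.95$;
private host frequencies 0.05–0.48; about 1,800 loci. Running the pipeline
on it shows an instructive property: labels that are *exactly* conspecific
cannot have label-private loci at all, so panels emerge only for the
genuinely distinct species. Real oversplit species pairs are close but not
identical, so real data sit between this demonstration and the fully
distinct scenario.

What the generator does **not** emulate: linkage (loci are independent),
selection, batch or informative missingness, and genotyping error. Passing
the simulation-based tests therefore demonstrates the pipeline's
correctness and calibration under its own model, not robustness to those
real-data complications.

## Problem sizes and calibration checks

The package's own test battery runs, among others:

* exhaustive-enumeration equivalence of the private-locus rule on 200
  random matrices of up to 8 individuals × 10 loci × 3 populations;
* analytic Weir & Cockerham cases (fixed difference $\theta = 1$; the
  equal-frequency two-population case with hand-derived components);
* recovery of planted panels: 4 populations × 30 individuals, host MAF
  uniform on $[0.2, 0.5]$ at Hardy–Weinberg equilibrium, no missingness, 20
  seeds — chosen by a power calculation so that the probability of a
  planted allele being lost from the sample (or a shared locus drifting to
  empirical privacy in three populations of 30) is negligible, making
  "every planted locus in the core panel, no shared locus in it" a fair
  deterministic expectation;
* stability calibration: a host population of 10 with a single heterozygous
  carrier gives full-data frequency $1/20 = 0.05$ (detectable) and carrier
  inclusion probability $8/10$ per resample, so the stability count must
  average $100 \times 0.8 = 80$ — verified over 50 seeds against the
  binomial standard error;
* study-scale assignment: seven populations of 20 with 12 planted private
  loci each (host MAF 0.2–0.5, $F = 0.9$, 2% missingness, 400 shared
  loci): the supervised DAPC assignment test must be perfect with the core
  panel and with all loci alike.

These sizes keep the whole suite under a minute while leaving each check
statistically meaningful; `scripts/acceptance.R` re-runs the study-scale
scenarios from scratch and writes the headline numbers as JSON.

## Known limitations

* The private-locus rule is frequency-based; with very small host samples
  the distinction between "segregating at 0.03" and "fixed" rests on one or
  two alleles, which is why the resampling stability count — not the
  full-data call — defines the panels.
* The discovery and validation samples are the same individuals, as in the
  study design this mirrors; supervised accuracy on training data is
  optimistic, and an independent sample is the only honest way to certify
  a panel for deployment.
* The all-population Weir & Cockerham $\theta$ of a locus private to one of
  many populations is structurally modest at moderate host MAF (see above);
  with the default `fst_min = 0.7` the filter is only informative when
  private alleles approach fixation in their host, and it will empty a
  panel of moderate-frequency private loci. Set `fst_min` lower (or to 0)
  when that regime applies.
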