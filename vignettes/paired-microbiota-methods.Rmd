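---
title: "Methods: comparing paired oral and faecal microbiota"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparing paired oral and faecal microbiota}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`micropair` implements a complete statistical workflow for comparing the
microbiota of two gastrointestinal-tract (GIT) regions — a proximal oral
swab and a distal faecal sample — collected from the same wild-bird
individuals. The design is paired but incomplete: some individuals
contribute a sample to both regions, most to only one. Every stage of the
workflow has to respect that partial pairing. This vignette explains the
models and procedures, the tunable parameters, the numerical choices, and
what the synthetic-data generator does and does not emulate.

## Data model and filtering

The central object is an integer OTU count table (samples x OTUs; on disk
the conventional transposed layout with OTUs as rows). Construction
enforces unique IDs, non-negative counts, and a positive total per sample.

Two filters precede analysis:

* **Contaminant filtering.** Chloroplast 16S reads are diet material, not
  host-associated bacteria, and OTUs without any phylum assignment are
  likely artefacts; both are removed. Reference taxonomies disagree about
  whether the chloroplast label sits at the class or the order rank
  (`Chloroplast` vs `Streptophyta`), so both ranks are matched,
  case-insensitively. Samples emptied by this filter are dropped with a
  warning because pairwise dissimilarities are undefined for empty samples.
* **Prevalence filtering** (differential-abundance scan only): OTUs
  detected in at least `min_samples` samples (default 5). Per-OTU mixed
  models on rarer OTUs are uninformative.

**Rarefaction** subsamples each sample without replacement to a common
depth, by default the minimum sample total. A single draw is used with an
explicit seed: averaging draws would shrink the sampling variance that the
diversity analyses are supposed to see. The depth is a configuration knob
because no single depth suits all datasets.

## Alpha diversity and its contrasts

Three per-sample indices: observed richness, Shannon entropy (natural log;
the base is an option), and Chao1. Chao1 uses the bias-corrected form
`S + F1(F1-1) / (2(F2+1))`, defined even without doubletons; the classic
`S + F1^2/(2 F2)` variant sits behind a flag.

The region contrast is a likelihood-ratio test between two
maximum-likelihood random-intercept models,

```
diversity ~ region + (1 | individual)   vs   diversity ~ 1 + (1 | individual)
```

with the statistic referred to chi-squared on 1 df. The random intercept
absorbs the within-individual dependence created by the paired samples. ML
rather than REML is used throughout the package because likelihood-ratio
statistics comparing different fixed-effect structures are only valid under
ML. A calibration caveat discovered while validating the package: at the
motivating design's size (37 samples, 29 individuals) the chi-squared
reference is mildly liberal — the long-run type-I error at nominal 0.05 is
about 0.072. This is a property of the asymptotic reference, not of the
implementation (which reproduces `lme4` deviances to ~1e-7).

Host covariates (sex; scaled body mass index) are tested per region by
one-way ANOVA and single-slope regression, per metric.

## Beta diversity

Four pairwise dissimilarities: Bray-Curtis (abundance), binary Jaccard
(presence/absence; the quantitative variant exists behind a flag),
unweighted UniFrac, and weighted UniFrac (normalized by default so values
lie in [0, 1]). UniFrac is computed from a branch-by-OTU incidence matrix
built in one postorder pass, so whole distance matrices are a few matrix
products; unrooted input trees are midpoint-rooted with a notice, since
UniFrac needs a root. All metrics are computed on the rarefied table
(weighted UniFrac on within-sample relative abundances), so sequencing
depth cannot masquerade as composition.

PCoA is classical scaling: Gower double-centering of `-d^2/2` and an
eigendecomposition. Negative eigenvalues — expected for non-Euclidean
dissimilarities like Bray-Curtis — are reported as-is, with no
Cailliez/Lingoes correction; axis variance shares are taken relative to the
sum of positive eigenvalues.

## Distance-based inference with individual strata

**PERMANOVA** partitions the squared-dissimilarity sums
(`SS_total = sum_{i<j} d_ij^2 / n`, within-group analogues per group) into
a pseudo-F. The null distribution respects the paired design: region
labels are permuted only *within* an individual. For the motivating design
(8 paired individuals plus singletons) that space collapses to exactly
`2^8 = 256` distinct relabelings, so the engine enumerates it completely
and reports an exact p (`#(F_perm >= F_obs)/N`, observed labelling
included; ties count). Monte-Carlo sampling with
`p = (1 + exceedances)/(1 + n_perm)` is used when enumeration is
infeasible; the default budget is 9,999 permutations. Two small design
facts worth knowing: with two *equal-sized* groups every partition occurs
under both labelings, so the exact p can never fall below `2/N`; and the
floor of the Monte-Carlo p is `1/(n_perm+1)`.

**Dispersion contrast.** Interindividual variation per region is compared
via the distance of each sample to its own region's centroid in the PCoA
embedding (negative-eigenvalue axes entering with negative squared
contributions, floored at zero), followed by a one-way ANOVA on those
distances. This is the centroid flavour of `vegan::betadisper`, which
performs the computation; centroids rather than spatial medians because a
single F and p per metric is wanted.

**Mantel tests** correlate the lower triangles of two distance matrices,
with a one-sided (positive-association) permutation p obtained by jointly
permuting rows and columns of one matrix.

## Within-individual concordance

For the individuals sampled in both regions: Pearson correlation of paired
alpha diversities; a Mantel comparison of the two within-region distance
sub-matrices (do individuals with similar oral communities also have
similar faecal communities?); and per-OTU Spearman correlations of relative
abundances across pairs, restricted to OTUs detected in both regions of
the paired set, summarised by their mean and interquartile range. A
Spearman coefficient computed from fewer than three distinct values is
reported as missing rather than a spurious +/-1.

## The differential-abundance scan

The scan asks, per OTU, whether read counts differ between regions beyond
what sequencing depth and individual identity explain:

1. Counts are shifted by +1 (zeros are ubiquitous) and Box-Cox
   transformed; sample totals are Box-Cox transformed and enter as an
   offset with coefficient fixed at 1, i.e. subtracted from the response.
   The transform parameter is profiled on `[-2, 2]` separately for the
   response and (once per dataset) for the totals; a shared fixed lambda
   is available via arguments.
2. A random-intercept LMM (individual) is fitted by ML with and without
   the region effect; the statistic is the deviance change.
3. Significance comes from a permutation null: the per-sample
   (count, total) *pairs* are permuted jointly across samples — keeping
   the count-depth coupling that the offset encodes while breaking any
   region association — and both models are refitted per permutation.
   Because a joint permutation of the pairs simply permutes the
   offset-adjusted response, and the profiled lambdas depend only on
   permutation-invariant marginals, the transforms are computed once.
   `p = (1 + #(ddev_null >= ddev_obs)) / (1 + n_perm)`, default
   `n_perm = 10,000`. Permutations here are unrestricted across samples.
4. Storey q-values control the FDR across the scanned set, with the null
   fraction estimated on the lambda grid 0.05..0.95, smoothed by a cubic
   spline (df 3) and read off at 0.95, clamped to (0, 1]. With the null
   fraction forced to 1 the q-values are exactly Benjamini-Hochberg.
5. An OTU is called significant when both p and q fall below 0.05; the
   direction flag (`+oral` / `+faecal`) is the sign of the fitted region
   contrast.

The inner fitter is written in C++: for the random-intercept model the
covariance `V = sigma2 (I + lambda Z Z')` has a closed-form inverse and
determinant per individual (compound symmetry), so the profiled deviance
is an O(n) function of group sums, minimised over the variance ratio by a
coarse log-grid plus golden-section refinement including the boundary at
zero. A scan involves on the order of a million model fits; this fitter
reproduces `lme4` ML deviances to ~1e-7 at microsecond cost.

Two practical notes. First, the pipeline runs the scan on the
contaminant-filtered but *unrarefied* table with the raw totals as offset:
an offset is only informative when totals vary, and rarefying first would
make it a constant. Prevalence is assessed on the same table. Second, the
permutation p floor interacts with the q-value threshold: with `n_perm`
permutations and `m` scanned OTUs, OTUs at the floor `1/(n_perm+1)` get
`q ~ pi0 * m / ((n_perm+1) k)` where `k` is the number of floor-hitters,
so at small permutation budgets (say 199) a joint p-and-q rule can be
unsatisfiable for any test, however powerful, unless `k` exceeds roughly
`pi0 * m * 0.05^{-1}/(n_perm+1)`. Use permutation budgets of a few
thousand or more when q-values matter.

## Host body condition

The scaled mass index standardises body mass to a reference tarsus length:
`SMI = mass * (L0 / tarsus)^b`, with `b` the standardized major axis slope
of log mass on log tarsus (`b_OLS / |r|`, equivalently the sd ratio with
the sign of r) and `L0` defaulting to the mean tarsus of the analysed
sample. Individuals at the reference length keep their observed mass.

## The synthetic-data generator

No public per-sample OTU table accompanies the motivating study, so the
package ships a generator that emulates the *statistical structure* the
analyses assume, with full ground truth:

* the incomplete paired design (default 20 oral + 17 faecal samples, 8
  individuals with both; 29 birds);
* per-OTU baseline log-abundances Normal(0, 1.5) — a steep rank-abundance
  curve;
* a Dirichlet-multinomial sampling model: composition is a Dirichlet draw
  around the softmax of the log-abundances with a region-specific
  concentration (oral 100, faecal 30 by default; the lower faecal
  concentration produces the higher faecal interindividual dispersion
  seen in the data, and both values sit in the range reported for
  Dirichlet-multinomial fits to 16S surveys), then multinomial counts at
  a log-normal depth (log-mean `log(6700)`, log-sd 0.55, putting the
  minimum depth across 37 samples near 2,000);
* per-individual, per-OTU Normal random intercepts (sd 0.5) shared across
  an individual's two samples;
* spiked region-differential OTUs at a configurable log2 fold change,
  plus "background" region-enriched OTUs (30% oral, 12% faecal,
  suppression of 3 natural-log units in the other region) that create the
  oral-richness excess and the partial-overlap pattern of the real data;
* chloroplast (5%) and phylum-unassigned (3%) OTUs with
  region-independent abundance, to exercise the contaminant filter;
* sex and body size with no compositional effect by default (the
  motivating study found none), switchable for power studies.

What the generator does *not* emulate: sequence-level artefacts (chimeras,
PCR bias), phylogenetic signal in abundances (the random tree is
independent of the abundance model), and taxon-specific dispersion (one
concentration per region). Passing tests therefore demonstrate the
correctness and calibration of the *procedures*, not how a particular real
community will behave.

Two consequences of realistic overdispersion are worth stating plainly.
Per-OTU fold-change estimates formed as the log of a ratio of mean
relative abundances are heavy-tailed and upward-biased at these
concentrations; consistency checks therefore use the mean of per-sample
log2 relative abundances with a half-read pseudocount. And the scan's
power at 4-fold effects on 40 samples is modest — which matches the
original analysis flagging only 33 of 240 scanned OTUs. When both regions
share a concentration the permutation test is well calibrated; when the
regions differ in dispersion the permutation null mixes the two variances
(a Behrens-Fisher situation) and the mean-effect test also reacts to the
dispersion difference.

## Numerical choices and degenerate inputs

* Variance-ratio optimisation: grid `log(lambda)` in [-10, 10] (41
  points) plus the `lambda = 0` boundary, golden-section refinement to
  1e-9; deviance changes of nested fits are floored at 0 within 1e-6.
* Box-Cox on a constant vector returns `lambda = 1` (any lambda fits);
  constant offset-adjusted responses yield `ddev = 0`, `p = 1`, with a
  warning.
* Permutation ties count as exceedances (conservative).
* PCoA eigenvalues below `max(eig) * 1e-12` are treated as null axes.
* All randomness flows from explicit seeds; the pipeline derives fixed
  per-stage offsets from one master seed, so stages can be re-run in
  isolation and identical configurations give byte-identical outputs.
* Problem sizes in the shipped checks are chosen to keep a full run at a
  few minutes on one core: the end-to-end analysis uses the 37-sample,
  1,127-OTU preset with 9,999 permutations for distance-based tests and
  1,999 permutations per OTU in the scan; calibration studies use 500 to
  6,000 simulations per procedure.

## Known limitations

* Single-factor PERMANOVA only; no multi-factor partitioning or post-hoc
  pairwise contrasts.
* The LRT's asymptotic reference is mildly liberal at small n (above);
  a parametric-bootstrap reference would fix this at substantial cost.
* The scan models one OTU at a time; no compositional (log-ratio) or
  zero-inflated treatment, and no covariates beyond region.
* Storey's pi0 estimate is unstable when the scanned set is small or
  p-values are strongly discrete; the BH-equivalent `pi0 = 1` option is
  the conservative fallback.
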