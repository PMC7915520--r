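---
title: "Mapping drought-plasticity QTLs with regression-residual trait scores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping drought-plasticity QTLs with regression-residual trait scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastiqtl)
```

## The problem

When a biparental mapping population is grown under contrasting irrigation
regimes — well-watered (WW) and water-limited (WL) — the interesting genetic
signal is often not the trait value itself but how a line's performance
*changes* under stress, and how much of that change is routed through
flowering phenology. A line that escapes drought by heading early will show
apparent "plasticity" in yield that is really a phenology effect; a line
that maintains its water status shows plasticity of a different, intrinsic
kind. `plastiqtl` implements a complete pipeline for dissecting these
signals in a recombinant inbred line (RIL) population: regression-residual
plasticity scores, heritability across regimes, genetic-map construction
and diagnostics, multi-model interval mapping, rule-based classification of
QTLs into phenology and drought-resistance-strategy categories, and
physical anchoring of QTL intervals to gene annotations.

## Derivative trait sets

All derivative traits are residuals of ordinary least-squares fits on line
means (three replicate plots are averaged per line and regime before any
fit). Writing $V$ for a trait's line means and $DH$ for the line means of
the heading-date trait DP-H (days from planting to heading):

* **Phenology-adjusted traits** (prefix `df`, per environment):
  $V_{DH} = \beta + \alpha\,DH$, and the df-trait is the residual
  $E_{DH} = V - V_{DH}$. This removes the (often dominant) linear effect of
  flowering time from every other trait, separately under WW and WL.
* **Drought plasticity I** (prefix `d`):
  $prV_{WL} = \beta + \alpha\,V_{WW}$, residual $E_{WL} = V_{WL} - prV_{WL}$.
  The d-trait measures how far a line's stress performance deviates from
  what its non-stress performance predicts — a plasticity score normalized
  for the line's potential under control conditions.
* **Drought plasticity II** (prefix `ddf`):
  $V_{WL}^{DH} = \beta + \alpha_1 V_{WW} - \alpha_2 DH_{WL}$, residual
  $E_{WL}^{DH} = V_{WL} - V_{WL}^{DH}$. Adding WL heading date as a second
  predictor removes the drought-escape component: plasticity that is
  mediated entirely by earlier flowering disappears here. The minus sign on
  $\alpha_2$ is a reporting convention; the fit is unconstrained OLS.

The contrast between the two plasticity sets carries the biology: a QTL
with a `d` effect but no `ddf` effect acts through phenology (escape),
while a QTL with both acts on the trait's intrinsic stress response.

Missing data are handled by per-fit listwise deletion: a line is dropped
only from fits whose inputs it lacks, which maximizes the usable n of each
derivative set. Whether to fit on line means or on pooled replicate-level
values is a genuine choice; fits here use line means, consistent with
computing descriptive statistics and correlations on means.

## Heritability

Broad-sense heritability across the two regimes uses the genotype and
genotype-by-environment mean squares of a two-way ANOVA on replicate-level
data: $\sigma_g^2 = (MS_{gen} - MS_{g\times e})/e$,
$\sigma_{g\times e}^2 = MS_{g\times e}$, and
$h^2 = \sigma_g^2 / (\sigma_g^2 + \sigma_{g\times e}^2/e)$ with $e = 2$
environments. A negative $\sigma_g^2$ estimate is truncated to zero
(flagged), keeping $h^2$ in $[0,1]$. The field experiment this emulates
used a split-plot block layout; block terms are omitted from the default
model because only the two mean squares above enter the estimator, and the
generator does not simulate blocks (they can be added to the ANOVA by
extending the model formula, not by re-deriving the estimator). Normality
checks are advisory only — logged per trait and environment, never
blocking — since field traits such as leaf rolling are routinely analyzed
despite non-normality.

## Genetic-map construction

The mapper is a deterministic re-implementation of the skeleton-map
workflow used by ultra-dense RIL maps:

1. **Marker QC** removes markers with more than 10% missing calls or a 1:1
   segregation chi-square above 35 (one degree of freedom over the two
   homozygote classes — F6 lines carry essentially no heterozygotes).
2. **Co-segregation binning** merges markers at RF 0 on shared informative
   lines (single linkage) and keeps the least-missing member as the
   skeleton marker, ties broken by the lexicographically smallest id.
3. **Linkage-group clustering** is single linkage at RF ≤ 0.2; if more
   groups emerge than the chromosome number, groups are merged by smallest
   end-to-end RF until the target (14 for tetraploid wheat) is reached.
   Natural groups are never force-split.
4. **Ordering** minimizes the sum of adjacent RF by greedy
   nearest-neighbour construction from the most peripheral marker followed
   by 2-opt reversal passes to convergence. This replaces the guided
   evolutionary search of commercial mappers: at skeleton density the
   objective is nearly decomposable and 2-opt converges to the true order
   (order recovery on simulated 1000-line chromosomes is exact up to full
   reversal), while being deterministic and testable.
5. **cM assignment** back-transforms adjacent RF through the selfed-RIL
   correction $r = R/(2-2R)$ and the Kosambi map function
   ($d = 25\,\ln[(1+2r)/(1-2r)]$). The source workflow does not name its
   map function or interference model; Kosambi with a Markov (no extra
   interference) crossover process is the de facto wheat-mapping standard
   and keeps the simulator and the mapper consistent — this is a declared
   assumption, not a derived fact. Adjacent RF is clamped at 0.49 before
   back-transformation so truncated estimates stay finite.
6. **Orientation** of a linkage group is arbitrary up to reversal; it is
   fixed deterministically (smaller end-marker id at position 0) unless an
   anchor table dictates the arm orientation.

Diagnostics report per-marker distortion (chi-square, p, favoured parent),
the proportion of non-recombinant line × chromosome units (a unit needs at
least two non-missing calls to be evaluable — a single call carries no
recombination information), and the per-group rank correlation between
genetic and physical order, sign-folded because orientation is arbitrary.

## Interval mapping

Scans use Haley–Knott regression on expected dosages rather than a
mixture-model EM: for near-homozygous RILs the two are practically
equivalent, and the regression form is orders of magnitude cheaper inside
permutation and bootstrap loops. Expected dosage at a grid position (1 cM
default step, marker positions always included) conditions on the nearest
non-missing flanking markers under the Markov model with RIL-corrected
recombination; at chromosome ends conditioning degrades to the single
nearest marker, and a line with no calls on a chromosome contributes
dosage 0.

At each position, $LOD = (n/2)\log_{10}(SSE_0/SSE_1)$, identically
$-(n/2)\log_{10}(1-R^2)$. A ceiling of 50 guards degenerate perfect fits;
when the ceiling flattens a peak, the peak position is tie-broken on $R^2$.
The additive effect $a$ is the regression slope — half the difference
between parental homozygote means, signed toward the wild parent — so the
increased-trait-value (ITV) allele is the wild parent's exactly when
$a > 0$. PEV is the model $R^2$ at the peak; the support interval is the
widest contiguous grid region around the peak within 1.5 LOD of it.

* **Thresholds**: per-trait permutation of trait values across lines
  (genotypes fixed); the genome-wide threshold is the empirical
  $(1-\alpha)$ quantile of max-LOD over permutations. Defaults are 1000
  permutations and 500 bootstraps (configurable up to 5000); with 1000
  permutations the Monte-Carlo standard error of the 95% quantile is small
  relative to the ~0.1 LOD spacing of adjacent order statistics. There is
  deliberately no cross-trait multiplicity correction, matching per-trait
  permutation testing practice.
* **Two-linked-QTL model**: a grid search over ordered position pairs at
  least 10 cM apart, retained only when its LOD beats the single-QTL model
  by at least 2. The source workflow names the model but not its selection
  rule; both margins are configurable and these defaults are the package's
  own calibration choice (a ΔLOD of 2 approximates a conventional
  two-degree-of-freedom penalty).
* **Joint two-environment analysis**: environment-specific intercepts and
  slopes; because the regimes are scored on disjoint plots the joint LOD
  is the sum of per-environment LODs, and the environment-specificity tag
  records which per-environment effect clears the threshold on its own.
* **MIM refinement**: each chromosome with a detected QTL is rescanned
  after residualizing the trait on the peak dosages of QTLs on *other*
  chromosomes (never its own), iterating at most 3 rounds or until peaks
  move less than 1 cM. Collinear background dosages are dropped via QR.
* **Bootstrap**: lines resampled with replacement, the chromosome
  rescanned, SD and 2.5/97.5 percentiles of peak position and effect
  reported; degenerate replicates are skipped and counted.

## Classification rules

Significant effects whose 1.5-LOD support intervals overlap on one
chromosome merge (single linkage) into putative QT loci. Three label
families are then pure functions of the member effects:

* **Phenology**: *associated* when the locus affects DP-H itself or shows
  full suppression (an observed effect with no significant df
  counterpart); *plastic* when an effect appears only after heading
  adjustment; *non-plastic* when observed and df effects co-occur and are
  similar. "Similar" is operationalized as the same ITV parent and a
  standardized-effect ratio within $[0.5, 2]$, computed as
  $\sqrt{PEV_{df}/PEV_{obs}}$ — raw additive effects of observed and
  residual traits are not on a common scale, so the comparison uses
  standardized effect sizes. The band is configurable; the source
  describes "rather similar" effects without a criterion. Precedence when
  a multi-trait locus triggers several rules: associated > plastic >
  non-plastic, mirroring the convention that any DP-H-affecting locus is
  heading-associated regardless of its other members.
* **Drought**: *plastic* whenever any member is a d or ddf effect,
  *non-plastic* otherwise. "Full suppression" is a binary
  presence/absence call (observed effect above threshold, df counterpart
  below); there is no partial-suppression category.
* **Strategy** (a set, not a single label, since pleiotropic loci can span
  strategies): *escape* when some trait has a d effect with no ddf
  counterpart; *avoidance* when the locus touches the carbon-isotope
  ratio or leaf rolling; *tolerance* for osmotic potential or chlorophyll
  content. For osmotic potential the resistance-conferring allele is the
  value-*decreasing* one. Loci affecting only yield traits get strategy
  "none": chlorophyll content is sometimes proposed as a general
  drought-adaptive trait, but no formal rule exists for strategy-labelling
  yield-only loci, so none is invented here.

ITV accounting sums, per trait and parent, the PEV of plasticity effects;
when d and ddf effects for one trait co-locate in a locus, only the
higher-PEV member contributes, once.

## Candidate-gene geometry

Physical anchoring consumes a marker → bp table (in a real study, the
product of BLASTing array probes against an assembly — out of scope here)
and a GFF3 annotation. The cM support interval of a locus's highest-LOD
effect converts to bp via the anchored markers flanking each endpoint,
taking the nearest anchor *at or outside* the endpoint: outward widening
guarantees the true support region is covered, at the price of slightly
conservative intervals (how the endpoints were projected in the source is
unstated; this is a declared choice). Genes overlap-query the interval
with 1-based inclusive coordinates; intervals with more than 200 genes are
flagged as excluded from candidate analysis. Gene cM positions are locally
linearly interpolated between flanking anchors using the gene's midpoint
(a symmetric choice; the source does not specify the reference point),
clamping with a flag beyond terminal anchors and warning across local
anchor inversions.

## The synthetic-data generator

Because the original raw data are not deposited, the pipeline ships with a
generator whose defaults encode the study's dimensions: 150 F6 lines, 14
chromosomes totalling ~1750 cM with 1.3 cM skeleton spacing (~1360 loci),
17 traits in five groups, 3 replicates per regime. Genotypes are simulated
as a Markov crossover process on the observed RIL scale (adjacent-marker
recombination $R = 2r/(1+2r)$ with Kosambi $r$); phenotypes are built
causally: DP-H first from its QTLs plus a line-level environmental
deviation (1.5 days by default), then every downstream trait as intercept
+ direct QTL effects (per environment) + a per-trait phenology-coupling
slope times the line's DP-H + Gaussian replicate noise. This coupling is
what makes escape-type architectures constructible: a heading QTL with a
stronger WL effect induces d effects on coupled traits with no ddf
counterpart. Segregation distortion is injected as whole-chromosome
transmission bias (with probability $2s$ a line's chromosome is replaced
by the favoured parent's), which hits the target allele frequency
$0.5+s$ in expectation, preserves within-chromosome co-segregation, and —
as in real wide crosses — simultaneously inflates the non-recombinant
chromosome count. Missingness is uniform at random.

The generator deliberately does **not** simulate epistasis, residual
heterozygosity, genotyping errors beyond missingness, block effects, or
non-Gaussian trait distributions. Passing tests therefore demonstrate that
the estimators recover the truth under the stated statistical structure;
they do not certify behaviour under model misspecification (e.g.
segregation distortion that is locally rather than chromosome-wide
distributed, or heavy-tailed traits such as leaf-rolling scores).

## Numerical choices and problem sizes

Degenerate inputs fail loudly: zero-variance predictors and collinear
predictor pairs (|r| > 1 − 10⁻⁸) in the derivative fits raise errors
naming the offending variable; empty line × environment ANOVA cells are
listed; constant traits scan to a flat zero profile and produce no
effects; pairs of markers with no shared informative line get RF `NA`,
never 0. Correlations require at least 3 complete pairs and return `NA`
for constant columns. All residual fits agree with an independent
normal-equations solve to 10⁻¹⁰ relative error.

The shipped test-suite and analysis scripts run the generator at sizes
chosen to make each property measurable while keeping a desk-scale
runtime: map recovery at n = 1000 lines and 2 cM spacing, scan
calibration with 1000-permutation thresholds checked against 200
independent null scans, power at n = 150 with PEV 0.20 over 50 replicates
with 200-permutation thresholds, and the full 17-trait pipeline at the
study's own dimensions. These sizes are the package's validation design;
the functions themselves accept the full-scale settings (5000 permutations
and bootstraps) unchanged.

## Known limitations

* The two-QTL selection margin, the similarity band of the phenology
  classifier, and the whole-chromosome distortion mechanism are declared
  substitutes for unspecified internals of the original commercial
  software; all are configurable and their defaults are documented above.
* Joint-environment scanning assumes independent errors between regimes
  (disjoint plots); shared spatial structure would make the additive-LOD
  decomposition anticonservative.
* MIM refinement conditions on point estimates of background QTL
  positions and does not propagate their uncertainty.
* The mapper assumes a biparental, effectively homozygous population; no
  outcrossing or heterozygous codes are handled.
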