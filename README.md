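# plastiqtl

Genetic dissection of phenotypic plasticity under water stress in
biparental RIL populations.

When a recombinant-inbred-line (RIL) population is phenotyped under
well-watered (WW) and water-limited (WL) irrigation, the plasticity of a
trait — how a line's stress performance deviates from what its non-stress
performance predicts — is itself a heritable trait, and much of it can be
routed through flowering phenology (drought escape) rather than intrinsic
stress physiology. `plastiqtl` implements an end-to-end pipeline for
separating and mapping these signals. It is written for quantitative
geneticists working on stress adaptation in crops (the shipped defaults
emulate a durum × wild emmer wheat population), but every component is
population-agnostic for two-state homozygous genotypes.

## The model

Plasticity scores are regression residuals on line means. With `V` a
trait's line means, `DH` the line means of heading date (DP-H):

* phenology-adjusted traits (`df`, per environment):
  residuals of `V = β + α·DH`;
* drought plasticity I (`d`): residuals of `V_WL = β + α·V_WW`;
* drought plasticity II (`ddf`): residuals of
  `V_WL = β + α₁·V_WW − α₂·DH_WL`.

A QTL with a `d` effect but no `ddf` effect acts through phenology —
the drought-escape signature. Heritability across regimes is
`h² = σ²_g / (σ²_g + σ²_g×e / e)` with `σ²_g = (MS_gen − MS_g×e)/e` from a
two-way ANOVA. Interval mapping is Haley–Knott regression on expected
dosages (`LOD = (n/2)·log10(SSE₀/SSE₁)`), with permutation-based
genome-wide thresholds, two-linked-QTL and joint two-environment models,
MIM background adjustment and bootstrap support. Co-localized effects are
grouped into loci and classified by presence/absence rules into phenology
categories (associated / plastic / non-plastic), drought-plasticity
categories, and drought-resistance strategies (escape / avoidance /
tolerance). A synthetic-data generator with a known causal architecture
(phenology-mediated effects included) makes the whole pipeline testable.

## Worked example

Simulate a small three-chromosome study with a heading-date QTL whose WL
effect is stronger (its influence on grain yield runs entirely through
phenology) and a WL-specific osmotic-potential QTL; build the map, scan
all trait sets, and classify the loci:

```r
library(plastiqtl)
cfg <- sim_config(n_lines = 150, n_chromosomes = 3,
                  chrom_lengths_cM = c(120, 100, 90),
                  marker_spacing_cM = 2, missing_rate = 0.02, seed = 11)
arch <- trait_architecture(
  traits = data.frame(name = c("DP-H", "GY", "OP"),
                      group = c("phenology", "yield", "DAT"),
                      intercept = c(60, 200, -1.6),
                      noise_sd_ww = c(1, 10, 0.15),
                      noise_sd_wl = c(1, 10, 0.15)),
  qtls = data.frame(trait = c("DP-H", "OP"), chrom = c("chr1", "chr3"),
                    pos_cM = c(40, 30), a_ww = c(-1.5, 0),
                    a_wl = c(-3.5, -0.12)),
  phenology_coupling = c(GY = -4))
st <- simulate_study(cfg, arch)

gmap <- build_genetic_map(st$geno, target_groups = 3)
print(gmap)
#> genetic map: 157 skeleton markers in 3 linkage groups, 293.4 cM total

agg <- aggregate_means(st$phenotypes)
derivs <- derivative_traits(agg$means)
variance_components_heritability(st$phenotypes, "GY")$h2
#> [1] 0.5250407

probs <- genotype_probabilities(gmap$map, st$geno, step_cM = 1)
effects <- scan_all_traits(probs, agg$means, derivs, n_perm = 1000, seed = 2)
effects[, c("trait", "set", "chrom", "pos_cM", "lod", "a", "pev", "itv")]
#>      trait set chrom pos_cM   lod      a    pev itv
#> 1  DP-H_WW obs  LG01   40.0 20.82 -1.377 0.4723  P1
#> 2  DP-H_WL obs  LG01   40.0 50.00 -3.476 0.7864  P1
#> 3    GY_WW obs  LG01   40.0 10.76  4.888 0.2813  P2
#> 5    GY_WL obs  LG01   40.0 38.43 13.672 0.6927  P2
#> 7    OP_WL obs  LG03   29.8 36.46 -0.117 0.6736  P1
#> 8    dDP-H   d  LG01   40.0 14.08 -1.856 0.3509  P1
#> 9      dGY   d  LG01   40.0 19.60 10.055 0.4522  P2
#> 11 dfOP_WL  df  LG03   29.8 36.47 -0.117 0.6736  P1
#> 12     dOP   d  LG03   29.8 34.89 -0.114 0.6574  P1
#> 13   ddfOP ddf  LG03   29.8 34.88 -0.114 0.6573  P1
#> # (three further effects with LOD < 3, trimmed for display)

classify_loci(group_colocalized_effects(effects))[
  , c("locus_id", "n_traits", "phenology", "drought", "strategies")]
#>   locus_id n_traits   phenology     drought strategies
#> 1   LG01.1        2  associated     plastic     escape
#> 2   LG02.1        1  associated non-plastic       none
#> 3   LG02.2        1        <NA>     plastic     escape
#> 4   LG03.1        1 non-plastic     plastic  tolerance
```

Reading the output: the planted heading QTL is recovered at 40 cM with the
wild-parent (P2) allele heading earlier (`a < 0` on DP-H, ITV P1 for the
cultivated parent). Grain yield shows observed effects in both regimes and
a `d` effect (`dGY`, PEV 0.45) but **no** `ddf` effect at that locus —
exactly the escape signature — so the locus classifies as
heading-associated, drought-plastic, strategy escape. The
osmotic-potential QTL appears in the observed-WL, `df`, `d` *and* `ddf`
sets (intrinsic plasticity) and classifies as tolerance; its
value-decreasing allele (here the wild parent's) is the
resistance-conferring one. The two weak LG02 entries are per-trait
threshold false positives (LOD ≈ 2.6 against per-trait thresholds ≈ 2.5),
a realistic feature of per-trait permutation testing.

## The analysis workflow

Numbered drivers under `analysis/` run the full study at its native
dimensions (150 lines, 14 chromosomes, ~1360 skeleton markers, 17 traits)
and write their tables to `results/`:

```sh
Rscript analysis/01_simulate.R         # synthetic study -> results/study/
Rscript analysis/02_derive_traits.R    # line means, df/d/ddf, h², correlations
Rscript analysis/03_build_map.R        # skeleton map + diagnostics
Rscript analysis/04_scan_qtl.R         # multi-set scans, joint-env, 2-QTL, bootstrap
Rscript analysis/05_classify.R         # loci, labels, ITV accounting
Rscript analysis/06_candidate_genes.R  # synthetic anchors/annotation, intervals
```

`run_pipeline(pipeline_config(...), out_dir)` runs the same stages from a
single configuration (YAML via `read_pipeline_config()`) with a
checksummed JSON run report.

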