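#!/usr/bin/env Rscript
# Stage 2 - replicate aggregation, derivative traits, heritability,
# correlations.
#
# Line means per environment feed three regression-residual trait sets:
# phenology-adjusted traits (df, per environment), drought plasticity I
# (d: residuals of WL on WW means) and drought plasticity II (ddf:
# residuals of WL on WW means and WL heading date).  Broad-sense
# heritability across the two regimes comes from the genotype and
# genotype-by-environment ANOVA mean squares.

suppressPackageStartupMessages(library(plastiqtl))

ph <- read_phenotypes_tsv("results/study/phenotypes.tsv")
agg <- aggregate_means(ph)
derivs <- derivative_traits(agg$means)

h2 <- do.call(rbind, lapply(unique(ph$trait), function(tr) {
  v <- variance_components_heritability(ph, tr)
  data.frame(trait = tr, MS_gen = v$MS_gen, MS_gxe = v$MS_gxe,
             sigma2_g = v$sigma2_g, h2 = v$h2, truncated = v$truncated)
}))

obs_wl <- trait_matrix(agg$means[agg$means$env == "WL", ], "mean")
cor_obs <- correlation_analysis(obs_wl, "pearson")
d_mat <- trait_matrix(derivs[derivs$set == "d", ], "value")
cor_d <- correlation_analysis(d_mat, "pearson")

dir.create("results", showWarnings = FALSE)
utils::write.table(agg$means, "results/line_means.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
utils::write.table(derivs, "results/derivative_traits.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
utils::write.table(h2, "results/heritability.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
utils::write.table(cor_obs$edges, "results/correlation_edges_obs_WL.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(cor_d$edges, "results/correlation_edges_plasticityI.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)

message(length(unique(derivs$trait)), " derivative traits from ",
        length(unique(ph$trait)), " observed traits")
message("heritability range: ",
        paste(round(range(h2$h2), 2), collapse = " - "))
message("strongest WL trait correlations:")
print(utils::head(cor_obs$edges, 5), row.names = FALSE)
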