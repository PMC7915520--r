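#!/usr/bin/env Rscript
# Stage 4 - multi-model QTL scans.
#
# Haley-Knott regression on expected dosages at a 1 cM grid for all
# observed and derivative traits, per-trait genome-wide thresholds from
# 1000 permutations (alpha 0.05), MIM background adjustment across
# chromosomes, plus three model demonstrations on the strongest signal:
# joint two-environment analysis, the two-linked-QTL model, and
# bootstrap uncertainty of position and effect.

suppressPackageStartupMessages(library(plastiqtl))

geno <- read_genotypes_tsv("results/study/genotypes.tsv")
gmap_df <- read_map_tsv("results/genetic_map.tsv")
ph <- read_phenotypes_tsv("results/study/phenotypes.tsv")
agg <- aggregate_means(ph)
derivs <- derivative_traits(agg$means)

probs <- genotype_probabilities(gmap_df, geno, step_cM = 1)
effects <- scan_all_traits(probs, agg$means, derivs, n_perm = 1000L,
                           alpha = 0.05, seed = 424242L)
utils::write.table(effects, "results/qtl_effects.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
message(nrow(effects), " significant QTL effects across ",
        length(unique(effects$trait[effects$lod > 0])), " analysis traits")
message("effects by set: ",
        paste(names(table(effects$set)), table(effects$set),
              sep = "=", collapse = ", "))

top <- effects[which.max(effects$lod), ]
message("strongest effect: ", top$trait, " on ", top$chrom, " at ",
        top$pos_cM, " cM (LOD ", round(top$lod, 1), ", PEV ",
        round(top$pev, 2), ", ITV ", top$itv, ")")

# joint two-environment model for the top base trait
y_ww <- line_mean_vector(agg$means, top$base_trait, "WW")
y_wl <- line_mean_vector(agg$means, top$base_trait, "WL")
joint <- scan_joint_environments(probs, y_ww, y_wl)
pk <- which.max(joint$lod)
message("joint-environment peak for ", top$base_trait, ": LOD ",
        round(joint$lod[pk], 1), " (WW ", round(joint$lod_ww[pk], 1),
        " + WL ", round(joint$lod_wl[pk], 1), "), ",
        env_specificity(joint[pk, ], env_threshold = 3))

# two-linked-QTL model on the top chromosome
y_top <- if (top$set == "obs") {
  line_mean_vector(agg$means, top$base_trait, top$env)
} else {
  with(derivs[derivs$trait == top$trait, ], setNames(value, line))
}
two <- scan_two_linked(probs, y_top, top$chrom)
message("two-linked-QTL model on ", top$chrom, ": ",
        if (two$retained) paste0("retained (LOD ", round(two$lod2, 1),
                                 " vs single ", round(two$lod1, 1), ")")
        else "not retained (single-QTL model stands)")

# bootstrap uncertainty of the top peak
bs <- bootstrap_ci(probs, y_top, top$chrom, n_boot = 500L, seed = 99L)
message(sprintf("bootstrap (n=%d ok): position SD %.1f cM [%.0f, %.0f], effect SD %.3f",
                bs$n_ok, bs$sd_pos, bs$ci_pos[1], bs$ci_pos[2], bs$sd_a))
boot_tab <- data.frame(trait = top$trait, chrom = top$chrom,
                       sd_pos_cM = bs$sd_pos, ci_pos_lo = bs$ci_pos[1],
                       ci_pos_hi = bs$ci_pos[2], sd_a = bs$sd_a)
utils::write.table(boot_tab, "results/top_qtl_bootstrap.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
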