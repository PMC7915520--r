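#!/usr/bin/env Rscript
# Stage 1 - simulate the study.
#
# Generates the synthetic RIL drought experiment the rest of the workflow
# analyses: 150 F6 lines from a wide cross, 14 chromosomes with ~1.3 cM
# skeleton marker spacing, 3% missing genotype calls, segregation
# distortion on four chromosomes, and 17 traits (yield, biomass,
# morphology, physiology, phenology) scored in 3 replicates under
# well-watered (WW) and water-limited (WL) regimes.  The QTL architecture
# includes a major heading-date locus with a stronger WL effect whose
# influence on yield is entirely phenology-mediated (drought escape),
# WL-specific physiological QTLs, and equal-effect (non-plastic) loci.

suppressPackageStartupMessages(library(plastiqtl))

out <- "results/study"
cfg <- sim_config(
  n_lines = 150L, n_chromosomes = 14L, marker_spacing_cM = 1.3,
  missing_rate = 0.03,
  distortion = c(0.08, 0, 0, 0.06, 0, 0, 0, 0.1, 0, 0, 0.06, 0, 0, 0),
  replicates_per_env = 3L, seed = 20260923L %% 100000L)
st <- simulate_study(cfg, default_trait_architecture())
paths <- write_simulated_study(st, out)

message("simulated ", nrow(st$geno), " lines x ", ncol(st$geno), " markers, ",
        length(unique(st$phenotypes$trait)), " traits, ",
        nrow(st$phenotypes), " replicate records")
message("true QTL architecture: ", nrow(st$truth$effects),
        " expected (locus, trait) effects")
for (p in paths) message("  wrote ", p)
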