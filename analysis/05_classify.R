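#!/usr/bin/env Rscript
# Stage 5 - locus grouping and rule-based classification.
#
# Co-localized effects (overlapping 1.5-LOD support intervals on one
# chromosome) merge into putative QT loci, which are then labelled:
# phenology relation (associated / plastic / non-plastic from the
# observed-vs-df effect pattern), drought plasticity (any d/ddf member),
# and drought-resistance strategies (escape: d without ddf; avoidance:
# delta13C/LR; tolerance: OP/Chl, resistance = value-decreasing OP
# allele).  Labels are compared against the simulator's truth registry.

suppressPackageStartupMessages(library(plastiqtl))

effects <- utils::read.delim("results/qtl_effects.tsv",
                             stringsAsFactors = FALSE)
loci <- group_colocalized_effects(effects)
classified <- classify_loci(loci)
itv <- itv_accounting(loci)
summary_tab <- summarize_architecture(loci, classified)

utils::write.table(classified, "results/loci_classified.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
utils::write.table(itv, "results/itv_accounting.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
utils::write.table(summary_tab, "results/architecture_summary.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)

message(nrow(classified), " putative QT loci (",
        sum(classified$multi_trait), " multi-trait)")
message("phenology relation: ",
        paste(names(table(classified$phenology)), table(classified$phenology),
              sep = "=", collapse = ", "))
message("drought relation:   ",
        paste(names(table(classified$drought)), table(classified$drought),
              sep = "=", collapse = ", "))
message("strategies: ", paste(sort(unique(unlist(
  strsplit(classified$strategies, ",")))), collapse = ", "))

# plasticity ITV origin: which parent contributes value-increasing alleles
if (nrow(itv)) {
  by_parent <- stats::aggregate(cbind(n, total_pev) ~ itv, itv, sum)
  message("plasticity ITV alleles: ",
          paste(by_parent$itv, " n=", by_parent$n, " sumPEV=",
                round(by_parent$total_pev, 2), collapse = "; ", sep = ""))
}

# against the simulator's expected labels
truth <- jsonlite::read_json("results/study/truth.json", simplifyVector = TRUE)
arch <- default_trait_architecture()
expected <- truth_expected_labels(truth_registry(arch))
message("truth registry expects ", nrow(expected), " loci: ",
        sum(expected$drought == "plastic"), " drought-plastic, ",
        sum(grepl("escape", expected$strategies)), " escape")
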