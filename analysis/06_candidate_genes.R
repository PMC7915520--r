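#!/usr/bin/env Rscript
# Stage 6 - physical anchoring and candidate-gene intervals.
#
# Real studies anchor markers to a genome assembly by BLAST; here a
# SYNTHETIC anchor table and gene annotation stand in for that product:
# marker bp positions follow a smooth monotone cM->bp transform
# (compressed recombination around the chromosome middle emulating
# pericentromeric regions), and genes are placed on a jittered grid.
# The geometry - support-interval -> bp conversion with outward-flanking
# anchors, overlap queries, the >200-genes exclusion rule, and cM
# interpolation of gene positions - is exactly what a real annotation
# would exercise.

suppressPackageStartupMessages(library(plastiqtl))

gmap_df <- read_map_tsv("results/genetic_map.tsv")
effects <- utils::read.delim("results/qtl_effects.tsv",
                             stringsAsFactors = FALSE)
loci <- group_colocalized_effects(effects)

set.seed(606060)
# synthetic anchors: bp = monotone warp of cM with a flat middle
anchors <- do.call(rbind, lapply(split(gmap_df, gmap_df$chrom), function(d) {
  L <- max(d$pos_cM)
  u <- d$pos_cM / max(L, 1)
  bp <- round(6e8 * (u + 0.8 * (u - 0.5)^3 + 0.1))  # slow middle, fast arms
  keep <- sort(sample(nrow(d), ceiling(0.9 * nrow(d))))  # ~90% anchored
  data.frame(marker = d$marker[keep], chrom = d$chrom[1], bp = bp[keep])
}))
utils::write.table(anchors, "results/synthetic_anchors.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

# synthetic gene models: ~1500 genes per chromosome on a jittered grid
genes <- do.call(rbind, lapply(unique(gmap_df$chrom), function(g) {
  starts <- sort(sample.int(7e8, 1500))
  data.frame(gene_id = sprintf("%s_g%04d", g, seq_along(starts)), chrom = g,
             start = starts, end = starts + sample(2e3:2e4, 1500, TRUE),
             annotation = "synthetic gene model")
}))

rows <- list(); gene_lists <- list()
for (lc in loci) {
  pi <- tryCatch(qtl_physical_interval(lc, gmap_df, anchors),
                 error = function(e) NULL)
  if (is.null(pi)) next
  gl <- genes_in_interval(pi, genes, max_genes = 200L)
  rows[[length(rows) + 1L]] <- data.frame(
    locus_id = pi$locus_id, chrom = pi$chrom,
    start_Mbp = pi$start_bp / 1e6, end_Mbp = pi$end_bp / 1e6,
    span_Mbp = (pi$end_bp - pi$start_bp) / 1e6,
    n_genes = gl$n_genes, excluded_from_cg = gl$excluded_from_cg)
  if (!gl$excluded_from_cg && gl$n_genes > 0) {
    cg <- gl$genes
    cg$pos_cM <- vapply(seq_len(nrow(cg)), function(i)
      interpolate_gene_cm(cg[i, ], gmap_df, anchors)$pos_cM, numeric(1))
    cg$locus_id <- pi$locus_id
    gene_lists[[length(gene_lists) + 1L]] <- cg
  }
}
intervals <- do.call(rbind, rows)
utils::write.table(intervals, "results/qtl_physical_intervals.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
if (length(gene_lists))
  utils::write.table(do.call(rbind, gene_lists),
                     "results/candidate_gene_lists.tsv", sep = "\t",
                     quote = FALSE, row.names = FALSE)

message(nrow(intervals), " QTL physical intervals, spanning ",
        round(min(intervals$span_Mbp), 2), " - ",
        round(max(intervals$span_Mbp), 2), " Mbp")
message(sum(intervals$excluded_from_cg),
        " intervals exceed 200 genes and are excluded from CG analysis")
message(sum(!intervals$excluded_from_cg), " intervals carry ",
        if (length(gene_lists)) nrow(do.call(rbind, gene_lists)) else 0,
        " candidate genes with interpolated cM positions")
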