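#' Read gene models from a GFF3 annotation
#'
#' Imports `gene`-type features (1-based inclusive coordinates) from a
#' GFF3 file into a plain gene-model table.
#'
#' @param path GFF3 file
#' @return data.frame: `gene_id`, `chrom`, `start`, `end`, `annotation`
#' @export
read_gene_models_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "gene"]
  ann <- if (!is.null(gr$description)) as.character(gr$description)
  else if (!is.null(gr$Name)) as.character(gr$Name) else NA_character_
  ids <- if (!is.null(gr$ID)) as.character(gr$ID)
  else paste0("gene", seq_along(gr))
  data.frame(gene_id = ids,
             chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             annotation = ann, stringsAsFactors = FALSE)
}

#' Physical interval of a QTL locus
#'
#' Converts the 1.5-LOD cM support interval of the locus's highest-LOD
#' member effect to bp using the anchored markers flanking each
#' endpoint: the nearest anchored marker *at or outside* the endpoint
#' bounds it (conservative outward widening, so the true support region
#' is always covered).  Endpoints beyond all anchors clip to the
#' terminal anchor with a flag.
#'
#' @param locus a `qtl_locus` (see [group_colocalized_effects()])
#' @param map data.frame with `marker`, `chrom`, `pos_cM` for the
#'   locus's chromosome
#' @param anchors anchor table (`marker`, `bp`)
#' @return list: `locus_id`, `chrom`, `start_bp`, `end_bp`,
#'   `flank_markers` (ids bounding each side), `clipped` (logical)
#' @export
qtl_physical_interval <- function(locus, map, anchors) {
  best <- locus$effects[which.max(locus$effects$lod), , drop = FALSE]
  ci <- c(best$ci_lo, best$ci_hi)
  sub <- merge(map[map$chrom == locus$chrom, , drop = FALSE],
               anchors[, c("marker", "bp")], by = "marker")
  if (nrow(sub) < 2L)
    stop("chromosome ", locus$chrom, " has fewer than 2 anchored markers")
  sub <- sub[order(sub$pos_cM), , drop = FALSE]
  clipped <- FALSE
  left <- sub[sub$pos_cM <= ci[1], , drop = FALSE]
  if (nrow(left)) left <- left[nrow(left), ] else { left <- sub[1, ]; clipped <- TRUE }
  right <- sub[sub$pos_cM >= ci[2], , drop = FALSE]
  if (nrow(right)) right <- right[1, ] else { right <- sub[nrow(sub), ]; clipped <- TRUE }
  bp <- range(c(left$bp, right$bp))  # bp orientation may oppose cM order
  list(locus_id = locus$locus_id, chrom = locus$chrom,
       start_bp = bp[1], end_bp = bp[2],
       flank_markers = c(left$marker, right$marker), clipped = clipped)
}

#' Genes overlapping a physical interval
#'
#' Any-overlap query (1-based inclusive coordinates) of the gene-model
#' table against the interval, via [IRanges::findOverlaps()].  Intervals
#' whose gene count exceeds `max_genes` are flagged as excluded from
#' candidate-gene analysis (dense pericentromeric intervals are not
#' informative for candidate search).
#'
#' @param interval list with `chrom`, `start_bp`, `end_bp`
#'   (from [qtl_physical_interval()])
#' @param genes gene-model data.frame (see [read_gene_models_gff3()])
#' @param max_genes exclusion cap (default 200)
#' @return list: `genes` (overlapping rows sorted by start), `n_genes`,
#'   `excluded_from_cg` (logical)
#' @export
genes_in_interval <- function(interval, genes, max_genes = 200L) {
  if (!interval$chrom %in% genes$chrom)
    stop("chromosome ", interval$chrom, " absent from annotation; available: ",
         paste(sort(unique(genes$chrom)), collapse = ", "))
  sub <- genes[genes$chrom == interval$chrom, , drop = FALSE]
  hits <- IRanges::findOverlaps(
    IRanges::IRanges(start = sub$start, end = sub$end),
    IRanges::IRanges(start = interval$start_bp, end = interval$end_bp))
  out <- sub[S4Vectors::queryHits(hits), , drop = FALSE]
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  list(genes = out, n_genes = nrow(out),
       excluded_from_cg = nrow(out) > max_genes)
}

#' Interpolated genetic position of a gene
#'
#' Local linear approximation of genetic distance: the gene midpoint bp
#' is interpolated between the two anchored markers flanking it,
#' `cM = cM_left + (bp - bp_left) / (bp_right - bp_left) *
#' (cM_right - cM_left)`.  Beyond the terminal anchors the position
#' clamps to the terminal cM with a flag; a local inversion
#' (non-monotone anchors) still interpolates but warns.
#'
#' @param gene one gene-model row (`chrom`, `start`, `end`)
#' @param map marker map (`marker`, `chrom`, `pos_cM`)
#' @param anchors anchor table (`marker`, `chrom`, `bp`)
#' @return list: `pos_cM`, `extrapolated` (logical), `flank_markers`
#' @export
interpolate_gene_cm <- function(gene, map, anchors) {
  sub <- merge(map, anchors[anchors$chrom == gene$chrom,
                            c("marker", "bp"), drop = FALSE], by = "marker")
  if (nrow(sub) < 2L)
    stop("chromosome ", gene$chrom, " has fewer than 2 anchored markers")
  sub <- sub[order(sub$bp), , drop = FALSE]
  mid <- (gene$start + gene$end) / 2
  if (mid <= sub$bp[1])
    return(list(pos_cM = sub$pos_cM[1], extrapolated = TRUE,
                flank_markers = sub$marker[1]))
  if (mid >= sub$bp[nrow(sub)])
    return(list(pos_cM = sub$pos_cM[nrow(sub)], extrapolated = TRUE,
                flank_markers = sub$marker[nrow(sub)]))
  i <- findInterval(mid, sub$bp)
  bp_l <- sub$bp[i]; bp_r <- sub$bp[i + 1L]
  if (bp_l == bp_r) stop("flanking anchors share one bp position (degenerate)")
  cm_l <- sub$pos_cM[i]; cm_r <- sub$pos_cM[i + 1L]
  if (i > 1L || i + 1L < nrow(sub)) {
    local <- sub$pos_cM[max(1L, i - 1L):min(nrow(sub), i + 2L)]
    if (is.unsorted(local) && is.unsorted(rev(local)))
      warning("non-monotone local anchors around ", gene$chrom, ":", mid,
              " (possible inversion); interpolation applied anyway")
  }
  list(pos_cM = cm_l + (mid - bp_l) / (bp_r - bp_l) * (cm_r - cm_l),
       extrapolated = FALSE, flank_markers = sub$marker[c(i, i + 1L)])
}
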