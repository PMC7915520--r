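#' Marker quality control for map construction
#'
#' Removes markers failing either of the two skeleton-map entry rules:
#' more than `max_missing` missing calls, or segregation distortion with
#' a 1:1 chi-square statistic above `max_distortion_chi2`.  For
#' near-homozygous RILs the test has one degree of freedom over the two
#' parental classes: `chi2 = (nA - nB)^2 / (nA + nB)`.
#'
#' @param geno character genotype matrix (`A`/`B`/NA)
#' @param max_missing maximum tolerated missing fraction (default 0.10)
#' @param max_distortion_chi2 maximum tolerated distortion chi-square
#'   (default 35)
#' @return the filtered matrix, with a `qc_report` attribute
#'   (data.frame: marker, missing fraction, chi2, removal reason)
#' @export
qc_filter_markers <- function(geno, max_missing = 0.10,
                              max_distortion_chi2 = 35) {
  assert_genotype_matrix(geno)
  stopifnot(max_missing > 0, max_distortion_chi2 > 0)
  miss <- colMeans(is.na(geno))
  nA <- colSums(geno == "A", na.rm = TRUE)
  nB <- colSums(geno == "B", na.rm = TRUE)
  chi2 <- ifelse(nA + nB > 0, (nA - nB)^2 / (nA + nB), 0)
  reason <- rep(NA_character_, ncol(geno))
  reason[miss > max_missing] <- "missing"
  reason[is.na(reason) & chi2 > max_distortion_chi2] <- "distortion"
  report <- data.frame(marker = colnames(geno), missing = miss, chi2 = chi2,
                       removed = reason, stringsAsFactors = FALSE,
                       row.names = NULL)
  keep <- is.na(reason)
  if (!any(keep)) stop("marker QC removed every marker")
  out <- geno[, keep, drop = FALSE]
  attr(out, "qc_report") <- report
  out
}

#' Pairwise recombination-fraction matrix
#'
#' For every marker pair, RF = recombinant lines / informative lines,
#' where a line is informative when both calls are non-missing.  Raw
#' fractions above 0.5 are truncated to 0.5 (the raw value is kept in
#' `rf_raw`).  Pairs with no informative line get `NA`, not 0.
#'
#' @param geno character genotype matrix
#' @return object of class `rf_matrix`: list with `rf` (truncated),
#'   `rf_raw`, and `n_inf` (informative-line counts), all p x p
#' @export
estimate_rf_matrix <- function(geno) {
  assert_genotype_matrix(geno)
  M <- geno_to_dosage(geno)
  M[is.na(M)] <- 0
  N <- crossprod(M != 0)          # informative lines per pair
  S <- crossprod(M)               # matches minus mismatches
  rec <- (N - S) / 2
  rf_raw <- ifelse(N > 0, rec / N, NA_real_)
  diag(rf_raw) <- 0
  structure(list(rf = pmin(rf_raw, 0.5), rf_raw = rf_raw, n_inf = N),
            class = "rf_matrix")
}

#' Bin fully co-segregating markers and pick skeleton representatives
#'
#' Markers at RF 0 (identical on their shared informative lines) are
#' merged into bins by single linkage; each bin is represented by the
#' member with the least missing data (ties broken by the
#' lexicographically smallest identifier), the others become satellites.
#'
#' @param geno character genotype matrix
#' @param rf an [estimate_rf_matrix()] result for `geno`
#' @return list with `skeleton_geno` (genotypes restricted to skeleton
#'   markers) and `bins` (data.frame: `marker`, `skeleton`)
#' @export
bin_skeleton_markers <- function(geno, rf) {
  stopifnot(inherits(rf, "rf_matrix"))
  p <- ncol(geno)
  stopifnot(identical(colnames(geno), colnames(rf$rf)) || p == ncol(rf$rf))
  idx <- which(rf$rf == 0 & rf$n_inf > 0 & upper.tri(rf$rf), arr.ind = TRUE)
  comp <- connected_components(p, idx[, 1], idx[, 2])
  miss <- colMeans(is.na(geno))
  ids <- colnames(geno)
  skeleton_of <- character(p)
  for (cc in unique(comp)) {
    members <- which(comp == cc)
    best <- members[order(miss[members], ids[members])][1]
    skeleton_of[members] <- ids[best]
  }
  bins <- data.frame(marker = ids, skeleton = skeleton_of,
                     stringsAsFactors = FALSE)
  skeleton_ids <- unique(skeleton_of)
  list(skeleton_geno = geno[, skeleton_ids, drop = FALSE], bins = bins)
}

# Linkage-group labels by decreasing marker count
lg_names <- function(sizes) sprintf("LG%02d", seq_along(sizes))

#' Cluster skeleton markers into linkage groups
#'
#' Single-linkage clustering at `RF <= rf_threshold` (connected
#' components of the thresholded RF graph).  If more groups emerge than
#' `target_groups`, the pair of groups with the smallest end-to-end RF
#' (RF between their terminal markers after ordering) is merged
#' iteratively until the target is reached.  Groups are named `LG01`,
#' `LG02`, ... by decreasing marker count.
#'
#' @param skeleton_geno genotype matrix restricted to skeleton markers
#' @param rf [estimate_rf_matrix()] of `skeleton_geno`
#' @param rf_threshold linkage threshold (default 0.2)
#' @param target_groups desired number of groups (chromosome number);
#'   `NULL` to skip merging
#' @return named character vector: linkage group per marker
#' @export
cluster_linkage_groups <- function(skeleton_geno, rf, rf_threshold = 0.2,
                                   target_groups = NULL) {
  stopifnot(inherits(rf, "rf_matrix"),
            rf_threshold > 0, rf_threshold < 0.5)
  p <- ncol(skeleton_geno)
  ids <- colnames(skeleton_geno)
  idx <- which(rf$rf <= rf_threshold & !is.na(rf$rf) & upper.tri(rf$rf),
               arr.ind = TRUE)
  comp <- connected_components(p, idx[, 1], idx[, 2])
  groups <- split(seq_len(p), comp)
  if (!is.null(target_groups)) {
    if (length(groups) < target_groups)
      warning("only ", length(groups), " natural linkage groups at RF <= ",
              rf_threshold, "; fewer than target ", target_groups,
              " (no forced splits)")
    while (length(groups) > target_groups) {
      ends <- lapply(groups, function(g) {
        if (length(g) == 1L) c(g, g)
        else {
          o <- order_markers_greedy(rf$rf[g, g, drop = FALSE])
          c(g[o[1]], g[o[length(o)]])
        }
      })
      best <- c(Inf, NA, NA)
      for (i in seq_along(groups)[-length(groups)])
        for (j in (i + 1):length(groups)) {
          v <- min(rf$rf[ends[[i]], ends[[j]]], na.rm = TRUE)
          if (is.finite(v) && v < best[1]) best <- c(v, i, j)
        }
      if (!is.finite(best[1])) break  # disconnected beyond repair
      i <- best[2]; j <- best[3]
      groups[[i]] <- c(groups[[i]], groups[[j]])
      groups[[j]] <- NULL
    }
  }
  sizes <- vapply(groups, length, integer(1))
  groups <- groups[order(-sizes)]
  out <- character(p)
  for (g_i in seq_along(groups)) out[groups[[g_i]]] <- sprintf("LG%02d", g_i)
  stats::setNames(out, ids)
}

# Greedy nearest-neighbour order over an RF submatrix, seeded at the most
# peripheral marker (largest total RF to the rest).  NA treated as 0.5.
order_markers_greedy <- function(rfm) {
  k <- nrow(rfm)
  if (k <= 2L) return(seq_len(k))
  rfm[is.na(rfm)] <- 0.5
  start <- which.max(rowSums(rfm))
  ord <- integer(k); used <- logical(k)
  ord[1] <- start; used[start] <- TRUE
  for (i in 2:k) {
    cand <- which(!used)
    nxt <- cand[which.min(rfm[ord[i - 1L], cand])]
    ord[i] <- nxt; used[nxt] <- TRUE
  }
  ord
}

# 2-opt improvement of a path order under the sum-of-adjacent-RF objective.
order_markers_2opt <- function(rfm, ord) {
  k <- length(ord)
  if (k <= 3L) return(ord)
  rfm[is.na(rfm)] <- 0.5
  improved <- TRUE
  while (improved) {
    improved <- FALSE
    for (i in 1:(k - 1L)) {
      for (j in (i + 1L):k) {
        # reverse segment [i, j]
        left <- if (i > 1L) rfm[ord[i - 1L], ord[i]] else 0
        right <- if (j < k) rfm[ord[j], ord[j + 1L]] else 0
        new_left <- if (i > 1L) rfm[ord[i - 1L], ord[j]] else 0
        new_right <- if (j < k) rfm[ord[i], ord[j + 1L]] else 0
        if (new_left + new_right < left + right - 1e-12) {
          ord[i:j] <- rev(ord[i:j])
          improved <- TRUE
        }
      }
    }
  }
  ord
}

#' Order markers within a linkage group and assign cM positions
#'
#' The order minimizing the sum of adjacent RF is sought by greedy
#' nearest-neighbour construction from the most peripheral marker,
#' followed by 2-opt improvement passes until no reversal gains.
#' Adjacent cM distances are the Kosambi transform of the RIL-corrected
#' adjacent RF; positions are cumulative from 0.  Orientation is
#' arbitrary up to reversal and is fixed deterministically: the end whose
#' marker has the lexicographically smaller identifier becomes position 0
#' (an anchor table, when supplied downstream, overrides this).
#'
#' @param markers character vector of skeleton marker ids in the group
#' @param rf [estimate_rf_matrix()] covering those markers
#' @return data.frame: `marker`, `order`, `pos_cM`
#' @export
order_and_space_markers <- function(markers, rf) {
  stopifnot(inherits(rf, "rf_matrix"), length(markers) >= 1L)
  if (length(markers) == 1L)
    return(data.frame(marker = markers, order = 1L, pos_cM = 0,
                      stringsAsFactors = FALSE))
  rfm <- rf$rf[markers, markers, drop = FALSE]
  ord <- order_markers_2opt(rfm, order_markers_greedy(rfm))
  if (markers[ord[length(ord)]] < markers[ord[1]]) ord <- rev(ord)
  adj <- rfm[cbind(ord[-length(ord)], ord[-1])]
  adj[is.na(adj)] <- 0.49
  pos <- c(0, cumsum(ril_R_to_cM(adj)))
  data.frame(marker = markers[ord], order = seq_along(ord), pos_cM = pos,
             stringsAsFactors = FALSE)
}

#' Build a skeleton genetic map from a genotype matrix
#'
#' Full map-construction workflow: marker QC, co-segregation binning,
#' linkage-group clustering at the RF threshold, per-group ordering and
#' cM assignment.
#'
#' @param geno character genotype matrix
#' @param max_missing,max_distortion_chi2 QC thresholds
#'   (see [qc_filter_markers()])
#' @param rf_threshold linkage-group clustering threshold (default 0.2)
#' @param target_groups chromosome number to merge down to (default 14)
#' @return object of class `genetic_map`: list with `map` (data.frame:
#'   `marker`, `chrom`, `order`, `pos_cM`), `bins`, `groups` (per-group
#'   marker count and length), and `qc_report`
#' @export
build_genetic_map <- function(geno, max_missing = 0.10,
                              max_distortion_chi2 = 35,
                              rf_threshold = 0.2, target_groups = 14L) {
  kept <- qc_filter_markers(geno, max_missing, max_distortion_chi2)
  qc_report <- attr(kept, "qc_report")
  rf_all <- estimate_rf_matrix(kept)
  binned <- bin_skeleton_markers(kept, rf_all)
  skel <- binned$skeleton_geno
  rf <- estimate_rf_matrix(skel)
  lg <- cluster_linkage_groups(skel, rf, rf_threshold, target_groups)
  per_group <- lapply(sort(unique(lg)), function(g) {
    o <- order_and_space_markers(names(lg)[lg == g], rf)
    data.frame(marker = o$marker, chrom = g, order = o$order,
               pos_cM = o$pos_cM, stringsAsFactors = FALSE)
  })
  map <- do.call(rbind, per_group)
  groups <- do.call(rbind, lapply(per_group, function(d)
    data.frame(chrom = d$chrom[1], n_markers = nrow(d),
               length_cM = max(d$pos_cM), stringsAsFactors = FALSE)))
  structure(list(map = map, bins = binned$bins, groups = groups,
                 qc_report = qc_report),
            class = "genetic_map")
}

#' @export
print.genetic_map <- function(x, ...) {
  cat("genetic map:", nrow(x$map), "skeleton markers in",
      nrow(x$groups), "linkage groups,",
      sprintf("%.1f cM total\n", sum(x$groups$length_cM)))
  invisible(x)
}

#' Map and population diagnostics
#'
#' Per-marker segregation-distortion test (1:1 chi-square over the two
#' homozygous classes, df = 1) with counts of significantly distorted
#' loci split by favoured parent, and the non-recombinant chromosome
#' screen: a line x linkage-group unit is non-recombinant when it has at
#' least two non-missing calls and all of them are identical; units with
#' fewer than two calls are excluded from the denominator.
#'
#' @param geno character genotype matrix covering the mapped markers
#' @param map data.frame with `marker`, `chrom` (e.g. `gmap$map`)
#' @param alpha significance level for the distortion test (default 0.05)
#' @return list with `marker_distortion` (per-marker counts, chi2, p,
#'   favoured parent), `distorted_counts` (by favoured parent),
#'   `nonrecombinant` (per-unit flags), `prop_nonrecombinant`,
#'   `n_units_evaluated`, `n_units_total`
#' @export
map_diagnostics <- function(geno, map, alpha = 0.05) {
  stopifnot(all(map$marker %in% colnames(geno)))
  geno <- geno[, map$marker, drop = FALSE]
  nA <- colSums(geno == "A", na.rm = TRUE)
  nB <- colSums(geno == "B", na.rm = TRUE)
  chi2 <- ifelse(nA + nB > 0, (nA - nB)^2 / (nA + nB), 0)
  p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  favoured <- ifelse(nA > nB, "P1", ifelse(nB > nA, "P2", NA_character_))
  distorted <- p <= alpha & !is.na(favoured)
  marker_distortion <- data.frame(
    marker = map$marker, chrom = map$chrom, n_P1 = nA, n_P2 = nB,
    chi2 = chi2, p = p, favoured = favoured, distorted = distorted,
    stringsAsFactors = FALSE, row.names = NULL)
  distorted_counts <- c(P1 = sum(distorted & favoured == "P1", na.rm = TRUE),
                        P2 = sum(distorted & favoured == "P2", na.rm = TRUE))

  groups <- unique(map$chrom)
  units <- expand.grid(line = rownames(geno), chrom = groups,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  flags <- logical(nrow(units)); eval_ok <- logical(nrow(units))
  k <- 0L
  for (g in groups) {
    sub <- geno[, map$marker[map$chrom == g], drop = FALSE]
    n_calls <- rowSums(!is.na(sub))
    nB_line <- rowSums(sub == "B", na.rm = TRUE)
    same <- nB_line == 0L | nB_line == n_calls
    rows <- k + seq_len(nrow(geno))
    eval_ok[rows] <- n_calls >= 2L
    flags[rows] <- same & n_calls >= 2L
    k <- k + nrow(geno)
  }
  units$evaluated <- eval_ok
  units$nonrecombinant <- flags
  list(marker_distortion = marker_distortion,
       distorted_counts = distorted_counts,
       prop_distorted = mean(distorted),
       nonrecombinant = units,
       prop_nonrecombinant = sum(flags) / sum(eval_ok),
       n_units_evaluated = sum(eval_ok),
       n_units_total = nrow(units))
}

#' Concordance of genetic and physical marker order
#'
#' Per linkage group, the Spearman rank correlation between the genetic
#' order index and the physical bp position of anchored markers,
#' sign-folded (absolute value) because group orientation is arbitrary.
#' Groups with fewer than 3 anchored markers are skipped with a warning.
#'
#' @param map data.frame with `marker`, `chrom`, `order`
#' @param anchors anchor table (`marker`, `bp`; see [read_anchors_tsv()])
#' @return data.frame: `chrom`, `n_anchored`, `rank_cor`
#' @export
physical_concordance <- function(map, anchors) {
  out <- list()
  for (g in unique(map$chrom)) {
    sub <- map[map$chrom == g, , drop = FALSE]
    m <- merge(sub, anchors[, c("marker", "bp")], by = "marker")
    if (nrow(m) < 3L) {
      warning("linkage group ", g, " has fewer than 3 anchored markers; skipped")
      next
    }
    rc <- abs(stats::cor(m$order, m$bp, method = "spearman"))
    out[[g]] <- data.frame(chrom = g, n_anchored = nrow(m), rank_cor = rc,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
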