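#' Conditional expected dosages on an evaluation grid
#'
#' Haley-Knott machinery: at each grid position the expected genotype
#' dosage in `[-1, +1]` conditional on the nearest non-missing flanking
#' marker calls, under the Markov crossover model with RIL-corrected
#' recombination between marker and position.  At a non-missing marker
#' the dosage equals the observed call; beyond the outermost non-missing
#' marker, conditioning is on that single marker; a line with no call on
#' a chromosome gets dosage 0 (uninformative).
#'
#' @param map data.frame with `marker`, `chrom`, `pos_cM` (ordered
#'   within chromosome)
#' @param geno character genotype matrix covering the mapped markers
#' @param step_cM evaluation grid step (default 1)
#' @return object of class `geno_probs`: list with `grid` (data.frame
#'   `chrom`, `pos_cM`), `dosage` (lines x grid matrix), `step_cM`
#' @export
genotype_probabilities <- function(map, geno, step_cM = 1) {
  stopifnot(all(map$marker %in% colnames(geno)), step_cM > 0)
  dos_obs <- geno_to_dosage(geno[, map$marker, drop = FALSE])
  n <- nrow(dos_obs)
  grids <- list(); mats <- list()
  for (g in unique(map$chrom)) {
    sel <- which(map$chrom == g)
    sel <- sel[order(map$pos_cM[sel])]
    mpos <- map$pos_cM[sel]
    grid <- sort(unique(c(seq(0, max(mpos), by = step_cM), mpos)))
    D <- matrix(0, n, length(grid))
    sub <- dos_obs[, sel, drop = FALSE]
    for (l in seq_len(n)) {
      ok <- which(!is.na(sub[l, ]))
      if (!length(ok)) next  # uninformative line on this chromosome
      q <- mpos[ok]; gcall <- sub[l, ok]
      li <- findInterval(grid, q)
      at <- li >= 1L & grid == q[pmax(li, 1L)]
      D[l, at] <- gcall[li[at]]
      both <- !at & li >= 1L & li < length(q)
      if (any(both)) {
        i <- li[both]
        R1 <- ril_cM_to_R(grid[both] - q[i])
        R2 <- ril_cM_to_R(q[i + 1L] - grid[both])
        # P(x = +1 | left), P(right | x = +-1) under the Markov chain
        a <- ifelse(gcall[i] == 1, 1 - R1, R1)
        b_plus <- ifelse(gcall[i + 1L] == 1, 1 - R2, R2)
        b_minus <- ifelse(gcall[i + 1L] == 1, R2, 1 - R2)
        p_plus <- a * b_plus / (a * b_plus + (1 - a) * b_minus)
        D[l, both] <- 2 * p_plus - 1
      }
      left_only <- !at & li == length(q)
      if (any(left_only)) {
        R1 <- ril_cM_to_R(grid[left_only] - q[length(q)])
        D[l, left_only] <- gcall[length(q)] * (1 - 2 * R1)
      }
      right_only <- li == 0L
      if (any(right_only)) {
        R2 <- ril_cM_to_R(q[1L] - grid[right_only])
        D[l, right_only] <- gcall[1L] * (1 - 2 * R2)
      }
    }
    grids[[g]] <- data.frame(chrom = g, pos_cM = grid,
                             stringsAsFactors = FALSE)
    mats[[g]] <- D
  }
  grid <- do.call(rbind, grids)
  dosage <- do.call(cbind, mats)
  rownames(dosage) <- rownames(geno)
  structure(list(grid = grid, dosage = dosage, step_cM = step_cM),
            class = "geno_probs")
}

# LOD of a single-marker regression from R^2: (n/2) log10(SSE0/SSE1).
lod_from_r2 <- function(n, r2, cap = 50) {
  pmin(-(n / 2) * log10(pmax(1 - r2, 10^(-2 * cap / n))), cap)
}

# Per-position slope, R^2 and LOD of y on each dosage column.
# Returns a data.frame aligned with probs$grid.
hk_profile <- function(probs, y, cap = 50) {
  keep <- !is.na(y)
  n <- sum(keep)
  D <- probs$dosage[keep, , drop = FALSE]
  yv <- y[keep]
  yc <- yv - mean(yv)
  ss_y <- sum(yc^2)
  Dc <- sweep(D, 2L, colMeans(D))
  ss_d <- colSums(Dc^2)
  sxy <- as.vector(crossprod(Dc, yc))
  a <- ifelse(ss_d > 0, sxy / ss_d, 0)
  r2 <- if (ss_y > 0) ifelse(ss_d > 0, sxy^2 / (ss_d * ss_y), 0) else rep(0, ncol(D))
  r2 <- pmin(r2, 1)
  data.frame(chrom = probs$grid$chrom, pos_cM = probs$grid$pos_cM,
             lod = lod_from_r2(n, r2, cap), a = a, r2 = r2, n = n,
             stringsAsFactors = FALSE)
}

#' Single-QTL genome scan (Haley-Knott regression)
#'
#' At every grid position, least-squares regression of the trait on the
#' expected dosage; `LOD = (n/2) log10(SSE0/SSE1)`, capped at `cap` for
#' degenerate perfect fits.  The per-position additive effect `a` is the
#' regression slope (half the difference between parental homozygote
#' means, sign toward the wild parent P2).
#'
#' @param probs a [genotype_probabilities()] object
#' @param y named numeric trait values (line means); `NA` lines dropped
#' @param cap LOD ceiling (default 50)
#' @return object of class `scan_profile`: data.frame `chrom`, `pos_cM`,
#'   `lod`, `a`, `r2`, `n`, with attribute `model = "single"`
#' @export
scan_single <- function(probs, y, cap = 50) {
  stopifnot(inherits(probs, "geno_probs"))
  y <- align_trait(probs, y)
  if (sum(!is.na(y)) < 10L) stop("need >= 10 informative lines")
  if (stats::sd(y, na.rm = TRUE) == 0) {
    prof <- data.frame(chrom = probs$grid$chrom, pos_cM = probs$grid$pos_cM,
                       lod = 0, a = 0, r2 = 0, n = sum(!is.na(y)),
                       stringsAsFactors = FALSE)
  } else {
    prof <- hk_profile(probs, y, cap)
  }
  structure(prof, class = c("scan_profile", "data.frame"), model = "single")
}

# Match a named trait vector to the probability object's line order.
align_trait <- function(probs, y) {
  lines <- rownames(probs$dosage)
  if (!is.null(names(y))) {
    stats::setNames(y[lines], lines)
  } else {
    stopifnot(length(y) == nrow(probs$dosage))
    stats::setNames(y, lines)
  }
}

#' Genome-wide permutation threshold
#'
#' Trait values are permuted across lines with genotypes fixed; the
#' genome-wide maximum LOD is recorded for each permutation and the
#' threshold is the empirical `(1 - alpha)` quantile of that sample.
#'
#' @param probs a [genotype_probabilities()] object
#' @param y named trait values
#' @param n_perm number of permutations (>= 100)
#' @param alpha genome-wide significance level (default 0.05)
#' @param seed RNG seed (reproducible thresholds)
#' @param cap LOD ceiling
#' @return object of class `perm_threshold`: list with `threshold`,
#'   `alpha`, `n_perm`, `max_lods` (the permuted sample)
#' @export
permutation_threshold <- function(probs, y, n_perm = 1000L, alpha = 0.05,
                                  seed = 1L, cap = 50) {
  stopifnot(n_perm >= 100L, alpha > 0, alpha <= 1)
  y <- align_trait(probs, y)
  keep <- !is.na(y)
  n <- sum(keep)
  D <- probs$dosage[keep, , drop = FALSE]
  Dc <- sweep(D, 2L, colMeans(D))
  ss_d <- colSums(Dc^2)
  set.seed(seed)
  yv <- y[keep]
  Y <- vapply(seq_len(n_perm), function(i) sample(yv), numeric(n))
  Yc <- sweep(Y, 2L, colMeans(Y))
  ss_y <- colSums(Yc^2)
  Sxy <- crossprod(Dc, Yc)                       # positions x permutations
  r2 <- sweep(Sxy^2, 1L, pmax(ss_d, 1e-300), "/")
  r2 <- sweep(r2, 2L, pmax(ss_y, 1e-300), "/")
  max_lods <- lod_from_r2(n, pmin(apply(r2, 2L, max), 1), cap)
  qi <- stats::quantile(max_lods, probs = 1 - alpha, type = 1, names = FALSE)
  structure(list(threshold = qi, alpha = alpha, n_perm = n_perm,
                 max_lods = max_lods), class = "perm_threshold")
}

#' Summarize significant QTL effects from a scan profile
#'
#' Per chromosome, the peak is reported when its LOD exceeds the
#' threshold; the support interval is the widest contiguous grid region
#' around the peak with `LOD >= peak - drop` (1.5 by default), clipped
#' at chromosome ends; PEV is the model R-squared at the peak; the
#' increased-trait-value (ITV) parent is P2 (wild) when `a > 0`, P1
#' otherwise.
#'
#' @param profile a [scan_single()] (or joint) profile
#' @param threshold numeric LOD threshold or a `perm_threshold`
#' @param drop LOD support-interval drop (default 1.5)
#' @return data.frame, one row per significant chromosome peak: `chrom`,
#'   `pos_cM`, `lod`, `a`, `pev`, `itv`, `ci_lo`, `ci_hi`, `n`
#' @export
effect_summary <- function(profile, threshold, drop = 1.5) {
  thr <- if (inherits(threshold, "perm_threshold")) threshold$threshold
  else threshold
  out <- list()
  for (g in unique(profile$chrom)) {
    sub <- profile[profile$chrom == g, , drop = FALSE]
    pk <- which.max(sub$lod)
    # the LOD ceiling can flatten a perfect-fit peak; break ties on R^2
    ties <- which(sub$lod == sub$lod[pk])
    if (length(ties) > 1L && !is.null(sub$r2)) pk <- ties[which.max(sub$r2[ties])]
    if (sub$lod[pk] < thr || sub$lod[pk] <= 0) next
    keep_lvl <- sub$lod[pk] - drop
    lo <- pk; while (lo > 1L && sub$lod[lo - 1L] >= keep_lvl) lo <- lo - 1L
    hi <- pk; while (hi < nrow(sub) && sub$lod[hi + 1L] >= keep_lvl) hi <- hi + 1L
    out[[g]] <- data.frame(
      chrom = g, pos_cM = sub$pos_cM[pk], lod = sub$lod[pk], a = sub$a[pk],
      pev = sub$r2[pk], itv = if (sub$a[pk] > 0) "P2" else "P1",
      ci_lo = sub$pos_cM[lo], ci_hi = sub$pos_cM[hi], n = sub$n[pk],
      stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(chrom = character(), pos_cM = numeric(),
                      lod = numeric(), a = numeric(), pev = numeric(),
                      itv = character(), ci_lo = numeric(), ci_hi = numeric(),
                      n = integer(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Two-linked-QTL scan on one chromosome
#'
#' Grid search over ordered position pairs at least `min_sep_cM` apart,
#' jointly fitting the trait on both dosages.  The two-QTL model is
#' retained only when its LOD exceeds the best single-QTL LOD on the
#' chromosome by `delta_lod` (default 2).
#'
#' @param probs a [genotype_probabilities()] object
#' @param y named trait values
#' @param chrom chromosome to scan
#' @param min_sep_cM minimum separation of the two positions (default 10)
#' @param delta_lod retention margin over the single-QTL model (default 2)
#' @param cap LOD ceiling
#' @return list: `retained` (logical), `lod2`, `lod1`, `positions`
#'   (length 2), `effects` (a1, a2), `single` (the single-QTL peak row)
#' @export
scan_two_linked <- function(probs, y, chrom, min_sep_cM = 10, delta_lod = 2,
                            cap = 50) {
  y <- align_trait(probs, y)
  on_chr <- probs$grid$chrom == chrom
  pos <- probs$grid$pos_cM[on_chr]
  single <- scan_single(probs, y, cap)
  s_sub <- single[single$chrom == chrom, , drop = FALSE]
  pk <- which.max(s_sub$lod)
  single_peak <- s_sub[pk, , drop = FALSE]
  if (max(pos) - min(pos) < 20 || sum(on_chr) < 4L) {
    warning("chromosome ", chrom, " too short for a two-QTL grid; ",
            "falling back to the single-QTL model")
    return(list(retained = FALSE, lod2 = NA_real_, lod1 = single_peak$lod,
                positions = single_peak$pos_cM, effects = single_peak$a,
                single = single_peak))
  }
  keep <- !is.na(y)
  n <- sum(keep)
  D <- probs$dosage[keep, on_chr, drop = FALSE]
  yv <- y[keep]; yc <- yv - mean(yv)
  ss_y <- sum(yc^2)
  Dc <- sweep(D, 2L, colMeans(D))
  G <- crossprod(Dc)
  b <- as.vector(crossprod(Dc, yc))
  pairs <- which(outer(pos, pos, function(a2, b2) b2 - a2 >= min_sep_cM),
                 arr.ind = TRUE)
  best <- list(sse = Inf, i = NA, j = NA, beta = c(NA, NA))
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    S <- G[c(i, j), c(i, j)]
    if (abs(det(S)) < 1e-10) next
    beta <- solve(S, b[c(i, j)])
    sse <- ss_y - sum(beta * b[c(i, j)])
    if (sse < best$sse) best <- list(sse = sse, i = i, j = j, beta = beta)
  }
  lod2 <- if (is.finite(best$sse))
    min((n / 2) * log10(ss_y / max(best$sse, ss_y * 10^(-2 * cap / n))), cap)
  else NA_real_
  retained <- is.finite(lod2) && lod2 >= single_peak$lod + delta_lod
  list(retained = retained, lod2 = lod2, lod1 = single_peak$lod,
       positions = c(pos[best$i], pos[best$j]), effects = best$beta,
       single = single_peak)
}

#' Joint two-environment scan (multi-environment approach)
#'
#' At every position, environment-specific intercepts and dosage effects
#' are fitted; because the two environments are scored on disjoint
#' observations, the joint LOD against the no-QTL-in-either-environment
#' null is the sum of the per-environment LOD contributions.  The
#' environment-specificity tag records which per-environment effect is
#' individually significant at `env_threshold`.
#'
#' @param probs a [genotype_probabilities()] object
#' @param y_ww,y_wl named trait line means per environment
#' @param cap LOD ceiling (applied per environment)
#' @return object of class `scan_profile` with columns `chrom`,
#'   `pos_cM`, `lod` (joint), `lod_ww`, `lod_wl`, `a_ww`, `a_wl`, `r2`,
#'   `n`; attribute `model = "joint-env"`
#' @export
scan_joint_environments <- function(probs, y_ww, y_wl, cap = 50) {
  has_ww <- sum(!is.na(align_trait(probs, y_ww))) >= 10L
  has_wl <- sum(!is.na(align_trait(probs, y_wl))) >= 10L
  if (!has_ww && !has_wl) stop("both environments lack informative lines")
  if (!has_ww || !has_wl) {
    one <- if (has_ww) y_ww else y_wl
    prof <- scan_single(probs, one, cap)
    attr(prof, "model") <- "joint-env(degraded-single)"
    return(prof)
  }
  p_ww <- hk_profile(probs, align_trait(probs, y_ww), cap)
  p_wl <- hk_profile(probs, align_trait(probs, y_wl), cap)
  prof <- data.frame(chrom = p_ww$chrom, pos_cM = p_ww$pos_cM,
                     lod = p_ww$lod + p_wl$lod,
                     lod_ww = p_ww$lod, lod_wl = p_wl$lod,
                     a_ww = p_ww$a, a_wl = p_wl$a,
                     a = (p_ww$a + p_wl$a) / 2,
                     r2 = pmax(p_ww$r2, p_wl$r2),
                     n = p_ww$n + p_wl$n, stringsAsFactors = FALSE)
  structure(prof, class = c("scan_profile", "data.frame"), model = "joint-env")
}

#' Environment-specificity tag for a joint-scan peak
#'
#' @param profile_row one row of a joint [scan_joint_environments()]
#'   profile (the peak)
#' @param env_threshold per-environment LOD significance threshold
#' @return `"WW-specific"`, `"WL-specific"`, `"both"`, or `"none"`
#' @export
env_specificity <- function(profile_row, env_threshold) {
  ww <- profile_row$lod_ww >= env_threshold
  wl <- profile_row$lod_wl >= env_threshold
  if (ww && wl) "both" else if (ww) "WW-specific"
  else if (wl) "WL-specific" else "none"
}

#' Multiple-interval-mapping refinement
#'
#' Re-scans each chromosome carrying a detected QTL after residualizing
#' the trait on the peak dosages of detected QTLs on *other*
#' chromosomes, reducing residual variation.  Iterates until peak
#' positions move less than 1 cM or `max_iter` rounds.  Collinear
#' background dosages are dropped via the QR decomposition.
#'
#' @param effects data.frame of detected effects (`chrom`, `pos_cM`)
#' @param probs a [genotype_probabilities()] object
#' @param y named trait values
#' @param max_iter maximum refinement rounds (default 3)
#' @param cap LOD ceiling
#' @return `effects` with refreshed `pos_cM`, plus columns `lod_mim`,
#'   `a_mim`, `pev_mim` alongside the originals
#' @export
mim_refine <- function(effects, probs, y, max_iter = 3L, cap = 50) {
  if (nrow(effects) == 0L) return(effects)
  y <- align_trait(probs, y)
  keep <- !is.na(y)
  eff <- effects
  eff$lod_mim <- eff$lod; eff$a_mim <- eff$a; eff$pev_mim <- eff$pev
  dosage_at <- function(chrom, pos) {
    idx <- which(probs$grid$chrom == chrom)
    idx[which.min(abs(probs$grid$pos_cM[idx] - pos))]
  }
  for (iter in seq_len(max_iter)) {
    moved <- 0
    for (r in seq_len(nrow(eff))) {
      others <- eff[eff$chrom != eff$chrom[r], , drop = FALSE]
      if (nrow(others) == 0L) next  # nothing to adjust for
      cols <- vapply(seq_len(nrow(others)),
                     function(k) dosage_at(others$chrom[k], others$pos_cM[k]),
                     integer(1))
      X <- probs$dosage[keep, cols, drop = FALSE]
      qrX <- qr(cbind(1, X))
      if (qrX$rank < ncol(X) + 1L) {
        ok_cols <- qrX$pivot[seq_len(qrX$rank)][-1] - 1L
        X <- X[, ok_cols, drop = FALSE]
      }
      resid <- stats::lm.fit(cbind(1, X), y[keep])$residuals
      ry <- stats::setNames(rep(NA_real_, length(y)), names(y))
      ry[keep] <- resid
      prof <- hk_profile(probs, ry, cap)
      sub <- prof[prof$chrom == eff$chrom[r], , drop = FALSE]
      pk <- which.max(sub$lod)
      moved <- max(moved, abs(sub$pos_cM[pk] - eff$pos_cM[r]))
      eff$pos_cM[r] <- sub$pos_cM[pk]
      eff$lod_mim[r] <- sub$lod[pk]
      eff$a_mim[r] <- sub$a[pk]
      eff$pev_mim[r] <- sub$r2[pk]
    }
    if (moved < 1) break
  }
  eff
}

#' Bootstrap uncertainty of a chromosome's QTL position and effect
#'
#' Lines are resampled with replacement, the chromosome re-scanned, and
#' the standard deviation and 2.5/97.5 percentiles of the peak position
#' and additive effect returned.  Degenerate bootstrap replicates
#' (constant trait or dosage) are skipped and counted.
#'
#' @param probs a [genotype_probabilities()] object
#' @param y named trait values
#' @param chrom chromosome with the detected effect
#' @param n_boot number of bootstrap replicates (default 500)
#' @param seed RNG seed
#' @param cap LOD ceiling
#' @return list: `sd_pos`, `sd_a`, `ci_pos`, `ci_a`, `n_ok`, `n_skipped`
#' @export
bootstrap_ci <- function(probs, y, chrom, n_boot = 500L, seed = 1L, cap = 50) {
  y <- align_trait(probs, y)
  keep <- which(!is.na(y))
  on_chr <- probs$grid$chrom == chrom
  pos <- probs$grid$pos_cM[on_chr]
  D <- probs$dosage[keep, on_chr, drop = FALSE]
  yv <- y[keep]
  set.seed(seed)
  pk_pos <- pk_a <- rep(NA_real_, n_boot)
  for (bi in seq_len(n_boot)) {
    idx <- sample(length(yv), replace = TRUE)
    yb <- yv[idx]
    if (stats::sd(yb) == 0) next
    Db <- D[idx, , drop = FALSE]
    yc <- yb - mean(yb)
    Dc <- sweep(Db, 2L, colMeans(Db))
    ss_d <- colSums(Dc^2)
    sxy <- as.vector(crossprod(Dc, yc))
    r2 <- ifelse(ss_d > 0, sxy^2 / (ss_d * sum(yc^2)), 0)
    pk <- which.max(r2)
    pk_pos[bi] <- pos[pk]
    pk_a[bi] <- if (ss_d[pk] > 0) sxy[pk] / ss_d[pk] else NA_real_
  }
  ok <- !is.na(pk_pos)
  list(sd_pos = stats::sd(pk_pos[ok]), sd_a = stats::sd(pk_a[ok]),
       ci_pos = stats::quantile(pk_pos[ok], c(0.025, 0.975), names = FALSE),
       ci_a = stats::quantile(pk_a[ok], c(0.025, 0.975), names = FALSE),
       n_ok = sum(ok), n_skipped = sum(!ok))
}
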