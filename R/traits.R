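#' Aggregate replicate phenotypes to line means
#'
#' Arithmetic mean over non-missing replicates per line x environment x
#' trait, with replicate counts and advisory distribution summaries
#' (skewness and a Shapiro-Wilk normality p per trait x environment;
#' non-normality is logged, never blocking).
#'
#' @param phenotypes long-format data.frame (`line`, `env`, `rep`,
#'   `trait`, `value`)
#' @return list with `means` (data.frame: `line`, `env`, `trait`,
#'   `mean`, `n_reps`) and `distribution` (per trait x env skewness and
#'   normality p)
#' @export
aggregate_means <- function(phenotypes) {
  stopifnot(all(c("line", "env", "trait", "value") %in% names(phenotypes)))
  key <- paste(phenotypes$line, phenotypes$env, phenotypes$trait, sep = "\r")
  mu <- tapply(phenotypes$value, key, function(v) {
    v <- v[!is.na(v)]
    if (length(v)) mean(v) else NA_real_
  })
  n_reps <- tapply(phenotypes$value, key, function(v) sum(!is.na(v)))
  parts <- do.call(rbind, strsplit(names(mu), "\r", fixed = TRUE))
  means <- data.frame(line = parts[, 1], env = parts[, 2], trait = parts[, 3],
                      mean = as.numeric(mu), n_reps = as.integer(n_reps),
                      stringsAsFactors = FALSE, row.names = NULL)

  dist <- list()
  for (tr in unique(means$trait)) for (e in unique(means$env)) {
    v <- means$mean[means$trait == tr & means$env == e]
    v <- v[!is.na(v)]
    if (length(v) < 4L || stats::sd(v) == 0) next
    z <- (v - mean(v)) / stats::sd(v)
    sw <- tryCatch(stats::shapiro.test(v)$p.value, error = function(e) NA_real_)
    dist[[paste(tr, e)]] <- data.frame(
      trait = tr, env = e, n = length(v), skewness = mean(z^3),
      normality_p = sw, stringsAsFactors = FALSE)
  }
  list(means = means, distribution = do.call(rbind, dist))
}

#' Extract one trait's line means in one environment
#'
#' @param means line-mean data.frame from [aggregate_means()]
#' @param trait,env trait name and environment (`WW`/`WL`)
#' @return named numeric vector (names are line ids)
#' @export
line_mean_vector <- function(means, trait, env) {
  sub <- means[means$trait == trait & means$env == env, , drop = FALSE]
  stats::setNames(sub$mean, sub$line)
}

# Ordinary least squares on complete cases; returns the fit contract the
# derivative-trait operations share.
ols_fit <- function(y, X, min_n) {
  keep <- stats::complete.cases(cbind(y, X))
  if (sum(keep) < min_n)
    stop("need at least ", min_n, " lines with all inputs non-missing")
  Xc <- cbind(`(Intercept)` = 1, X[keep, , drop = FALSE])
  for (j in seq_len(ncol(X))) {
    if (stats::sd(X[keep, j]) == 0)
      stop("predictor '", colnames(X)[j], "' has zero variance (degenerate fit)")
  }
  if (ncol(X) == 2L) {
    r <- stats::cor(X[keep, 1], X[keep, 2])
    if (abs(r) > 1 - 1e-8)
      stop("predictors '", colnames(X)[1], "' and '", colnames(X)[2],
           "' are collinear (|r| = ", format(abs(r)), ")")
  }
  fit <- stats::lm.fit(Xc, y[keep])
  fitted <- stats::setNames(fit$fitted.values, rownames(X)[keep])
  resid <- stats::setNames(fit$residuals, rownames(X)[keep])
  ss_tot <- sum((y[keep] - mean(y[keep]))^2)
  list(coefficients = fit$coefficients, fitted = fitted, residuals = resid,
       n = sum(keep), r_squared = if (ss_tot > 0) 1 - sum(resid^2) / ss_tot else NA_real_)
}

#' Phenology-adjusted derivative traits (prefix `df`)
#'
#' Regresses a trait's line means on the line means of the phenology
#' trait DP-H within one environment, `V_DH = beta + alpha * DH`, and
#' returns the residuals `E_DH = V - V_DH` as the `df`-trait.  Computed
#' separately per environment.
#'
#' @param trait_means named numeric: line means of the trait in one
#'   environment
#' @param dh_means named numeric: line means of DP-H in the same
#'   environment
#' @return list with `residuals` (named by line) and `fit`
#' @export
adjust_for_phenology <- function(trait_means, dh_means) {
  lines <- union(names(trait_means), names(dh_means))
  X <- matrix(dh_means[lines], ncol = 1,
              dimnames = list(lines, "DH"))
  fit <- ols_fit(trait_means[lines], X, min_n = 3L)
  list(residuals = fit$residuals, fit = fit)
}

#' Drought plasticity I (prefix `d`)
#'
#' Regresses water-limited line means on well-watered line means,
#' `prV_WL = beta + alpha * V_WW`, and returns the residuals
#' `E_WL = V_WL - prV_WL` as the `d`-trait: the deviation of a line's
#' stress performance from what its non-stress performance predicts.
#'
#' @param v_ww,v_wl named numeric: line means under WW and WL
#' @return list with `residuals` and `fit`
#' @export
plasticity_I <- function(v_ww, v_wl) {
  lines <- union(names(v_ww), names(v_wl))
  X <- matrix(v_ww[lines], ncol = 1, dimnames = list(lines, "V_WW"))
  fit <- ols_fit(v_wl[lines], X, min_n = 3L)
  list(residuals = fit$residuals, fit = fit)
}

#' Drought plasticity II (prefix `ddf`)
#'
#' Two-predictor regression of WL line means on WW line means and the
#' WL heading date, `V_WL^DH = beta + alpha1 * V_WW - alpha2 * DH_WL`,
#' residuals `E_WL^DH = V_WL - V_WL^DH` returned as the `ddf`-trait.
#' The minus sign on `alpha2` is a reporting convention; the fit itself
#' is unconstrained OLS.  Removing the heading component separates
#' drought-escape (phenology-mediated) plasticity from intrinsic
#' plasticity: a purely escape-driven signal present in the `d`-trait
#' vanishes here.
#'
#' @param v_ww,v_wl named numeric: line means under WW and WL
#' @param dh_wl named numeric: line means of DP-H under WL
#' @return list with `residuals` and `fit`
#' @export
plasticity_II <- function(v_ww, v_wl, dh_wl) {
  lines <- Reduce(union, list(names(v_ww), names(v_wl), names(dh_wl)))
  X <- cbind(V_WW = v_ww[lines], DH_WL = dh_wl[lines])
  rownames(X) <- lines
  fit <- ols_fit(v_wl[lines], X, min_n = 4L)
  list(residuals = fit$residuals, fit = fit)
}

#' All derivative trait sets for a study
#'
#' Computes, for every observed trait, the phenology-adjusted `df`-traits
#' (per environment), drought plasticity I (`d`) and drought plasticity
#' II (`ddf`) residual sets.  DP-H itself is adjusted only in the
#' plasticity sets; its `df` version is skipped (regressing DP-H on
#' itself is degenerate).
#'
#' @param means line-mean data.frame from [aggregate_means()]
#' @param phenology_trait name of the phenology trait (default `"DP-H"`)
#' @return data.frame: `line`, `trait` (prefixed `df`/`d`/`ddf`, with
#'   `_WW`/`_WL` suffix for the per-environment `df` set), `set`,
#'   `base_trait`, `env`, `value`
#' @export
derivative_traits <- function(means, phenology_trait = "DP-H") {
  traits <- setdiff(unique(means$trait), character(0))
  dh_ww <- line_mean_vector(means, phenology_trait, "WW")
  dh_wl <- line_mean_vector(means, phenology_trait, "WL")
  out <- list(); k <- 0L
  add <- function(res, trait, set, env) {
    k <<- k + 1L
    prefix <- c(df = "df", d = "d", ddf = "ddf")[[set]]
    name <- if (set == "df") paste0(prefix, trait, "_", env)
    else paste0(prefix, trait)
    out[[k]] <<- data.frame(line = names(res), trait = name, set = set,
                            base_trait = trait, env = env, value = unname(res),
                            stringsAsFactors = FALSE)
  }
  for (tr in traits) {
    v_ww <- line_mean_vector(means, tr, "WW")
    v_wl <- line_mean_vector(means, tr, "WL")
    if (tr != phenology_trait) {
      add(adjust_for_phenology(v_ww, dh_ww)$residuals, tr, "df", "WW")
      add(adjust_for_phenology(v_wl, dh_wl)$residuals, tr, "df", "WL")
    }
    add(plasticity_I(v_ww, v_wl)$residuals, tr, "d", "WL")
    if (tr != phenology_trait)
      add(plasticity_II(v_ww, v_wl, dh_wl)$residuals, tr, "ddf", "WL")
  }
  do.call(rbind, out)
}

#' Variance components and broad-sense heritability across environments
#'
#' Two-way ANOVA on replicate-level data (genotype, environment, their
#' interaction, residual) yields the genotype and genotype x environment
#' mean squares, from which
#' `sigma_g^2 = (MS_gen - MS_gxe) / e`, `sigma_gxe^2 = MS_gxe`, and
#' `h^2 = sigma_g^2 / (sigma_g^2 + sigma_gxe^2 / e)` with `e` the number
#' of environments.  A negative genetic-variance estimate is truncated
#' to 0 (flagged), keeping `h^2` in `[0, 1]`.
#'
#' @param phenotypes replicate-level long data.frame
#' @param trait trait name to analyse
#' @return list: `MS_gen`, `MS_gxe`, `e`, `sigma2_g`, `sigma2_gxe`,
#'   `h2`, `truncated`
#' @export
variance_components_heritability <- function(phenotypes, trait) {
  sub <- phenotypes[phenotypes$trait == trait & !is.na(phenotypes$value), ,
                    drop = FALSE]
  e <- length(unique(sub$env))
  if (e < 2L) stop("need two environments for cross-environment heritability")
  cells <- table(sub$line, sub$env)
  if (any(cells == 0L)) {
    empty <- which(cells == 0L, arr.ind = TRUE)
    stop("empty line x environment cells: ",
         paste(rownames(cells)[empty[, 1]], colnames(cells)[empty[, 2]],
               sep = ":", collapse = ", "))
  }
  if (length(unique(sub$line)) < 2L) stop("need at least 2 lines")
  fit <- stats::lm(value ~ line * env, data = sub)
  an <- stats::anova(fit)
  MS_gen <- an["line", "Mean Sq"]
  MS_gxe <- an["line:env", "Mean Sq"]
  heritability_from_ms(MS_gen, MS_gxe, e)
}

#' Heritability from genotype and interaction mean squares
#'
#' The algebra behind [variance_components_heritability()], exposed so
#' mean squares from any ANOVA can be plugged in directly.
#'
#' @param MS_gen genotype mean square
#' @param MS_gxe genotype x environment mean square
#' @param e number of environments
#' @return list: `MS_gen`, `MS_gxe`, `e`, `sigma2_g`, `sigma2_gxe`,
#'   `h2`, `truncated`
#' @export
heritability_from_ms <- function(MS_gen, MS_gxe, e) {
  stopifnot(e >= 2)
  sigma2_g <- (MS_gen - MS_gxe) / e
  truncated <- sigma2_g < 0
  if (truncated) sigma2_g <- 0
  sigma2_gxe <- MS_gxe
  h2 <- if (sigma2_g + sigma2_gxe / e > 0)
    sigma2_g / (sigma2_g + sigma2_gxe / e) else 0
  list(MS_gen = MS_gen, MS_gxe = MS_gxe, e = e, sigma2_g = sigma2_g,
       sigma2_gxe = sigma2_gxe, h2 = h2, truncated = truncated)
}

#' Pairwise-complete correlation analysis
#'
#' Pearson or Kendall-tau correlations between columns of a line x trait
#' value matrix, with per-pair complete-case counts and an exportable
#' edge list thresholded at a minimum absolute correlation (0.16 by
#' default, the display floor used for trait-network figures).
#'
#' @param values numeric matrix, lines in rows, traits in columns
#' @param method `"pearson"` or `"kendall"`
#' @param min_abs_r edge-list display threshold (default 0.16)
#' @return list: `r` (correlation matrix, `NA` where undefined or fewer
#'   than 3 complete pairs), `n` (complete-pair counts), `edges`
#'   (data.frame `trait1`, `trait2`, `r`, `n`)
#' @export
correlation_analysis <- function(values, method = c("pearson", "kendall"),
                                 min_abs_r = 0.16) {
  method <- match.arg(method)
  stopifnot(is.matrix(values), !is.null(colnames(values)))
  p <- ncol(values)
  r <- matrix(NA_real_, p, p, dimnames = list(colnames(values), colnames(values)))
  n <- matrix(0L, p, p, dimnames = dimnames(r))
  diag(r) <- 1
  for (i in seq_len(p)) for (j in seq_len(p)) {
    if (j <= i) next
    ok <- stats::complete.cases(values[, c(i, j)])
    n[i, j] <- n[j, i] <- sum(ok)
    if (sum(ok) < 3L) next
    x <- values[ok, i]; y <- values[ok, j]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) next  # undefined, left NA
    r[i, j] <- r[j, i] <- stats::cor(x, y, method = method)
  }
  diag(n) <- colSums(!is.na(values))
  idx <- which(upper.tri(r) & !is.na(r) & abs(r) >= min_abs_r, arr.ind = TRUE)
  edges <- data.frame(trait1 = colnames(values)[idx[, 1]],
                      trait2 = colnames(values)[idx[, 2]],
                      r = r[idx], n = n[idx], stringsAsFactors = FALSE)
  list(r = r, n = n, edges = edges[order(-abs(edges$r)), , drop = FALSE])
}

#' Line-mean matrix for correlation analysis
#'
#' Pivots line means (or derivative traits) to a lines x traits matrix.
#'
#' @param df data.frame with `line`, `trait` and a value column
#' @param value name of the value column (`"mean"` or `"value"`)
#' @return numeric matrix, lines in rows
#' @export
trait_matrix <- function(df, value = "mean") {
  lines <- sort(unique(df$line))
  traits <- unique(df$trait)
  m <- matrix(NA_real_, length(lines), length(traits),
              dimnames = list(lines, traits))
  m[cbind(match(df$line, lines), match(df$trait, traits))] <- df[[value]]
  m
}
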