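make_pheno <- function(df) {
  df$rep <- df$rep %||% 1L
  df
}

test_that("replicate aggregation averages non-missing values per cell", {
  ph <- data.frame(line = c("a", "a", "b", "b", "b"),
                   env = "WW", rep = c(1, 2, 1, 2, 3), trait = "T",
                   value = c(2, 4, 1, NA, 3))
  m <- aggregate_means(ph)$means
  expect_equal(m$mean[m$line == "a"], 3)
  expect_equal(m$mean[m$line == "b"], 2)        # mean over two non-missing
  expect_equal(m$n_reps[m$line == "b"], 2L)
})

test_that("aggregation equals a brute-force group-by on a full fixture", {
  st <- small_study()
  m <- aggregate_means(st$phenotypes)$means
  brute <- aggregate(value ~ line + env + trait, st$phenotypes, mean)
  merged <- merge(m, brute, by = c("line", "env", "trait"))
  expect_equal(merged$mean, merged$value, tolerance = 1e-12)
  expect_equal(nrow(merged), nrow(m))
})

test_that("phenology adjustment returns exact OLS residuals", {
  set.seed(10)
  n <- 60
  dh <- rnorm(n, 60, 5); names(dh) <- sprintf("L%02d", 1:n)
  # perfectly linear trait -> zero residuals
  lin <- 2 + 0.5 * dh
  expect_equal(max(abs(adjust_for_phenology(lin, dh)$residuals)), 0,
               tolerance = 1e-10)
  # orthogonal-by-construction trait -> centered values
  x <- rnorm(n); x <- x - mean(x)
  x <- x - (sum(x * (dh - mean(dh))) / sum((dh - mean(dh))^2)) * (dh - mean(dh))
  names(x) <- names(dh)
  res <- adjust_for_phenology(x, dh)$residuals
  expect_equal(res[names(x)], x - mean(x), tolerance = 1e-10)
})

test_that("all three derivative computations match the normal-equations oracle", {
  set.seed(11)
  for (i in 1:100) {
    n <- sample(10:40, 1)
    nm <- sprintf("L%02d", 1:n)
    v_ww <- setNames(rnorm(n, 10, 3), nm)
    v_wl <- setNames(0.8 * v_ww + rnorm(n), nm)
    dh <- setNames(rnorm(n, 60, 4), nm)
    r_df <- adjust_for_phenology(v_ww, dh)$residuals
    o_df <- ols_oracle(v_ww, matrix(dh, ncol = 1))
    expect_equal(unname(r_df[nm]), o_df$residuals, tolerance = 1e-10)
    r_d <- plasticity_I(v_ww, v_wl)$residuals
    o_d <- ols_oracle(v_wl, matrix(v_ww, ncol = 1))
    expect_equal(unname(r_d[nm]), o_d$residuals, tolerance = 1e-10)
    r_ddf <- plasticity_II(v_ww, v_wl, dh)$residuals
    o_ddf <- ols_oracle(v_wl, cbind(v_ww, dh))
    expect_equal(unname(r_ddf[nm]), o_ddf$residuals, tolerance = 1e-10)
    # residual means vanish and residuals are orthogonal to predictors
    expect_lt(abs(mean(r_ddf)), 1e-8 * sd(v_wl))
    expect_lt(abs(sum(r_ddf * v_ww[nm])), 1e-6)
    expect_lt(abs(sum(r_ddf * dh[nm])), 1e-6)
  }
})

test_that("plasticity II with an uninformative heading predictor reproduces plasticity I", {
  set.seed(12)
  n <- 50
  nm <- sprintf("L%02d", 1:n)
  v_ww <- setNames(rnorm(n), nm)
  v_wl <- setNames(0.5 * v_ww + rnorm(n), nm)
  r1 <- plasticity_I(v_ww, v_wl)$residuals
  # heading orthogonalized against intercept, V_WW and the plasticity-I
  # residuals -> its fitted coefficient is exactly zero
  z <- ols_oracle(rnorm(n), cbind(v_ww, r1[nm]))$residuals
  dh <- setNames(z, nm)
  r2 <- plasticity_II(v_ww, v_wl, dh)$residuals
  expect_equal(r2[nm], r1[nm], tolerance = 1e-8)
})

test_that("degenerate plasticity inputs raise the declared errors", {
  n <- 20; nm <- sprintf("L%02d", 1:n)
  v_ww <- setNames(rnorm(n), nm)
  v_wl <- setNames(rnorm(n), nm)
  expect_error(plasticity_II(v_ww, v_wl, setNames(rep(60, n), nm)),
               "zero variance")
  expect_error(plasticity_I(setNames(rep(1, n), nm), v_wl), "zero variance")
  expect_error(plasticity_II(v_ww, v_wl, setNames(2 * v_ww + 3, nm)),
               "collinear")
})

test_that("an exact linear combination leaves zero plasticity-II residuals", {
  n <- 30; nm <- sprintf("L%02d", 1:n)
  v_ww <- setNames(rnorm(n), nm)
  dh <- setNames(rnorm(n, 60, 3), nm)
  v_wl <- 5 + 1.2 * v_ww - 0.4 * dh
  expect_equal(max(abs(plasticity_II(v_ww, v_wl, dh)$residuals)), 0,
               tolerance = 1e-10)
})

test_that("a WL-only QTL appears in plasticity I; a mediated one vanishes in plasticity II", {
  cfg <- sim_config(n_lines = 2000, n_chromosomes = 2,
                    chrom_lengths_cM = c(60, 60), marker_spacing_cM = 15,
                    replicates_per_env = 2, seed = 31)
  mg <- simulate_map_and_genotypes(cfg)
  traits <- data.frame(name = c("DP-H", "Tesc", "Twl"), group = "yield",
                       intercept = c(60, 100, 50),
                       noise_sd_ww = c(0.5, 3, 2), noise_sd_wl = c(0.5, 3, 2))
  # Tesc: driven only through heading (whose QTL is WL-stronger);
  # Twl: direct WL-only effect
  qtls <- data.frame(trait = c("DP-H", "Twl"), chrom = c("chr1", "chr2"),
                     pos_cM = c(30, 30), a_ww = c(-1, 0), a_wl = c(-3, 2))
  arch <- trait_architecture(traits, qtls,
                             phenology_coupling = c(Tesc = -2),
                             dph_line_sd = 1.5)
  ph <- simulate_phenotypes(mg$map, mg$geno, arch, cfg)
  agg <- aggregate_means(ph$phenotypes)
  lm_of <- function(tr, e) with(agg$means[agg$means$trait == tr &
                                          agg$means$env == e, ],
                                setNames(mean, line))
  dos1 <- ifelse(mg$geno[, which(mg$map$chrom == "chr1")[3]] == "B", 1, -1)
  dos2 <- ifelse(mg$geno[, which(mg$map$chrom == "chr2")[3]] == "B", 1, -1)
  dh_wl <- lm_of("DP-H", "WL")
  # direct WL-only QTL: d correlates with dosage, ddf still does
  d_twl <- plasticity_I(lm_of("Twl", "WW"), lm_of("Twl", "WL"))$residuals
  ddf_twl <- plasticity_II(lm_of("Twl", "WW"), lm_of("Twl", "WL"), dh_wl)$residuals
  expect_gt(abs(cor(d_twl[rownames(mg$geno)], dos2)), 0.3)
  expect_gt(abs(cor(ddf_twl[rownames(mg$geno)], dos2)), 0.3)
  # escape signature: d sees the mediated signal, ddf suppresses it
  d_esc <- plasticity_I(lm_of("Tesc", "WW"), lm_of("Tesc", "WL"))$residuals
  ddf_esc <- plasticity_II(lm_of("Tesc", "WW"), lm_of("Tesc", "WL"), dh_wl)$residuals
  expect_gt(abs(cor(d_esc[rownames(mg$geno)], dos1)), 0.2)
  expect_lt(abs(cor(ddf_esc[rownames(mg$geno)], dos1)), 0.08)
})

test_that("heritability algebra reproduces the hand-evaluated case", {
  v <- heritability_from_ms(MS_gen = 10, MS_gxe = 2, e = 2)
  expect_equal(v$sigma2_g, 4)
  expect_equal(v$sigma2_gxe, 2)
  expect_equal(v$h2, 0.8)
  eq <- heritability_from_ms(5, 5, 2)
  expect_equal(eq$sigma2_g, 0)
  expect_equal(eq$h2, 0)
  tr <- heritability_from_ms(1, 4, 2)
  expect_true(tr$truncated)
  expect_gte(tr$h2, 0)
})

test_that("ANOVA mean squares agree with a brute-force sums-of-squares oracle", {
  set.seed(14)
  lines <- sprintf("L%02d", 1:12)
  ph <- expand.grid(line = lines, env = c("WW", "WL"), rep = 1:3,
                    stringsAsFactors = FALSE)
  gv <- setNames(rnorm(12, 0, 2), lines)
  ge <- matrix(rnorm(24, 0, 1), 12, 2, dimnames = list(lines, c("WW", "WL")))
  ph$trait <- "T"
  ph$value <- 10 + gv[ph$line] + ge[cbind(ph$line, ph$env)] + rnorm(nrow(ph), 0, 0.5)
  v <- variance_components_heritability(ph, "T")
  # brute force balanced two-way mean squares
  r <- 3; e <- 2
  cell <- tapply(ph$value, list(ph$line, ph$env), mean)
  gbar <- rowMeans(cell); ebar <- colMeans(cell); gm <- mean(ph$value)
  ss_g <- e * r * sum((gbar - gm)^2)
  ss_ge <- r * sum((sweep(sweep(cell, 1, gbar), 2, ebar) + gm)^2)
  expect_equal(v$MS_gen, ss_g / (12 - 1), tolerance = 1e-10)
  expect_equal(v$MS_gxe, ss_ge / ((12 - 1) * (e - 1)), tolerance = 1e-10)
})

test_that("heritability is invariant to affine trait rescaling", {
  st <- small_study()
  v1 <- variance_components_heritability(st$phenotypes, "TKW")
  ph2 <- st$phenotypes
  ph2$value[ph2$trait == "TKW"] <- 3.7 * ph2$value[ph2$trait == "TKW"] + 11
  v2 <- variance_components_heritability(ph2, "TKW")
  expect_equal(v1$h2, v2$h2, tolerance = 1e-10)
})

test_that("empty line x environment cells are reported by name", {
  ph <- data.frame(line = c("a", "a", "b"), env = c("WW", "WL", "WW"),
                   rep = 1L, trait = "T", value = 1:3)
  expect_error(variance_components_heritability(ph, "T"), "b:WL")
})

test_that("correlation analysis handles identities, sign flips and Kendall pairs", {
  set.seed(15)
  x <- rnorm(30); y <- rnorm(30)
  m <- cbind(x = x, neg = -x, y = y, const = 1)
  rownames(m) <- sprintf("L%02d", 1:30)
  out <- correlation_analysis(m, "kendall", min_abs_r = 0)
  expect_equal(out$r["x", "x"], 1)
  expect_equal(out$r["x", "neg"], -1)
  expect_true(is.na(out$r["x", "const"]))
  # O(n^2) concordant/discordant pair-count oracle
  conc <- disc <- 0
  for (i in 1:29) for (j in (i + 1):30) {
    s <- sign(x[i] - x[j]) * sign(y[i] - y[j])
    if (s > 0) conc <- conc + 1 else if (s < 0) disc <- disc + 1
  }
  expect_equal(out$r["x", "y"], (conc - disc) / choose(30, 2), tolerance = 1e-12)
  expect_true(all(out$n[upper.tri(out$n)] == 30))
})

test_that("the derivative sweep yields the df/d/ddf naming contract", {
  st <- small_study()
  agg <- aggregate_means(st$phenotypes)
  der <- derivative_traits(agg$means)
  expect_setequal(unique(der$set), c("df", "d", "ddf"))
  expect_true(all(grepl("^df", der$trait[der$set == "df"])))
  expect_true(all(grepl("^d[^f]", der$trait[der$set == "d"])))
  expect_true(all(grepl("^ddf", der$trait[der$set == "ddf"])))
  # per-set residual means vanish
  mu <- tapply(der$value, der$trait, mean)
  expect_lt(max(abs(mu)), 1e-8)
})
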