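# Small deterministic map + genotypes used across scan tests
scan_fixture <- function(n = 150, seed = 51, n_chrom = 2,
                         len = 80, spacing = 10) {
  cfg <- sim_config(n_lines = n, n_chromosomes = n_chrom,
                    chrom_lengths_cM = len, marker_spacing_cM = spacing,
                    seed = seed)
  mg <- simulate_map_and_genotypes(cfg)
  probs <- genotype_probabilities(mg$map, mg$geno, step_cM = 1)
  list(cfg = cfg, map = mg$map, geno = mg$geno, probs = probs)
}

dosage_of <- function(fx, chrom, idx) {
  cols <- which(fx$map$chrom == chrom)
  ifelse(fx$geno[, cols[idx]] == "B", 1, -1)
}

test_that("expected dosage honours observed calls and the two-flank formula", {
  fx <- scan_fixture(n = 40)
  # at a non-missing marker the dosage is the call itself
  for (mk in sample(fx$map$marker, 5)) {
    gi <- which(fx$probs$grid$chrom == fx$map$chrom[fx$map$marker == mk] &
                fx$probs$grid$pos_cM == fx$map$pos_cM[fx$map$marker == mk])
    expect_equal(fx$probs$dosage[, gi],
                 ifelse(fx$geno[, mk] == "B", 1, -1))
  }
  # midpoint between equal +1 flanks, 10 cM apart: closed-form conditional
  R <- ril_cM_to_R(5)
  p_plus <- (1 - R)^2 / ((1 - R)^2 + R^2)
  expected_mid <- 2 * p_plus - 1
  expect_gt(expected_mid, 0.9)
  line <- which(fx$geno[, 1] == "B" & fx$geno[, 2] == "B")[1]
  gi <- which(fx$probs$grid$chrom == fx$map$chrom[1] &
              fx$probs$grid$pos_cM == 5)
  expect_equal(unname(fx$probs$dosage[line, gi]), expected_mid,
               tolerance = 1e-12)
  # opposite flanks: dosage crosses zero inside the interval
  line2 <- which(fx$geno[, 1] == "B" & fx$geno[, 2] == "A")[1]
  seg <- which(fx$probs$grid$chrom == fx$map$chrom[1] &
               fx$probs$grid$pos_cM >= 0 & fx$probs$grid$pos_cM <= 10)
  d_seg <- fx$probs$dosage[line2, seg]
  expect_equal(d_seg[1], 1)
  expect_equal(d_seg[length(d_seg)], -1)
  expect_equal(unname(fx$probs$dosage[line2, seg[fx$probs$grid$pos_cM[seg] == 5]]),
               0, tolerance = 1e-12)
})

test_that("scan LOD equals the brute-force regression identity everywhere", {
  fx <- scan_fixture()
  set.seed(52)
  y <- setNames(0.8 * dosage_of(fx, fx$map$chrom[1], 4) + rnorm(150),
                rownames(fx$geno))
  prof <- scan_single(fx$probs, y)
  for (gi in seq(1, nrow(prof), by = 17)) {
    fit <- lm(y ~ fx$probs$dosage[, gi])
    r2 <- summary(fit)$r.squared
    expect_equal(prof$lod[gi], -(150 / 2) * log10(1 - r2), tolerance = 1e-8)
    expect_equal(prof$a[gi], unname(coef(fit)[2]), tolerance = 1e-8)
  }
})

test_that("a perfect genetic signal caps the LOD and saturates PEV", {
  fx <- scan_fixture()
  y <- setNames(dosage_of(fx, fx$map$chrom[1], 4), rownames(fx$geno))
  prof <- scan_single(fx$probs, y)
  expect_equal(max(prof$lod), 50)
  expect_equal(max(prof$r2), 1)
  eff <- effect_summary(prof, 3)
  expect_equal(eff$pos_cM[1], fx$map$pos_cM[4])  # tie-broken by R^2
  expect_equal(eff$itv[1], "P2")
  expect_equal(eff$pev[1], 1)
})

test_that("a constant trait yields a flat zero profile", {
  fx <- scan_fixture(n = 30)
  prof <- scan_single(fx$probs, setNames(rep(5, 30), rownames(fx$geno)))
  expect_true(all(prof$lod == 0))
  expect_equal(nrow(effect_summary(prof, 0.1)), 0L)
})

test_that("permutation thresholds are reproducible and alpha=1 returns the minimum", {
  fx <- scan_fixture(n = 60)
  set.seed(53)
  y <- setNames(rnorm(60), rownames(fx$geno))
  t1 <- permutation_threshold(fx$probs, y, n_perm = 150, alpha = 0.05, seed = 9)
  t2 <- permutation_threshold(fx$probs, y, n_perm = 150, alpha = 0.05, seed = 9)
  expect_identical(t1$threshold, t2$threshold)
  expect_identical(t1$max_lods, t2$max_lods)
  tall <- permutation_threshold(fx$probs, y, n_perm = 150, alpha = 1, seed = 9)
  expect_equal(tall$threshold, min(tall$max_lods))
  expect_equal(t1$threshold,
               quantile(t1$max_lods, 0.95, type = 1, names = FALSE))
})

test_that("support intervals clip at chromosome ends and track symmetry", {
  grid <- data.frame(chrom = "c1", pos_cM = 0:40)
  monotone <- structure(
    data.frame(chrom = "c1", pos_cM = 0:40, lod = seq(1, 9, length.out = 41),
               a = 1, r2 = 0.2, n = 100),
    class = c("scan_profile", "data.frame"))
  eff <- effect_summary(monotone, 3)
  expect_equal(eff$pos_cM, 40)
  expect_equal(eff$ci_hi, 40)           # clipped at the end
  symmetric <- monotone
  symmetric$lod <- 8 - abs(20 - symmetric$pos_cM) * 0.3
  eff2 <- effect_summary(symmetric, 3)
  expect_equal(eff2$pos_cM, 20)
  expect_equal(eff2$pos_cM - eff2$ci_lo, eff2$ci_hi - eff2$pos_cM)
  expect_equal(eff2$ci_hi - eff2$ci_lo, 10)  # 1.5/0.3 cM each side
})

test_that("the two-linked-QTL model is kept only when it earns its margin", {
  fx <- scan_fixture(n = 500, seed = 54, n_chrom = 1, len = 80, spacing = 10)
  d20 <- setNames(dosage_of(fx, "chr1", 3), rownames(fx$geno))  # 20 cM
  d60 <- setNames(dosage_of(fx, "chr1", 7), rownames(fx$geno))  # 60 cM
  set.seed(55)
  noise <- rnorm(500, 0, 1)
  two <- scan_two_linked(fx$probs, d20 * 1 - d60 * 1 + noise, "chr1")
  expect_true(two$retained)
  expect_lt(abs(min(two$positions) - 20), 5)
  expect_lt(abs(max(two$positions) - 60), 5)
  expect_equal(sign(two$effects), c(1, -1))
  one <- scan_two_linked(fx$probs, d20 * 1.2 + noise, "chr1")
  expect_false(one$retained)
  null <- scan_two_linked(fx$probs, setNames(noise, rownames(fx$geno)), "chr1")
  expect_false(null$retained)
})

test_that("joint-environment LOD adds per-environment contributions", {
  fx <- scan_fixture(n = 200, seed = 56)
  d <- setNames(dosage_of(fx, fx$map$chrom[1], 4), rownames(fx$geno))
  set.seed(57)
  y_ww <- d * 0.8 + rnorm(200); names(y_ww) <- names(d)
  y_wl <- d * 0.8 + rnorm(200); names(y_wl) <- names(d)
  joint <- scan_joint_environments(fx$probs, y_ww, y_wl)
  s_ww <- scan_single(fx$probs, y_ww)
  s_wl <- scan_single(fx$probs, y_wl)
  expect_equal(joint$lod, s_ww$lod + s_wl$lod, tolerance = 1e-10)
  pk <- which.max(joint$lod)
  expect_equal(env_specificity(joint[pk, ], env_threshold = 3), "both")
  # WL-only architecture tags WL-specific
  y_flat <- setNames(rnorm(200), names(d))
  joint2 <- scan_joint_environments(fx$probs, y_flat, y_wl)
  pk2 <- which.max(joint2$lod)
  expect_equal(env_specificity(joint2[pk2, ], env_threshold = 3), "WL-specific")
})

test_that("MIM refinement is a no-op for one QTL and sharpens two unlinked QTLs", {
  fx <- scan_fixture(n = 300, seed = 58, n_chrom = 2)
  d1 <- setNames(dosage_of(fx, fx$map$chrom[1], 4), rownames(fx$geno))
  cols2 <- which(fx$map$chrom == unique(fx$map$chrom)[2])
  d2 <- ifelse(fx$geno[, cols2[4]] == "B", 1, -1)
  set.seed(59)
  y <- 0.8 * d1 + 0.8 * d2 + rnorm(300); names(y) <- names(d1)
  prof <- scan_single(fx$probs, y)
  eff <- effect_summary(prof, 3)
  expect_equal(nrow(eff), 2L)
  ref <- mim_refine(eff, fx$probs, y)
  expect_true(all(ref$lod_mim > eff$lod))  # background adjustment helps
  one <- eff[1, , drop = FALSE]
  ref1 <- mim_refine(one, fx$probs, y)
  expect_equal(ref1$lod_mim, one$lod)      # nothing to adjust for
  expect_equal(ref1$pos_cM, one$pos_cM)
})

test_that("bootstrap uncertainty is reproducible and orders by signal strength", {
  fx <- scan_fixture(n = 500, seed = 60, n_chrom = 1)
  d <- setNames(dosage_of(fx, "chr1", 4), rownames(fx$geno))
  set.seed(61)
  strong <- d + rnorm(500, 0, 1); names(strong) <- names(d)   # PEV ~ 0.5
  weak <- 0.35 * d + rnorm(500, 0, 1); names(weak) <- names(d)
  bs <- bootstrap_ci(fx$probs, strong, "chr1", n_boot = 200, seed = 4)
  bs2 <- bootstrap_ci(fx$probs, strong, "chr1", n_boot = 200, seed = 4)
  expect_identical(bs, bs2)
  expect_lt(bs$sd_pos, 3)
  bw <- bootstrap_ci(fx$probs, weak, "chr1", n_boot = 200, seed = 4)
  expect_gt(bw$sd_pos, bs$sd_pos)
  expect_true(bs$ci_pos[1] <= 30 && bs$ci_pos[2] >= 30)
})

test_that("scan_trait tags effects and skips degenerate traits", {
  fx <- scan_fixture(n = 150, seed = 62)
  d <- setNames(dosage_of(fx, fx$map$chrom[1], 4), rownames(fx$geno))
  set.seed(63)
  y <- 0.9 * d + rnorm(150); names(y) <- names(d)
  eff <- scan_trait(fx$probs, y, "dGY", "d", "GY", "WL",
                    n_perm = 150, seed = 3)
  expect_gte(nrow(eff), 1L)
  expect_equal(eff$set[1], "d")
  expect_equal(eff$base_trait[1], "GY")
  expect_true(all(c("threshold", "ci_lo", "ci_hi") %in% names(eff)))
  none <- scan_trait(fx$probs, setNames(rep(1, 150), names(d)),
                     "x", "obs", "x", "WW", n_perm = 150, seed = 3)
  expect_equal(nrow(none), 0L)
})
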